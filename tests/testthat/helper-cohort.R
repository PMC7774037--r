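# Desk-scale simulation configs for tests. Library depth scales with the
# gene count so per-gene coverage matches the full-size default (~200 reads
# per gene per sample).

small_config <- function(n_genes = 800, seed = 1, ...) {
  args <- list(...)
  defaults <- list(
    n_genes = n_genes,
    n_up_total = round(829 / 5000 * n_genes),
    n_down_total = round(1125 / 5000 * n_genes),
    n_signature = round(300 / 5000 * n_genes),
    depth_range = c(0.8e6, 1.2e6) * n_genes / 5000,
    seed = seed
  )
  do.call(sim_config, utils::modifyList(defaults, args))
}

null_config <- function(n_genes = 800, seed = 1, ...) {
  small_config(n_genes = n_genes, seed = seed,
               n_up_total = 0, n_down_total = 0, n_signature = 0,
               behavior_params = list(b0 = 3, b1 = -4, wt_sd = 0.2,
                                      ad_sd = 1.0, decouple = FALSE,
                                      decouple_base = 0.8,
                                      decouple_slope = -0.01),
               ...)
}

cohort_logcpm <- function(ch) {
  kept <- filter_genes(compute_rpkm(ch$counts, ch$lengths))$kept
  nf <- tmm_factors(ch$counts, kept_genes = kept)
  log_expression(ch$counts[kept, , drop = FALSE], nf)
}
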