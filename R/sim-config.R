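#' Configuration for the synthetic longitudinal cohort generator
#'
#' Builds and validates the full parameter set of the generative model used
#' by [simulate_cohort()]. The default design mirrors a two-genotype mouse
#' cohort (wild-type `WT` vs transgenic `AD`) with three animals per genotype
#' sampled at 2, 7, 8, 11 and 14 months of age (30 samples in total), planted
#' directional differential expression whose extent decreases with age, a
#' progressive amyloid-beta (1-42) burden in `AD` animals, and a "signature"
#' subset of down-regulated genes whose expression is coupled to a latent
#' cortical-function variable that also drives taste-aversion learning in
#' healthy animals.
#'
#' @param n_genes number of genes simulated.
#' @param ages postnatal ages in months at which animals are sampled.
#' @param n_rep animals per genotype per age.
#' @param n_up_total,n_down_total pooled numbers of up- / down-regulated
#'   differentially expressed genes across all ages.
#' @param de_age_profile per-age fraction of each directional DEG pool that
#'   carries a nonzero expression effect at that age; values in `[0, 1]`,
#'   monotone non-increasing by default so the count of active DEGs falls
#'   with age (exactly `round(p * n)` genes per age). Signature genes are
#'   always active; the remaining active genes are drawn at random per age,
#'   so age-step expression patterns are decorrelated across genes (see the
#'   methods vignette for why the default profile is kept near-flat).
#' @param lfc_range magnitude interval of planted log2 fold changes.
#' @param n_signature number of down-regulated DEGs additionally coupled to
#'   the latent variable (drawn from the always-active head of the down
#'   pool).
#' @param beta_range coupling coefficient interval (log2 scale per unit of
#'   latent variable) for signature genes.
#' @param dispersion negative-binomial dispersion phi (scalar, or one value
#'   per gene); counts have variance `mu + phi * mu^2`.
#' @param depth_range library-size interval (total expected counts per
#'   sample); depths are drawn uniformly.
#' @param length_range gene length interval in bp (uniform integer draw).
#' @param abundance_sdlog log-normal sd of relative gene abundances.
#' @param abeta_params amyloid model: `wt_mean`/`wt_sd` for the flat
#'   wild-type baseline (pg/mL); `ad_intercept`, `ad_slope` (pg/mL per
#'   month past the youngest age) and `ad_sd` for transgenic animals.
#'   Values are left-truncated at 0.
#' @param latent_params latent cortical-function variable `L`:
#'   `wt_sd` around a wild-type mean of 1; in `AD`,
#'   `L = 1 - gamma * abeta / max(abeta) + noise(ad_sd)`.
#' @param behavior_params aversion-index model on the logit scale:
#'   `index = logistic(b0 + b1 * driver + noise)` with `driver = L` in WT.
#'   With `decouple = TRUE` (default) the AD driver is replaced by the
#'   age-driven term `decouple_base + decouple_slope * (age - min(age))`
#'   with noise sd `ad_sd`, severing the behavior-signature correlation
#'   in transgenic animals; with `decouple = FALSE` AD behavior follows
#'   `L` like WT. Lower index = stronger learned aversion.
#' @param seed integer RNG seed.
#'
#' @return an object of class `sim_config` (a validated named list).
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 500, seed = 1)
#' cfg$ages
sim_config <- function(n_genes = 5000,
                       ages = c(2, 7, 8, 11, 14),
                       n_rep = 3,
                       n_up_total = 829,
                       n_down_total = 1125,
                       de_age_profile = c(1, 0.9875, 0.975, 0.9625, 0.95),
                       lfc_range = c(1, 3),
                       n_signature = 300,
                       beta_range = c(0.3, 0.8),
                       dispersion = 0.1,
                       depth_range = c(0.8e6, 1.2e6),
                       length_range = c(200, 10000),
                       abundance_sdlog = 1.2,
                       abeta_params = list(wt_mean = 50, wt_sd = 15,
                                           ad_intercept = 400, ad_slope = 4,
                                           ad_sd = 250),
                       latent_params = list(wt_sd = 0.45, gamma = 1.7,
                                            ad_sd = 0.05),
                       behavior_params = list(b0 = 3, b1 = -4,
                                              wt_sd = 0.2, ad_sd = 1.0,
                                              decouple = TRUE,
                                              decouple_base = 0.8,
                                              decouple_slope = -0.01),
                       seed = 1) {
  cfg <- list(n_genes = n_genes, ages = ages, n_rep = n_rep,
              genotypes = c("WT", "AD"),
              n_up_total = n_up_total, n_down_total = n_down_total,
              de_age_profile = de_age_profile, lfc_range = lfc_range,
              n_signature = n_signature, beta_range = beta_range,
              dispersion = dispersion, depth_range = depth_range,
              length_range = length_range, abundance_sdlog = abundance_sdlog,
              abeta_params = abeta_params, latent_params = latent_params,
              behavior_params = behavior_params, seed = seed)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (!is_count(cfg$n_genes, 1)) {
    stop2("configuration error: 'n_genes' must be a positive integer")
  }
  assert_numeric_range(cfg$ages, "ages", lo = 0)
  if (anyDuplicated(cfg$ages)) {
    stop2("configuration error: 'ages' must be distinct")
  }
  if (!is_count(cfg$n_rep, 1)) {
    stop2("configuration error: 'n_rep' must be a positive integer")
  }
  for (f in c("n_up_total", "n_down_total", "n_signature")) {
    if (!is_count(cfg[[f]], 0)) {
      stop2("configuration error: '", f, "' must be a non-negative integer")
    }
  }
  if (cfg$n_up_total + cfg$n_down_total + cfg$n_signature > cfg$n_genes) {
    stop2("configuration error: 'n_up_total' + 'n_down_total' + ",
          "'n_signature' exceeds 'n_genes'")
  }
  if (cfg$n_signature > cfg$n_down_total) {
    stop2("configuration error: 'n_signature' exceeds 'n_down_total'")
  }
  assert_numeric_range(cfg$de_age_profile, "de_age_profile", 0, 1,
                       len = length(cfg$ages))
  assert_numeric_range(cfg$lfc_range, "lfc_range", lo = 0, len = 2)
  assert_numeric_range(cfg$beta_range, "beta_range", lo = 0, len = 2)
  if (!is.numeric(cfg$dispersion) || any(cfg$dispersion <= 0)) {
    stop2("configuration error: 'dispersion' must be > 0")
  }
  if (!length(cfg$dispersion) %in% c(1L, cfg$n_genes)) {
    stop2("configuration error: 'dispersion' must be scalar or per-gene")
  }
  assert_numeric_range(cfg$depth_range, "depth_range", lo = 1, len = 2)
  assert_numeric_range(cfg$length_range, "length_range", lo = 1, len = 2)
  assert_numeric_range(cfg$abundance_sdlog, "abundance_sdlog", lo = 0, len = 1)
  ab <- cfg$abeta_params
  for (f in c("wt_mean", "wt_sd", "ad_intercept", "ad_slope", "ad_sd")) {
    if (!is.numeric(ab[[f]] %||% NA) || is.na(ab[[f]])) {
      stop2("configuration error: 'abeta_params$", f, "' missing or invalid")
    }
  }
  if (ab$wt_sd <= 0 || ab$ad_sd <= 0) {
    stop2("configuration error: 'abeta_params' sd values must be > 0")
  }
  lt <- cfg$latent_params
  if (!is.numeric(lt$wt_sd %||% NA) || lt$wt_sd <= 0 ||
      !is.numeric(lt$ad_sd %||% NA) || lt$ad_sd <= 0 ||
      !is.numeric(lt$gamma %||% NA)) {
    stop2("configuration error: 'latent_params' needs wt_sd > 0, ad_sd > 0, gamma")
  }
  bh <- cfg$behavior_params
  for (f in c("b0", "b1", "wt_sd", "ad_sd", "decouple_base",
              "decouple_slope")) {
    if (!is.numeric(bh[[f]] %||% NA) || is.na(bh[[f]])) {
      stop2("configuration error: 'behavior_params$", f, "' missing or invalid")
    }
  }
  if (bh$wt_sd <= 0 || bh$ad_sd <= 0) {
    stop2("configuration error: 'behavior_params' sd values must be > 0")
  }
  if (!is.logical(bh$decouple %||% NA) || is.na(bh$decouple)) {
    stop2("configuration error: 'behavior_params$decouple' must be TRUE/FALSE")
  }
  if (!is_count(abs(cfg$seed), 0)) {
    stop2("configuration error: 'seed' must be an integer")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_genes, "genes;",
      length(x$ages) * 2 * x$n_rep, "samples (",
      paste(x$ages, collapse = "/"), "months x WT/AD x", x$n_rep, "reps )\n")
  cat("  planted DEGs: up", x$n_up_total, "| down", x$n_down_total,
      "| signature", x$n_signature, "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}
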