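#' Simulate a longitudinal two-genotype cohort with ground truth
#'
#' Draws a complete synthetic cohort from the generative model described in
#' [sim_config()]: per-gene log-normal baseline abundances, uniform library
#' depths, a progressive amyloid burden in transgenic animals, a latent
#' cortical-function variable `L` coupling a signature subset of
#' down-regulated genes to behavior (in WT) and to amyloid (in AD), and
#' negative-binomial counts with per-gene dispersion. All randomness flows
#' from `config$seed`.
#'
#' The count model is
#' `counts[i, j] ~ NB(mean = q_i * N_j * 2^eta_ij, dispersion = phi_i)` with
#' `eta_ij = lfc_i * [genotype_j == "AD" & age_j active for gene i] +
#' beta_i * (L_j - 1)`, where `beta_i > 0` only for signature genes.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `ad_cohort`: a list with elements
#'   * `counts`: integer matrix, genes x samples;
#'   * `lengths`: named integer vector of gene lengths (bp);
#'   * `samples`: data frame with `sample_id`, `genotype`, `age_months`,
#'     `replicate`, `aversion_index`, `abeta42`;
#'   * `truth`: list with `genes` (per-gene `status`, `active_ages`,
#'     `lfc`, `beta`) and `latent` (per-sample `L`).
#' @export
#' @examples
#' ch <- simulate_cohort(sim_config(n_genes = 300, seed = 7))
#' dim(ch$counts)
#' table(ch$truth$genes$status)
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)

  n_genes <- config$n_genes
  gene_ids <- sprintf("G%05d", seq_len(n_genes))
  ages <- config$ages
  n_age <- length(ages)
  n_rep <- config$n_rep

  samples <- expand.grid(replicate = seq_len(n_rep), age_months = ages,
                         genotype = config$genotypes,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  samples <- samples[, c("genotype", "age_months", "replicate")]
  samples$sample_id <- sprintf("%s_%02dm_r%d", samples$genotype,
                               samples$age_months, samples$replicate)
  n_samp <- nrow(samples)
  is_ad <- samples$genotype == "AD"

  # -- gene-level structure ------------------------------------------------
  lengths_bp <- sample.int(config$length_range[2] - config$length_range[1] + 1L,
                           n_genes, replace = TRUE) + config$length_range[1] - 1L
  q <- stats::rlnorm(n_genes, meanlog = 0, sdlog = config$abundance_sdlog)
  q <- q / sum(q)

  perm <- sample.int(n_genes)
  up_idx <- if (config$n_up_total > 0) perm[seq_len(config$n_up_total)] else integer(0)
  down_idx <- if (config$n_down_total > 0) {
    perm[config$n_up_total + seq_len(config$n_down_total)]
  } else integer(0)
  sig_idx <- if (config$n_signature > 0) down_idx[seq_len(config$n_signature)] else integer(0)

  status <- rep("null", n_genes)
  status[up_idx] <- "up"
  status[down_idx] <- "down"
  status[sig_idx] <- "signature"

  # Per-age activity with exact counts round(p_a * n) per directional pool.
  # Signature genes are active at every age with nonzero profile (their
  # phenotype coupling is the planted signal and must not be confounded
  # with age-step patterns); the remaining active genes at each age are an
  # independent random draw from the pool, so age-step expression patterns
  # are decorrelated across genes rather than forming one shared trend.
  active <- matrix(FALSE, n_genes, n_age, dimnames = list(gene_ids, ages))
  pick_active <- function(pool, fixed, k) {
    # `fixed` genes (a subset of pool) take priority; the rest are random.
    if (k <= length(fixed)) return(fixed[seq_len(k)])
    free <- setdiff(pool, fixed)
    c(fixed, free[sample.int(length(free), k - length(fixed))])
  }
  for (a in seq_len(n_age)) {
    if (config$de_age_profile[a] == 0) next
    k_up <- round(config$de_age_profile[a] * config$n_up_total)
    k_down <- round(config$de_age_profile[a] * config$n_down_total)
    if (k_up > 0) {
      active[pick_active(up_idx, integer(0), k_up), a] <- TRUE
    }
    if (k_down > 0) {
      active[pick_active(down_idx, sig_idx, k_down), a] <- TRUE
    }
  }

  lfc <- numeric(n_genes)
  de_idx <- c(up_idx, down_idx)
  if (length(de_idx) > 0) {
    mag <- stats::runif(length(de_idx), config$lfc_range[1], config$lfc_range[2])
    lfc[de_idx] <- mag * ifelse(seq_along(de_idx) <= length(up_idx), 1, -1)
  }
  beta <- numeric(n_genes)
  if (length(sig_idx) > 0) {
    beta[sig_idx] <- stats::runif(length(sig_idx), config$beta_range[1],
                                  config$beta_range[2])
  }
  phi <- rep_len(config$dispersion, n_genes)

  # -- per-animal phenotypes ----------------------------------------------
  depth <- stats::runif(n_samp, config$depth_range[1], config$depth_range[2])

  ab <- config$abeta_params
  abeta <- numeric(n_samp)
  abeta[!is_ad] <- pmax(0, stats::rnorm(sum(!is_ad), ab$wt_mean, ab$wt_sd))
  abeta[is_ad] <- pmax(0, ab$ad_intercept +
                          ab$ad_slope * (samples$age_months[is_ad] - min(ages)) +
                          stats::rnorm(sum(is_ad), 0, ab$ad_sd))

  lt <- config$latent_params
  L <- numeric(n_samp)
  L[!is_ad] <- stats::rnorm(sum(!is_ad), 1, lt$wt_sd)
  max_ab <- max(abeta[is_ad], 1e-12)
  L[is_ad] <- 1 - lt$gamma * (abeta[is_ad] / max_ab) +
    stats::rnorm(sum(is_ad), 0, lt$ad_sd)

  bh <- config$behavior_params
  driver <- L
  if (isTRUE(bh$decouple)) {
    driver[is_ad] <- bh$decouple_base +
      bh$decouple_slope * (samples$age_months[is_ad] - min(ages))
  }
  noise <- ifelse(is_ad, stats::rnorm(n_samp, 0, bh$ad_sd),
                  stats::rnorm(n_samp, 0, bh$wt_sd))
  aversion <- stats::plogis(bh$b0 + bh$b1 * driver + noise)

  samples$aversion_index <- aversion
  samples$abeta42 <- abeta
  samples <- samples[, c("sample_id", "genotype", "age_months", "replicate",
                         "aversion_index", "abeta42")]

  # -- counts --------------------------------------------------------------
  age_col <- match(samples$age_months, ages)
  eta <- matrix(0, n_genes, n_samp)
  for (j in seq_len(n_samp)) {
    if (is_ad[j]) eta[, j] <- lfc * active[, age_col[j]]
  }
  if (length(sig_idx) > 0) {
    eta <- eta + outer(beta, L - 1)
  }
  mu <- (q * 2^eta) %*% diag(depth) # genes x samples
  counts <- sample_nb_counts(mu, phi)
  dimnames(counts) <- list(gene_ids, samples$sample_id)

  truth_genes <- data.frame(
    gene_id = gene_ids,
    status = status,
    active_ages = vapply(seq_len(n_genes), function(i) {
      paste(ages[active[i, ]], collapse = ",")
    }, character(1)),
    lfc = lfc,
    beta = beta,
    stringsAsFactors = FALSE
  )
  truth <- list(genes = truth_genes,
                latent = data.frame(sample_id = samples$sample_id, L = L,
                                    stringsAsFactors = FALSE))

  structure(list(counts = counts,
                 lengths = stats::setNames(as.integer(lengths_bp), gene_ids),
                 samples = samples,
                 truth = truth),
            class = "ad_cohort")
}

# Negative-binomial count draw with variance mu + phi * mu^2; phi recycled
# over genes. Kept as a separate routine so the marginal parameterization
# can be tested in isolation.
sample_nb_counts <- function(mu, phi) {
  n_genes <- nrow(mu)
  phi <- rep_len(phi, n_genes)
  out <- matrix(stats::rnbinom(length(mu), size = rep(1 / phi, ncol(mu)),
                               mu = as.vector(mu)),
                n_genes, ncol(mu))
  storage.mode(out) <- "integer"
  out
}

#' @export
print.ad_cohort <- function(x, ...) {
  cat("ad_cohort:", nrow(x$counts), "genes x", ncol(x$counts), "samples\n")
  cat("  genotypes:", paste(names(table(x$samples$genotype)), collapse = "/"),
      "| ages:", paste(sort(unique(x$samples$age_months)), collapse = "/"), "\n")
  if (!is.null(x$truth)) {
    cat("  truth:", sum(x$truth$genes$status != "null"), "planted DEGs\n")
  }
  invisible(x)
}

#' Write a cohort to a directory of TSV files
#'
#' Emits `counts.tsv` (gene_id, length_bp, one integer column per sample),
#' `samples.tsv`, and, when ground truth is present, `truth.tsv` (per gene)
#' and `latent.tsv` (per sample). All files are UTF-8, tab-delimited with a
#' header row; decimals use full precision so that [read_cohort()] restores
#' values exactly.
#'
#' @param cohort an `ad_cohort` object.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ad_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  counts_df <- data.frame(gene_id = rownames(cohort$counts),
                          length_bp = as.integer(cohort$lengths),
                          cohort$counts, check.names = FALSE,
                          stringsAsFactors = FALSE)
  files <- file.path(dir, c("counts.tsv", "samples.tsv"))
  write_tsv(counts_df, files[1])
  write_tsv(cohort$samples, files[2])
  if (!is.null(cohort$truth)) {
    f3 <- file.path(dir, "truth.tsv")
    f4 <- file.path(dir, "latent.tsv")
    write_tsv(cohort$truth$genes, f3)
    write_tsv(cohort$truth$latent, f4)
    files <- c(files, f3, f4)
  }
  invisible(files)
}

#' Read a cohort written by [write_cohort()]
#'
#' Validates count integrality and non-negativity, gene-length positivity,
#' and uniqueness of (genotype, age, replicate) while reading; violations
#' raise a parse/validation error naming the file and first offending line.
#'
#' @param dir directory containing `counts.tsv` and `samples.tsv`
#'   (optionally `truth.tsv` and `latent.tsv`).
#' @return an `ad_cohort` object.
#' @export
read_cohort <- function(dir) {
  cfile <- file.path(dir, "counts.tsv")
  counts_df <- read_tsv(cfile)
  if (ncol(counts_df) < 3 || names(counts_df)[1] != "gene_id" ||
      names(counts_df)[2] != "length_bp") {
    stop2("parse error: ", cfile,
          " must start with columns gene_id, length_bp")
  }
  m <- as.matrix(counts_df[, -(1:2), drop = FALSE])
  if (!is.numeric(m)) stop2("parse error: non-numeric counts in ", cfile)
  bad <- which(m < 0 | m != floor(m), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop2("parse error: ", cfile, " line ", bad[1, 1] + 1L,
          ": counts must be non-negative integers")
  }
  storage.mode(m) <- "integer"
  rownames(m) <- counts_df$gene_id
  lengths <- counts_df$length_bp
  if (any(lengths < 1 | lengths != floor(lengths))) {
    stop2("parse error: ", cfile, " line ",
          which(lengths < 1 | lengths != floor(lengths))[1] + 1L,
          ": length_bp must be a positive integer")
  }

  sfile <- file.path(dir, "samples.tsv")
  samples <- read_tsv(sfile)
  need <- c("sample_id", "genotype", "age_months", "replicate",
            "aversion_index", "abeta42")
  miss <- setdiff(need, names(samples))
  if (length(miss) > 0) {
    stop2("parse error: ", sfile, ": missing columns ",
          paste(miss, collapse = ", "))
  }
  key <- paste(samples$genotype, samples$age_months, samples$replicate)
  if (anyDuplicated(key)) {
    stop2("validation error: ", sfile, " line ",
          which(duplicated(key))[1] + 1L,
          ": duplicated (genotype, age, replicate)")
  }
  if (any(samples$aversion_index < 0 | samples$aversion_index > 1)) {
    stop2("validation error: ", sfile, ": aversion_index outside [0, 1]")
  }
  if (any(samples$abeta42 < 0)) {
    stop2("validation error: ", sfile, ": abeta42 must be >= 0")
  }
  if (!setequal(colnames(m), samples$sample_id) ||
      ncol(m) != nrow(samples)) {
    stop2("validation error: sample ids in ", cfile,
          " do not match ", sfile)
  }
  m <- m[, samples$sample_id, drop = FALSE]

  truth <- NULL
  tfile <- file.path(dir, "truth.tsv")
  if (file.exists(tfile)) {
    genes <- read_tsv(tfile, colClasses = c(active_ages = "character"))
    genes$active_ages[is.na(genes$active_ages)] <- ""
    latent <- read_tsv(file.path(dir, "latent.tsv"))
    truth <- list(genes = genes, latent = latent)
  }

  structure(list(counts = m,
                 lengths = stats::setNames(as.integer(lengths), rownames(m)),
                 samples = samples, truth = truth),
            class = "ad_cohort")
}

#' Generate a synthetic GMT annotation with optional planted enrichment
#'
#' Builds `n_terms` gene sets over the simulated gene universe. A fraction
#' of terms is "planted": their members are drawn preferentially from
#' down-regulated genes (including the signature subset), emulating
#' learning-and-memory style ontology categories that a down-regulated DEG
#' set should recover by over-representation analysis. Remaining terms are
#' uniform draws from all genes.
#'
#' @param truth the `truth` element of an `ad_cohort` (or a compatible list
#'   with a `genes` data frame).
#' @param n_terms number of terms to generate (>= 1).
#' @param enriched_fraction fraction of terms planted as down-enriched.
#' @param seed RNG seed.
#' @param size_range term size interval (uniform integer draw).
#' @param down_weight fraction of a planted term's members drawn from the
#'   down/signature pool.
#' @return a `gmt` data frame with columns `term_id`, `description` and a
#'   list-column `members`.
#' @export
make_annotation <- function(truth, n_terms = 50, enriched_fraction = 0.2,
                            seed = 1, size_range = c(20, 150),
                            down_weight = 0.75) {
  if (!is_count(n_terms, 1)) {
    stop2("configuration error: 'n_terms' must be a positive integer")
  }
  if (!is.numeric(enriched_fraction) || enriched_fraction < 0 ||
      enriched_fraction > 1) {
    stop2("configuration error: 'enriched_fraction' must lie in [0, 1]")
  }
  genes <- truth$genes
  all_ids <- genes$gene_id
  down_ids <- genes$gene_id[genes$status %in% c("down", "signature")]
  set.seed(seed)
  n_enr <- round(enriched_fraction * n_terms)
  if (n_enr > 0 && length(down_ids) == 0) {
    warning("no down/signature genes in truth; planted terms drawn uniformly")
    n_enr <- 0
  }
  sizes <- sample.int(size_range[2] - size_range[1] + 1L, n_terms,
                      replace = TRUE) + size_range[1] - 1L
  sizes <- pmin(sizes, length(all_ids))
  members <- vector("list", n_terms)
  for (t in seq_len(n_terms)) {
    if (t <= n_enr) {
      k_down <- min(round(down_weight * sizes[t]), length(down_ids))
      mem <- c(sample(down_ids, k_down),
               sample(setdiff(all_ids, down_ids), sizes[t] - k_down))
    } else {
      mem <- sample(all_ids, sizes[t])
    }
    members[[t]] <- sort(mem)
  }
  out <- data.frame(
    term_id = sprintf("T%04d", seq_len(n_terms)),
    description = ifelse(seq_len(n_terms) <= n_enr,
                         "planted_down_enriched", "random_background"),
    stringsAsFactors = FALSE
  )
  out$members <- members
  class(out) <- c("gmt", "data.frame")
  out
}
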