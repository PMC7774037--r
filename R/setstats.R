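#' Chi-square test on the overlap of two gene sets
#'
#' Pearson chi-square (df = 1, no continuity correction) on the 2x2
#' membership table of two sets over a common universe.
#'
#' @param setA,setB character vectors, subsets of `universe`.
#' @param universe character vector of all eligible genes.
#' @return a list with the four cell counts (`n_both`, `n_a_only`,
#'   `n_b_only`, `n_neither`), `chi2` and `pvalue`.
#' @export
overlap_chisq <- function(setA, setB, universe) {
  if (length(universe) < 2) stop2("universe must contain at least 2 genes")
  offA <- setdiff(setA, universe)
  offB <- setdiff(setB, universe)
  if (length(offA) + length(offB) > 0) {
    stop2("sets are not subsets of the universe: ",
          paste(utils::head(c(offA, offB), 10), collapse = ", "))
  }
  N <- as.numeric(length(universe))
  inA <- universe %in% setA
  inB <- universe %in% setB
  a <- as.numeric(sum(inA & inB))
  b <- as.numeric(sum(inA & !inB))
  c <- as.numeric(sum(!inA & inB))
  d <- N - a - b - c
  mA <- a + b
  mB <- a + c
  if (mA == 0 || mB == 0 || mA == N || mB == N) {
    stop2("degenerate margin: a set is empty or spans the whole universe")
  }
  chi2 <- N * (a * d - b * c)^2 / (mA * (N - mA) * mB * (N - mB))
  list(n_both = a, n_a_only = b, n_b_only = c, n_neither = d,
       chi2 = chi2, pvalue = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Per-gene absolute Pearson correlation with a phenotype
#'
#' Restricts the expression matrix to one genotype's samples across all
#' ages and correlates each gene's expression with the chosen per-animal
#' phenotype. Genes with zero expression variance within the subset have an
#' undefined correlation; they are flagged and excluded from downstream set
#' means.
#'
#' @param expr expression matrix (genes x samples), e.g. logCPM or RPKM.
#' @param samples the cohort sample data frame.
#' @param genotype `"WT"` or `"AD"`.
#' @param phenotype `"aversion_index"` or `"abeta42"`.
#' @return a data frame (`gene_id`, `abs_r`, `defined`) with attributes
#'   `genotype`, `phenotype`, `n_samples`, `n_undefined`.
#' @export
gene_phenotype_abscorr <- function(expr, samples, genotype,
                                   phenotype = c("aversion_index", "abeta42")) {
  phenotype <- match.arg(phenotype)
  sel <- samples$genotype == genotype
  if (sum(sel) < 3) stop2("need at least 3 samples of genotype ", genotype)
  ids <- samples$sample_id[sel]
  if (!all(ids %in% colnames(expr))) {
    stop2("expression matrix lacks samples: ",
          paste(setdiff(ids, colnames(expr)), collapse = ", "))
  }
  ph <- samples[[phenotype]][sel]
  if (stats::sd(ph) == 0) {
    stop2("phenotype ", phenotype, " is constant across ", genotype,
          " samples")
  }
  sub <- expr[, ids, drop = FALSE]
  defined <- row_var(sub) > 0
  r <- rep(NA_real_, nrow(sub))
  r[defined] <- as.vector(stats::cor(t(sub[defined, , drop = FALSE]), ph))
  out <- data.frame(gene_id = rownames(expr), abs_r = abs(r),
                    defined = defined, stringsAsFactors = FALSE)
  attr(out, "genotype") <- genotype
  attr(out, "phenotype") <- phenotype
  attr(out, "n_samples") <- length(ids)
  attr(out, "n_undefined") <- sum(!defined)
  out
}

#' Competitive randomization test for a gene set's phenotype association
#'
#' Compares the mean absolute correlation of a gene set with the means of
#' equally sized random samples of background genes (sampled uniformly
#' without replacement). Significance follows the exceed-max rule: the
#' association is flagged when the observed mean is strictly greater than
#' the largest null mean, so the smallest attainable empirical p-value is
#' `1/(B + 1)` (`p < 0.001` at the conventional `B = 1000`). Genes with an
#' undefined correlation are removed from both the set and the background
#' before testing.
#'
#' @param abscorr per-gene table from [gene_phenotype_abscorr()].
#' @param geneset character vector of set members (>= 2 after removal of
#'   undefined genes).
#' @param background character vector of background genes (larger than the
#'   set; by convention it may include the set's members).
#' @param B number of random draws (default 1000).
#' @param seed RNG seed for the draws.
#' @param exhaustive when `TRUE`, enumerate all subsets of the background
#'   of the set's size instead of sampling; only feasible for small
#'   backgrounds (`choose(n, k) <= 2e5`). The empirical p-value is then the
#'   exact fraction of subsets whose mean is at least the observed one.
#' @return a one-row data frame: `n_set`, `mean_abs_r`, `null_mean`,
#'   `null_sd`, `z`, `empirical_p`, `exceeds_max`, `degenerate`, `B`,
#'   `seed`, `mode`.
#' @export
set_association_test <- function(abscorr, geneset, background, B = 1000,
                                 seed = 1, exhaustive = FALSE) {
  r <- stats::setNames(abscorr$abs_r, abscorr$gene_id)
  ok <- abscorr$gene_id[abscorr$defined]
  geneset <- intersect(geneset, ok)
  background <- intersect(background, ok)
  if (length(geneset) < 2) {
    stop2("gene set needs at least 2 genes with defined correlations")
  }
  if (length(geneset) >= length(background)) {
    stop2("background must be larger than the gene set")
  }
  k <- length(geneset)
  observed <- mean(r[geneset])
  tol <- 1e-12

  if (exhaustive) {
    n_sub <- choose(length(background), k)
    if (n_sub > 2e5) {
      stop2("exhaustive mode infeasible: choose(", length(background), ", ",
            k, ") = ", n_sub, " subsets")
    }
    idx <- utils::combn(length(background), k)
    rb <- r[background]
    null_means <- colMeans(matrix(rb[idx], nrow = k))
    emp_p <- sum(null_means >= observed - tol) / n_sub
    B_used <- as.integer(n_sub)
    mode <- "exhaustive"
  } else {
    set.seed(seed)
    rb <- r[background]
    nb <- length(background)
    null_means <- vapply(seq_len(B), function(b) {
      mean(rb[sample.int(nb, k)])
    }, numeric(1))
    emp_p <- (1 + sum(null_means >= observed - tol)) / (B + 1)
    B_used <- as.integer(B)
    mode <- "monte_carlo"
  }

  null_mean <- mean(null_means)
  null_sd <- stats::sd(null_means)
  degenerate <- !is.finite(null_sd) || null_sd < 1e-15
  z <- if (degenerate) 0 else (observed - null_mean) / null_sd
  data.frame(n_set = k, mean_abs_r = observed, null_mean = null_mean,
             null_sd = if (degenerate) 0 else null_sd, z = z,
             empirical_p = emp_p,
             exceeds_max = observed > max(null_means),
             degenerate = degenerate, B = B_used, seed = seed,
             mode = mode, stringsAsFactors = FALSE)
}

#' Association grid over genotypes, phenotypes and pooled DEG sets
#'
#' Runs [set_association_test()] for every combination of genotype
#' (`WT`, `AD`), phenotype (`aversion_index`, `abeta42`) and pooled set
#' (`all`, `up`, `down`), on TMM-normalized logCPM by default (RPKM mode is
#' available for cohorts imported at the RPKM scale). Each cell uses a
#' deterministic seed derived from the master seed and the cell labels.
#'
#' @param cohort an `ad_cohort` (counts) or `rpkm_cohort` (imported RPKM).
#' @param sets a `deg_sets` object from [pool_degs()] (or a named list of
#'   gene-id vectors).
#' @param B random draws per cell (default 1000).
#' @param seed master seed.
#' @param scale `"logCPM"` (default; requires counts) or `"RPKM"`.
#' @param genes optional filtered gene universe; by default computed with
#'   [filter_genes()].
#' @param exclude_set when `TRUE`, the tested set's members are removed
#'   from the background (default `FALSE`: the background is all filtered
#'   genes).
#' @return a tidy data frame, one row per (set, genotype, phenotype) cell.
#' @export
signature_grid <- function(cohort, sets, B = 1000, seed = 1,
                           scale = c("logCPM", "RPKM"), genes = NULL,
                           exclude_set = FALSE) {
  scale <- match.arg(scale)
  if (is.null(genes)) {
    rpkm <- if (inherits(cohort, "rpkm_cohort")) cohort$expr
            else compute_rpkm(cohort$counts, cohort$lengths)
    genes <- filter_genes(rpkm)$kept
  }
  expr <- cohort_expression(cohort, scale, genes)
  samples <- cohort$samples
  set_labels <- intersect(c("all", "up", "down"), names(sets))
  rows <- list()
  for (genotype in c("WT", "AD")) {
    for (phenotype in c("aversion_index", "abeta42")) {
      ac <- gene_phenotype_abscorr(expr, samples, genotype, phenotype)
      for (lab in set_labels) {
        gs <- intersect(sets[[lab]], genes)
        bg <- if (exclude_set) setdiff(genes, gs) else genes
        cell_seed <- derive_seed(seed, genotype, phenotype, lab)
        res <- set_association_test(ac, gs, bg, B = B, seed = cell_seed)
        rows[[length(rows) + 1L]] <-
          cbind(data.frame(set_label = lab, genotype = genotype,
                           phenotype = phenotype, stringsAsFactors = FALSE),
                res)
      }
    }
  }
  do.call(rbind, rows)
}

# Expression matrix of a cohort on the requested scale, restricted to the
# given gene universe (all genes when NULL).
cohort_expression <- function(cohort, scale, genes = NULL) {
  if (inherits(cohort, "rpkm_cohort")) {
    if (scale != "RPKM") {
      stop2("imported RPKM cohorts only support scale = \"RPKM\"")
    }
    expr <- cohort$expr
    if (!is.null(genes)) expr <- expr[genes, , drop = FALSE]
    return(expr)
  }
  stopifnot(inherits(cohort, "ad_cohort"))
  if (scale == "RPKM") {
    rpkm <- compute_rpkm(cohort$counts, cohort$lengths)
    if (!is.null(genes)) rpkm <- rpkm[genes, , drop = FALSE]
    rpkm
  } else {
    if (is.null(genes)) {
      genes <- filter_genes(compute_rpkm(cohort$counts, cohort$lengths))$kept
    }
    nf <- tmm_factors(cohort$counts, kept_genes = genes)
    log_expression(cohort$counts[genes, , drop = FALSE], nf)
  }
}
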