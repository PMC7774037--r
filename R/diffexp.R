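#' Map counts to pseudo-counts at a common library size
#'
#' Equalizes library sizes ahead of the conditional exact test: the common
#' size is the geometric mean of the effective library sizes and each
#' sample's counts are scaled by `common / N_j` (moderated scaling; see the
#' methods vignette for why the re-estimation iterations of the full
#' quantile-matching recursion reduce to plain scaling here).
#'
#' @param countsA,countsB count matrices for the two groups (same genes).
#' @param libsizes effective library sizes, length `ncol(A) + ncol(B)`,
#'   ordered as `c(A, B)`.
#' @return list with `pseudoA`, `pseudoB` (non-negative real matrices) and
#'   `common_libsize`.
#' @export
quantile_adjust <- function(countsA, countsB, libsizes) {
  nA <- ncol(countsA)
  nB <- ncol(countsB)
  if (nA < 1 || nB < 1) stop2("each group needs at least one sample")
  if (length(libsizes) != nA + nB) {
    stop2("libsizes must have one entry per sample")
  }
  if (any(libsizes <= 0)) {
    stop2("zero effective library size for sample(s): ",
          paste(which(libsizes <= 0), collapse = ", "))
  }
  common <- exp(mean(log(libsizes)))
  list(pseudoA = sweep(countsA, 2, common / libsizes[seq_len(nA)], "*"),
       pseudoB = sweep(countsB, 2, common / libsizes[nA + seq_len(nB)], "*"),
       common_libsize = common)
}

# Summed conditional log-likelihood of within-group pseudo-counts given the
# group totals, as a function of delta = phi / (1 + phi) (qCML).
cond_loglik <- function(y_list, delta) {
  r <- (1 - delta) / delta
  ll <- 0
  for (y in y_list) {
    n <- ncol(y)
    z <- rowSums(y)
    ll <- ll + sum(rowSums(lgamma(y + r)) - n * lgamma(r) +
                     lgamma(n * r) - lgamma(z + n * r))
  }
  ll
}

golden_section_max <- function(f, lo, hi, tol = 1e-6) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - gr * (b - a)
  x2 <- a + gr * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  while (b - a > tol) {
    if (f1 < f2) {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- f(x2)
    } else {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- f(x1)
    }
  }
  (a + b) / 2
}

#' Common negative-binomial dispersion by conditional maximum likelihood
#'
#' Maximizes the summed conditional log-likelihood of within-group
#' pseudo-counts given group totals over `delta = phi/(1+phi)` in
#' `[0, 0.999]` by golden-section search (tolerance 1e-6). A maximum at the
#' lower boundary is reported as the Poisson limit `phi = 0`.
#'
#' @param pseudoA,pseudoB pseudo-count matrices from [quantile_adjust()].
#' @param pseudo_libsize common library size (recorded in the result).
#' @param tol golden-section tolerance on delta.
#' @return an object of class `dispersion_estimate`: list with `phi`,
#'   `method` (`"qcml"` or `"poisson"`) and `pseudo_libsize`.
#' @export
estimate_common_dispersion <- function(pseudoA, pseudoB,
                                       pseudo_libsize = NA_real_,
                                       tol = 1e-6) {
  if (ncol(pseudoA) + ncol(pseudoB) < 2) stop2("need at least 2 samples")
  if (all(pseudoA == 0) && all(pseudoB == 0)) {
    stop2("all-zero matrix: cannot estimate dispersion")
  }
  # Groups with a single sample carry no conditional information.
  y_list <- Filter(function(y) ncol(y) >= 2, list(pseudoA, pseudoB))
  if (length(y_list) == 0) stop2("need a group with >= 2 samples")
  f <- function(delta) cond_loglik(y_list, max(delta, 1e-8))
  delta_hat <- golden_section_max(f, 0, 0.999, tol = tol)
  if (delta_hat <= tol * 2 || f(delta_hat) <= f(1e-8) + 1e-10) {
    return(structure(list(phi = 0, method = "poisson",
                          pseudo_libsize = pseudo_libsize),
                     class = "dispersion_estimate"))
  }
  structure(list(phi = delta_hat / (1 - delta_hat), method = "qcml",
                 pseudo_libsize = pseudo_libsize),
            class = "dispersion_estimate")
}

#' @export
print.dispersion_estimate <- function(x, ...) {
  cat("common NB dispersion phi =", format(x$phi, digits = 4),
      paste0("(", x$method, ")\n"))
  invisible(x)
}

# Conditional pmf of the group-A sum given the total, under H0.
nb_exact_pmf <- function(total, nA, nB, phi) {
  a <- 0:total
  muA <- total * nA / (nA + nB)
  muB <- total * nB / (nA + nB)
  if (phi <= 0) {
    lp <- stats::dbinom(a, total, nA / (nA + nB), log = TRUE)
  } else {
    lp <- stats::dnbinom(a, size = nA / phi, mu = muA, log = TRUE) +
      stats::dnbinom(total - a, size = nB / phi, mu = muB, log = TRUE)
  }
  lp <- lp - max(lp)
  p <- exp(lp)
  p / sum(p)
}

#' Two-group negative-binomial exact test on group sums
#'
#' Conditional on the total `T = sumA + sumB`, the two-sided p-value is the
#' sum of the probabilities of all splits no more likely than the observed
#' one: `p = sum over {a : P(a) <= P(obs)} of P(a)`, with
#' `P(a) proportional to NB_A(a) * NB_B(T - a)`, where the group sums have
#' means proportional to `nA`, `nB` and dispersions `phi/nA`, `phi/nB`.
#' Splits with `P(a)` equal to `P(obs)` within 1e-12 are included. At
#' `phi = 0` this is the Poisson limit (an exact binomial test).
#'
#' @param sumA,sumB group pseudo-count totals (rounded to integers).
#' @param nA,nB number of samples per group.
#' @param phi common NB dispersion.
#' @return two-sided p-value in `[0, 1]`; `T = 0` returns 1 by convention.
#' @export
nb_exact_test <- function(sumA, nA, sumB, nB, phi) {
  if (nA < 1 || nB < 1) stop2("each group needs at least one sample")
  if (sumA < 0 || sumB < 0) stop2("group sums must be non-negative")
  sA <- round(sumA)
  total <- round(sumA) + round(sumB)
  if (total == 0) return(1)
  p <- nb_exact_pmf(total, nA, nB, phi)
  p_obs <- p[sA + 1]
  min(1, sum(p[p <= p_obs * (1 + 1e-12)]))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_(i) = min over {j >= i} of (p_(j) * m / j)`, clamped at 1; the result
#' is invariant under permutations of the input order.
#'
#' @param pvalues vector of p-values in `[0, 1]`.
#' @return adjusted values in the original order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    stop2("p-values must lie in [0, 1]")
  }
  m <- length(pvalues)
  o <- order(pvalues, decreasing = TRUE)
  q <- pmin(1, cummin(pvalues[o] * m / (m:1)))
  q[order(o)]
}

#' Per-age two-group differential expression
#'
#' Runs the full exact-test pipeline at one age: TMM factors on the age
#' subset, pseudo-counts at the common library size, common-dispersion
#' estimation by conditional maximum likelihood, a per-gene exact test on
#' the group sums, and Benjamini-Hochberg adjustment across genes.
#' `log2fc` is `log2((mean AD pseudo-count + prior) /
#' (mean WT pseudo-count + prior))`, i.e. positive = higher in `AD`.
#'
#' @param cohort an `ad_cohort` object.
#' @param age one of the cohort's ages.
#' @param alpha FDR threshold used for the `significant` flag (default
#'   0.05).
#' @param genes gene ids to test; by default, the cohort-wide
#'   [filter_genes()] selection.
#' @param dispersion optional fixed dispersion; when `NULL` (default) the
#'   common dispersion is estimated from the data.
#' @param prior pseudo-count used in the fold-change (default 0.5).
#' @return a data frame with one row per tested gene (`gene_id`,
#'   `age_months`, `log2fc`, `pvalue`, `fdr`, `direction`, `significant`),
#'   with the estimated dispersion in `attr(, "phi")`.
#' @export
run_de <- function(cohort, age, alpha = 0.05, genes = NULL,
                   dispersion = NULL, prior = 0.5) {
  stopifnot(inherits(cohort, "ad_cohort"))
  sel <- cohort$samples$age_months == age
  if (!any(sel)) stop2("no samples at age ", age)
  sub <- cohort$samples[sel, ]
  wt <- sub$sample_id[sub$genotype == "WT"]
  ad <- sub$sample_id[sub$genotype == "AD"]
  if (length(wt) == 0 || length(ad) == 0) {
    stop2("missing genotype at age ", age, ": need both WT and AD samples")
  }
  if (is.null(genes)) {
    rpkm <- compute_rpkm(cohort$counts, cohort$lengths)
    genes <- filter_genes(rpkm)$kept
  }
  counts <- cohort$counts[genes, c(wt, ad), drop = FALSE]
  nf <- tmm_factors(counts)
  eff <- nf$effective_libsize
  qa <- quantile_adjust(counts[, wt, drop = FALSE],
                        counts[, ad, drop = FALSE], eff)
  if (is.null(dispersion)) {
    disp <- estimate_common_dispersion(qa$pseudoA, qa$pseudoB,
                                       pseudo_libsize = qa$common_libsize)
    phi <- disp$phi
  } else {
    phi <- dispersion
    disp <- structure(list(phi = phi, method = "fixed",
                           pseudo_libsize = qa$common_libsize),
                      class = "dispersion_estimate")
  }
  sum_wt <- rowSums(qa$pseudoA)
  sum_ad <- rowSums(qa$pseudoB)
  pv <- vapply(seq_along(genes), function(i) {
    nb_exact_test(sum_wt[i], length(wt), sum_ad[i], length(ad), phi)
  }, numeric(1))
  log2fc <- log2((rowMeans(qa$pseudoB) + prior) /
                   (rowMeans(qa$pseudoA) + prior))
  fdr <- bh_adjust(pv)
  out <- data.frame(gene_id = genes,
                    age_months = age,
                    log2fc = log2fc,
                    pvalue = pv,
                    fdr = fdr,
                    direction = ifelse(log2fc > 0, "up", "down"),
                    significant = fdr < alpha,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "phi") <- phi
  attr(out, "dispersion") <- disp
  attr(out, "alpha") <- alpha
  out
}

#' Pool directional DEG sets across ages
#'
#' `up` is the union of genes ever significantly up-regulated, `down` the
#' union of genes ever significantly down-regulated, and `all` their union.
#' A gene with opposite directions at different ages belongs to both `up`
#' and `down` but appears once in `all` (so `|up| + |down|` can exceed
#' `|all|`).
#'
#' @param de_list list of per-age data frames from [run_de()].
#' @return an object of class `deg_sets`: list with character vectors
#'   `all`, `up`, `down`.
#' @export
pool_degs <- function(de_list) {
  if (length(de_list) == 0) stop2("need at least one analyzed age")
  up <- character(0)
  down <- character(0)
  for (de in de_list) {
    sig <- de[de$significant, , drop = FALSE]
    up <- union(up, sig$gene_id[sig$direction == "up"])
    down <- union(down, sig$gene_id[sig$direction == "down"])
  }
  structure(list(all = union(up, down), up = up, down = down),
            class = "deg_sets")
}

#' @export
print.deg_sets <- function(x, ...) {
  cat("pooled DEG sets: all", length(x$all), "| up", length(x$up),
      "| down", length(x$down), "\n")
  invisible(x)
}
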