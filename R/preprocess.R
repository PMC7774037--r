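#' Reads-per-kilobase-per-million (RPKM) expression values
#'
#' `RPKM[i, j] = counts[i, j] * 1e9 / (length_bp[i] * colsum[j])`.
#'
#' @param counts integer count matrix, genes x samples, with rownames.
#' @param lengths gene lengths in bp, recycled/matched by name when named.
#' @return a numeric matrix with attribute `scale = "RPKM"`.
#' @export
compute_rpkm <- function(counts, lengths) {
  if (is.null(dim(counts)) || nrow(counts) == 0 || ncol(counts) == 0) {
    stop2("empty count matrix")
  }
  if (!is.null(names(lengths)) && !is.null(rownames(counts))) {
    lengths <- lengths[rownames(counts)]
  }
  if (length(lengths) != nrow(counts) || anyNA(lengths)) {
    stop2("gene lengths do not align with the count matrix")
  }
  if (any(lengths < 1)) stop2("gene lengths must be >= 1 bp")
  cs <- colSums(counts)
  if (any(cs <= 0)) {
    stop2("zero column sum for sample(s): ",
          paste(colnames(counts)[cs <= 0], collapse = ", "))
  }
  rpkm <- counts * 1e9 / (as.numeric(lengths) %o% cs)
  dimnames(rpkm) <- dimnames(counts)
  attr(rpkm, "scale") <- "RPKM"
  rpkm
}

#' Filter genes on zero variance and cumulative RPKM
#'
#' Drops genes whose RPKM is exactly constant across all samples, then genes
#' whose RPKM summed over all samples is strictly less than `min_total`.
#' A gene failing both rules is counted once, attributed to the
#' zero-variance rule.
#'
#' @param rpkm RPKM matrix from [compute_rpkm()].
#' @param min_total strict cumulative-RPKM threshold (default 5).
#' @return a list with `kept` (gene ids), `dropped_zero_variance`,
#'   `dropped_low_expression` (counts) and `report` (per-rule summary).
#' @export
filter_genes <- function(rpkm, min_total = 5) {
  if (is.null(dim(rpkm)) || nrow(rpkm) == 0 || ncol(rpkm) == 0) {
    stop2("empty expression matrix")
  }
  zero_var <- row_var(rpkm) == 0
  low <- rowSums(rpkm) < min_total
  drop_low <- low & !zero_var
  kept <- rownames(rpkm)[!(zero_var | drop_low)]
  list(kept = kept,
       dropped_zero_variance = sum(zero_var),
       dropped_low_expression = sum(drop_low),
       report = data.frame(rule = c("zero_variance", "low_expression", "kept"),
                           n = c(sum(zero_var), sum(drop_low), length(kept))))
}

#' Trimmed-mean-of-M-values (TMM) normalization factors
#'
#' For each sample `s` against the reference `r`, per-gene log-ratios
#' `M = log2((c_s/N_s)/(c_r/N_r))` and average log-abundances
#' `A = (1/2) log2((c_s/N_s)(c_r/N_r))` are computed over genes with
#' positive counts in both samples; the top and bottom `trim_m` fraction by
#' M and `trim_a` fraction by A are discarded, and the factor is
#' `2^weighted mean(M)` with inverse asymptotic binomial variance weights
#' `1 / ((N_s - c_s)/(N_s c_s) + (N_r - c_r)/(N_r c_r))`. Factors are
#' renormalized to unit product. When `ref_sample` is missing, the
#' reference is the sample whose upper-quartile CPM is closest to the mean
#' upper quartile.
#'
#' @param counts count matrix, genes x samples.
#' @param kept_genes optional gene ids to use (e.g. from [filter_genes()]).
#' @param ref_sample optional reference sample id or column index.
#' @param trim_m,trim_a trim fractions for M and A (defaults 0.30 / 0.05).
#' @return an object of class `tmm_factors`: list with `factors` (named,
#'   product 1), `libsize` (column sums over used genes),
#'   `effective_libsize` (`libsize * factors`), `ref_sample`, and a
#'   `diagnostics` data frame with the per-sample trimmed M mean and
#'   weight sum.
#' @export
tmm_factors <- function(counts, kept_genes = NULL, ref_sample = NULL,
                        trim_m = 0.30, trim_a = 0.05) {
  if (ncol(counts) < 2) stop2("TMM needs at least 2 samples")
  if (!is.null(kept_genes)) {
    counts <- counts[kept_genes, , drop = FALSE]
  }
  N <- colSums(counts)
  if (any(N <= 0)) {
    stop2("zero library size for sample(s): ",
          paste(colnames(counts)[N <= 0], collapse = ", "))
  }
  cpm <- sweep(counts, 2, N, "/") * 1e6
  uq <- apply(cpm, 2, stats::quantile, probs = 0.75, names = FALSE)
  if (is.null(ref_sample)) {
    r <- which.min(abs(uq - mean(uq)))
  } else {
    r <- if (is.character(ref_sample)) match(ref_sample, colnames(counts)) else ref_sample
    if (is.na(r) || r < 1 || r > ncol(counts)) stop2("unknown ref_sample")
  }

  f <- numeric(ncol(counts))
  diag_m <- numeric(ncol(counts))
  diag_w <- numeric(ncol(counts))
  for (s in seq_len(ncol(counts))) {
    cs <- counts[, s]
    cr <- counts[, r]
    pos <- cs > 0 & cr > 0
    if (!any(pos)) {
      stop2("sample ", colnames(counts)[s] %||% s,
            " shares no positive genes with the reference")
    }
    ps <- cs[pos] / N[s]
    pr <- cr[pos] / N[r]
    M <- log2(ps / pr)
    A <- 0.5 * log2(ps * pr)
    w <- 1 / ((N[s] - cs[pos]) / (N[s] * cs[pos]) +
                (N[r] - cr[pos]) / (N[r] * cr[pos]))
    n <- length(M)
    cut_m <- floor(trim_m * n)
    cut_a <- floor(trim_a * n)
    rm_rank <- rank(M, ties.method = "first")
    ra_rank <- rank(A, ties.method = "first")
    keep <- rm_rank > cut_m & rm_rank <= n - cut_m &
      ra_rank > cut_a & ra_rank <= n - cut_a
    if (!any(keep) || all(!is.finite(w[keep]))) {
      f[s] <- 1
      diag_m[s] <- 0
      diag_w[s] <- 0
      next
    }
    diag_m[s] <- sum(M[keep] * w[keep]) / sum(w[keep])
    diag_w[s] <- sum(w[keep])
    f[s] <- 2^diag_m[s]
  }
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  structure(list(factors = f,
                 libsize = N,
                 effective_libsize = N * f,
                 ref_sample = colnames(counts)[r] %||% r,
                 diagnostics = data.frame(sample_id = colnames(counts),
                                          trimmed_m_mean = diag_m,
                                          weight_sum = diag_w)),
            class = "tmm_factors")
}

#' @export
print.tmm_factors <- function(x, ...) {
  cat("tmm_factors (ref:", x$ref_sample, ")\n")
  print(round(x$factors, 4))
  invisible(x)
}

#' Log2 counts-per-million on TMM effective library sizes
#'
#' `logCPM[i, j] = log2((counts[i, j] + prior) /
#' (effective_libsize[j] + 2 * prior) * 1e6)`.
#'
#' @param counts count matrix (restricted to the genes used for `nf`).
#' @param nf a [tmm_factors()] object (or a vector of effective library
#'   sizes).
#' @param prior pseudo-count (default 0.5).
#' @return a numeric matrix with attribute `scale = "logCPM"`.
#' @export
log_expression <- function(counts, nf, prior = 0.5) {
  eff <- if (inherits(nf, "tmm_factors")) nf$effective_libsize else nf
  if (length(eff) != ncol(counts)) {
    stop2("effective library sizes do not align with the count matrix")
  }
  out <- log2(sweep(counts + prior, 2, eff + 2 * prior, "/") * 1e6)
  dimnames(out) <- dimnames(counts)
  attr(out, "scale") <- "logCPM"
  out
}

#' Classical MDS sample ordination on leading log-fold-change distances
#'
#' The distance between two samples is the root-mean-square of the
#' `top_genes` largest absolute gene-wise logCPM differences (the standard
#' "leading log fold change" distance for TMM-normalized counts). The
#' embedding is classical (Torgerson) MDS: double-centering of squared
#' distances followed by eigendecomposition. Each axis is oriented so its
#' first nonzero loading is positive.
#'
#' @param logcpm logCPM matrix from [log_expression()].
#' @param top_genes number of leading genes per pair (default 500).
#' @param dims embedding dimension (default 2; must be < number of samples).
#' @return a list with `points` (samples x dims), `eig` (all eigenvalues)
#'   and `dist` (the pairwise distance matrix).
#' @export
mds_coordinates <- function(logcpm, top_genes = 500, dims = 2) {
  n <- ncol(logcpm)
  if (n < 3) stop2("MDS needs at least 3 samples")
  if (dims >= n) stop2("dims must be smaller than the number of samples")
  k <- min(top_genes, nrow(logcpm))
  D <- matrix(0, n, n, dimnames = list(colnames(logcpm), colnames(logcpm)))
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      d2 <- (logcpm[, s] - logcpm[, t])^2
      D[s, t] <- D[t, s] <- sqrt(mean(sort(d2, decreasing = TRUE)[seq_len(k)]))
    }
  }
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% D^2 %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  lam <- pmax(e$values[seq_len(dims)], 0)
  pts <- e$vectors[, seq_len(dims), drop = FALSE] %*% diag(sqrt(lam), dims)
  for (d in seq_len(dims)) {
    nz <- which(abs(pts[, d]) > 1e-12)
    if (length(nz) > 0 && pts[nz[1], d] < 0) pts[, d] <- -pts[, d]
  }
  rownames(pts) <- colnames(logcpm)
  colnames(pts) <- paste0("dim", seq_len(dims))
  list(points = pts, eig = e$values, dist = D)
}
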