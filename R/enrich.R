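#' Read a GMT annotation file
#'
#' Standard tab-delimited GMT: one term per line with fields
#' `term`, `description`, then member gene ids.
#'
#' @param path path to a GMT file.
#' @return a `gmt` data frame with columns `term_id`, `description` and a
#'   list-column `members`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop2("parse error: file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short) > 0) {
    stop2("parse error: ", path, " line ", short[1],
          ": a GMT line needs term, description and at least one member")
  }
  out <- data.frame(term_id = vapply(fields, `[`, character(1), 1),
                    description = vapply(fields, `[`, character(1), 2),
                    stringsAsFactors = FALSE)
  out$members <- lapply(fields, function(f) unique(f[-(1:2)]))
  class(out) <- c("gmt", "data.frame")
  out
}

#' Write a GMT annotation file
#'
#' @param gmt a `gmt` data frame (see [read_gmt()] / [make_annotation()]).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_gmt <- function(gmt, path) {
  lines <- vapply(seq_len(nrow(gmt)), function(i) {
    paste(c(gmt$term_id[i], gmt$description[i], gmt$members[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Hypergeometric over-representation analysis
#'
#' For each annotation term (intersected with the universe and filtered to
#' sizes in `[min_term, max_term]`), tests over-representation of the gene
#' set with the hypergeometric upper tail `P(X >= k)` where `X ~
#' Hypergeometric(N, K, n_set)`, then applies Benjamini-Hochberg across
#' retained terms.
#'
#' @param geneset character vector, a subset of `universe`.
#' @param gmt a `gmt` data frame.
#' @param universe character vector of eligible genes.
#' @param min_term,max_term in-universe term-size bounds (defaults 5 and
#'   2000).
#' @return a data frame sorted by p-value with columns `term_id`,
#'   `term_name`, `k`, `n_set`, `K`, `N`, `pvalue`, `qvalue`.
#' @export
ora <- function(geneset, gmt, universe, min_term = 5, max_term = 2000) {
  if (length(universe) == 0) stop2("empty universe")
  if (length(geneset) == 0) stop2("empty gene set")
  off <- setdiff(geneset, universe)
  if (length(off) > 0) {
    stop2("gene set not contained in the universe: ",
          paste(utils::head(off, 10), collapse = ", "))
  }
  N <- length(universe)
  n_set <- length(geneset)
  members <- lapply(gmt$members, intersect, y = universe)
  K <- lengths(members)
  keep <- K >= min_term & K <= max_term
  if (!any(keep)) {
    warning("no annotation terms retained after size filtering")
    return(data.frame(term_id = character(0), term_name = character(0),
                      k = integer(0), n_set = integer(0), K = integer(0),
                      N = integer(0), pvalue = numeric(0),
                      qvalue = numeric(0), stringsAsFactors = FALSE))
  }
  k <- vapply(members[keep], function(m) length(intersect(m, geneset)),
              integer(1))
  pv <- stats::phyper(k - 1, K[keep], N - K[keep], n_set, lower.tail = FALSE)
  out <- data.frame(term_id = gmt$term_id[keep],
                    term_name = gmt$description[keep],
                    k = k, n_set = n_set, K = K[keep], N = N,
                    pvalue = pv, qvalue = bh_adjust(pv),
                    stringsAsFactors = FALSE)
  out <- out[order(out$pvalue, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Over-representation reports for up- and down-regulated sets
#'
#' Runs [ora()] separately on the pooled up and down sets and tabulates
#' `-log10(q)` per term per set (the usual bar-chart quantity).
#'
#' @param up,down character vectors of pooled directional DEGs.
#' @param gmt a `gmt` data frame.
#' @param universe character vector of eligible genes.
#' @inheritParams ora
#' @return a list with `up`, `down` (full [ora()] tables) and `comparison`
#'   (term x set table of `-log10(qvalue)`).
#' @export
enrichment_report <- function(up, down, gmt, universe, min_term = 5,
                              max_term = 2000) {
  res_up <- ora(up, gmt, universe, min_term, max_term)
  res_down <- ora(down, gmt, universe, min_term, max_term)
  terms <- union(res_up$term_id, res_down$term_id)
  comparison <- data.frame(
    term_id = terms,
    neglog10_q_up = -log10(res_up$qvalue[match(terms, res_up$term_id)]),
    neglog10_q_down = -log10(res_down$qvalue[match(terms, res_down$term_id)]),
    stringsAsFactors = FALSE
  )
  list(up = res_up, down = res_down, comparison = comparison)
}
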