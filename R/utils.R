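# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == floor(x) && x >= min
}

#' @keywords internal
assert_numeric_range <- function(x, field, lo = -Inf, hi = Inf, len = NULL) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop2("configuration error: '", field, "' must be finite numeric")
  }
  if (!is.null(len) && length(x) != len) {
    stop2("configuration error: '", field, "' must have length ", len)
  }
  if (any(x < lo) || any(x > hi)) {
    stop2("configuration error: '", field, "' must lie in [", lo, ", ", hi, "]")
  }
  invisible(x)
}

# Deterministic 31-bit seed derived from a master seed plus string labels.
# Used so that every cell of a result grid gets its own reproducible stream.
derive_seed <- function(seed, ...) {
  labels <- paste(c(seed, ...), collapse = "|")
  h <- as.double(seed %% 2147483647L)
  for (code in utf8ToInt(labels)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h %% 2147483646 + 1)
}

# Full-precision decimal formatting so numeric TSV columns round-trip exactly.
format_full <- function(x) {
  out <- formatC(x, digits = 17, format = "g")
  gsub(" ", "", out, fixed = TRUE)
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  out <- df
  out[num] <- lapply(df[num], format_full)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, colClasses = NA) {
  if (!file.exists(path)) stop2("parse error: file not found: ", path)
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    colClasses = colClasses, check.names = FALSE)
}

row_var <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1)
}
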