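#' Pipeline configuration
#'
#' Collects every stage parameter with defaults equal to the module-level
#' defaults. Unknown arguments are rejected before any computation.
#'
#' @param out_dir output directory for stage TSVs and the run summary.
#' @param input_dir cohort directory (read with [read_cohort()]) when
#'   `simulate = FALSE`.
#' @param simulate generate a synthetic cohort (default `TRUE`).
#' @param sim named list of overrides passed to [sim_config()].
#' @param gmt_file optional GMT annotation path for the enrichment stage;
#'   when `NULL` and simulating, an annotation is generated from the truth
#'   with [make_annotation()] if `annotate_from_truth` is `TRUE`.
#' @param annotate_from_truth see `gmt_file` (default `TRUE`).
#' @param filter_min_rpkm cumulative-RPKM filter threshold (default 5).
#' @param alpha DE significance threshold on the FDR (default 0.05).
#' @param prior pseudo-count for fold changes and logCPM (default 0.5).
#' @param B randomization draws per association cell (default 1000).
#' @param scale correlation scale, `"logCPM"` or `"RPKM"`.
#' @param exclude_set drop tested-set members from the background
#'   (default `FALSE`).
#' @param min_term,max_term ORA term-size bounds (defaults 5 / 2000).
#' @param top_genes,mds_dims MDS parameters (defaults 500 / 2).
#' @param seed master seed; every stage seed derives from it.
#' @param verbose log stage progress to standard error (default `TRUE`).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("adsig_run_"),
                            input_dir = NULL,
                            simulate = TRUE,
                            sim = list(),
                            gmt_file = NULL,
                            annotate_from_truth = TRUE,
                            filter_min_rpkm = 5,
                            alpha = 0.05,
                            prior = 0.5,
                            B = 1000,
                            scale = "logCPM",
                            exclude_set = FALSE,
                            min_term = 5,
                            max_term = 2000,
                            top_genes = 500,
                            mds_dims = 2,
                            seed = 1,
                            verbose = TRUE) {
  cfg <- as.list(environment())
  if (!is.list(cfg$sim)) stop2("configuration error: 'sim' must be a list")
  known_sim <- names(formals(sim_config))
  unknown <- setdiff(names(cfg$sim), known_sim)
  if (length(unknown) > 0) {
    stop2("configuration error: unknown sim key(s): ",
          paste(unknown, collapse = ", "))
  }
  if (!cfg$scale %in% c("logCPM", "RPKM")) {
    stop2("configuration error: 'scale' must be logCPM or RPKM")
  }
  assert_numeric_range(cfg$alpha, "alpha", 0, 1, len = 1)
  assert_numeric_range(cfg$filter_min_rpkm, "filter_min_rpkm", lo = 0, len = 1)
  if (!is_count(cfg$B, 1)) stop2("configuration error: 'B' must be >= 1")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Build a pipeline configuration from a named list, rejecting unknown keys
#'
#' @param x named list (e.g. parsed from a JSON/YAML-like config file).
#' @return a `pipeline_config`.
#' @export
pipeline_config_from_list <- function(x) {
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(x), known)
  if (length(unknown) > 0) {
    stop2("configuration error: unknown key(s): ",
          paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, x)
}

log_stage <- function(verbose, ...) {
  if (verbose) message(format(Sys.time(), "[%H:%M:%S] "), ...)
}

#' Run the full pipeline
#'
#' Executes simulate (optional) -> preprocess (filter, TMM, logCPM, MDS) ->
#' per-age differential expression -> pooling -> pairwise DEG overlaps ->
#' association grid -> enrichment (when an annotation is available), writes
#' every stage output as TSV under `config$out_dir`, and returns a run
#' summary with parameter values, per-stage counts, headline booleans and
#' md5 checksums of all written files. Re-running with an identical
#' configuration reproduces identical checksums.
#'
#' @param config a [pipeline_config()].
#' @return an object of class `run_summary` (also written as
#'   `summary.json`).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  unlink(file.path(out, "FAILED"))
  files <- character(0)
  stage <- "setup"
  summary <- list(package_version = as.character(utils::packageVersion("adsig")),
                  seed = config$seed, parameters = unclass(config)[
                    c("filter_min_rpkm", "alpha", "prior", "B", "scale",
                      "exclude_set", "min_term", "max_term", "top_genes",
                      "mds_dims")])

  run <- function(name, expr) {
    stage <<- name
    log_stage(config$verbose, "stage ", name)
    tryCatch(expr, error = function(e) {
      writeLines(paste0("stage ", name, ": ", conditionMessage(e)),
                 file.path(out, "FAILED"))
      stop2("stage ", name, " failed: ", conditionMessage(e))
    })
  }

  cohort <- run("input", {
    if (config$simulate) {
      sim_args <- config$sim
      if (is.null(sim_args$seed)) sim_args$seed <- config$seed
      ch <- simulate_cohort(do.call(sim_config, sim_args))
      files <- c(files, write_cohort(ch, out))
      ch
    } else {
      if (is.null(config$input_dir)) {
        stop2("input_dir required when simulate = FALSE")
      }
      read_cohort(config$input_dir)
    }
  })

  pp <- run("preprocess", {
    rpkm <- compute_rpkm(cohort$counts, cohort$lengths)
    flt <- filter_genes(rpkm, min_total = config$filter_min_rpkm)
    nf <- tmm_factors(cohort$counts, kept_genes = flt$kept)
    logcpm <- log_expression(cohort$counts[flt$kept, , drop = FALSE], nf,
                             prior = config$prior)
    mds <- mds_coordinates(logcpm, top_genes = config$top_genes,
                           dims = config$mds_dims)
    f1 <- file.path(out, "factors.tsv")
    write_tsv(data.frame(sample_id = names(nf$factors),
                         factor = as.numeric(nf$factors),
                         libsize = as.numeric(nf$libsize),
                         effective_libsize = as.numeric(nf$effective_libsize),
                         stringsAsFactors = FALSE), f1)
    f2 <- file.path(out, "mds.tsv")
    write_tsv(data.frame(sample_id = rownames(mds$points), mds$points,
                         stringsAsFactors = FALSE), f2)
    files <- c(files, f1, f2)
    list(flt = flt, nf = nf, logcpm = logcpm, mds = mds)
  })

  ages <- sort(unique(cohort$samples$age_months))
  de_list <- run("diffexp", {
    lst <- lapply(ages, function(a) {
      de <- run_de(cohort, a, alpha = config$alpha, genes = pp$flt$kept,
                   prior = config$prior)
      f <- file.path(out, sprintf("de_%02d.tsv", a))
      write_tsv(de, f)
      files <<- c(files, f)
      de
    })
    names(lst) <- as.character(ages)
    lst
  })

  sets <- run("pool", {
    st <- pool_degs(de_list)
    f <- file.path(out, "deg_sets.gmt")
    gm <- data.frame(term_id = c("all", "up", "down"),
                     description = "pooled_degs", stringsAsFactors = FALSE)
    gm$members <- list(st$all, st$up, st$down)
    class(gm) <- c("gmt", "data.frame")
    write_gmt(gm, f)
    files <- c(files, f)
    st
  })

  overlaps <- run("overlap", {
    per_age <- lapply(de_list, function(de) de$gene_id[de$significant])
    rows <- list()
    for (i in seq_along(ages)) {
      for (j in seq_along(ages)) {
        if (j <= i) next
        res <- tryCatch(
          overlap_chisq(per_age[[i]], per_age[[j]], pp$flt$kept),
          error = function(e) NULL)
        if (is.null(res)) next
        rows[[length(rows) + 1L]] <- data.frame(
          age_a = ages[i], age_b = ages[j],
          n_a = length(per_age[[i]]), n_b = length(per_age[[j]]),
          n_both = res$n_both, n_a_only = res$n_a_only,
          n_b_only = res$n_b_only, n_neither = res$n_neither,
          chi2 = res$chi2, pvalue = res$pvalue, stringsAsFactors = FALSE)
      }
    }
    ov <- if (length(rows) > 0) do.call(rbind, rows) else NULL
    if (!is.null(ov)) {
      f <- file.path(out, "overlaps.tsv")
      write_tsv(ov, f)
      files <- c(files, f)
    }
    ov
  })

  grid <- run("associate", {
    g <- signature_grid(cohort, sets, B = config$B, seed = config$seed,
                        scale = config$scale, genes = pp$flt$kept,
                        exclude_set = config$exclude_set)
    f <- file.path(out, "associations.tsv")
    write_tsv(g, f)
    files <- c(files, f)
    g
  })

  enrichment <- run("enrich", {
    gmt <- NULL
    if (!is.null(config$gmt_file)) {
      gmt <- read_gmt(config$gmt_file)
    } else if (config$simulate && isTRUE(config$annotate_from_truth)) {
      gmt <- make_annotation(cohort$truth,
                             seed = derive_seed(config$seed, "annotation"))
      f <- file.path(out, "annotation.gmt")
      write_gmt(gmt, f)
      files <- c(files, f)
    }
    universe <- if (is.null(gmt)) character(0) else {
      intersect(pp$flt$kept, unique(unlist(gmt$members)))
    }
    if (is.null(gmt) || length(sets$up) == 0 || length(sets$down) == 0 ||
        length(universe) == 0) {
      NULL
    } else {
      rep <- enrichment_report(intersect(sets$up, universe),
                               intersect(sets$down, universe), gmt, universe,
                               min_term = config$min_term,
                               max_term = config$max_term)
      for (lab in c("up", "down")) {
        f <- file.path(out, paste0("enrichment_", lab, ".tsv"))
        write_tsv(rep[[lab]], f)
        files <- c(files, f)
      }
      rep
    }
  })

  cell <- function(lab, gt, ph) {
    row <- grid$set_label == lab & grid$genotype == gt & grid$phenotype == ph
    isTRUE(grid$exceeds_max[row])
  }
  headline <- list(
    down_wt_behavior_significant = cell("down", "WT", "aversion_index"),
    down_ad_abeta_significant = cell("down", "AD", "abeta42"),
    down_ad_behavior_significant = cell("down", "AD", "aversion_index"),
    down_wt_abeta_significant = cell("down", "WT", "abeta42"),
    up_any_significant = any(grid$exceeds_max[grid$set_label == "up"])
  )

  summary <- c(summary, list(
    ages = ages,
    n_samples = ncol(cohort$counts),
    genes_total = nrow(cohort$counts),
    genes_kept = length(pp$flt$kept),
    dropped_zero_variance = pp$flt$dropped_zero_variance,
    dropped_low_expression = pp$flt$dropped_low_expression,
    degs_per_age = stats::setNames(
      vapply(de_list, function(d) sum(d$significant), integer(1)),
      names(de_list)),
    pooled_sizes = list(all = length(sets$all), up = length(sets$up),
                        down = length(sets$down)),
    headline = headline,
    associations = grid,
    checksums = as.list(tools::md5sum(sort(unique(files))))
  ))
  class(summary) <- "run_summary"
  jsonlite::write_json(unclass(summary), file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  summary
}

#' @export
print.run_summary <- function(x, ...) {
  cat("adsig run summary (seed", x$seed, ")\n")
  cat("  genes kept:", x$genes_kept, "/", x$genes_total,
      "| samples:", x$n_samples, "\n")
  cat("  DEGs per age:",
      paste(names(x$degs_per_age), unname(x$degs_per_age), sep = ":",
            collapse = "  "), "\n")
  cat("  pooled sets: all", x$pooled_sizes$all, "| up", x$pooled_sizes$up,
      "| down", x$pooled_sizes$down, "\n")
  hb <- x$headline
  cat("  headline: down/WT/behavior", hb$down_wt_behavior_significant,
      "| down/AD/abeta", hb$down_ad_abeta_significant,
      "| down/AD/behavior", hb$down_ad_behavior_significant,
      "| down/WT/abeta", hb$down_wt_abeta_significant,
      "| up any", hb$up_any_significant, "\n")
  invisible(x)
}

#' Export a cohort in the deposited-matrix dialect
#'
#' Writes an RPKM expression matrix (`expression.tsv`: `gene_id` plus one
#' column per sample) and a phenotype table (`phenotypes.tsv`), the layout
#' consumed by [import_deposited()].
#'
#' @param cohort an `ad_cohort`.
#' @param dir output directory.
#' @return invisibly, the files written.
#' @export
write_deposited <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rpkm <- compute_rpkm(cohort$counts, cohort$lengths)
  f1 <- file.path(dir, "expression.tsv")
  write_tsv(data.frame(gene_id = rownames(rpkm), rpkm, check.names = FALSE,
                       stringsAsFactors = FALSE), f1)
  f2 <- file.path(dir, "phenotypes.tsv")
  write_tsv(cohort$samples, f2)
  invisible(c(f1, f2))
}

#' Import a deposited RPKM matrix with phenotype metadata
#'
#' Builds an RPKM-scale cohort directly from an expression TSV and a
#' phenotype TSV (count-level stages are unavailable; association and
#' enrichment run in RPKM mode). Column names can be remapped with
#' `mapping` for files whose headers differ from the native dialect.
#'
#' @param expr_file TSV with a gene-id column followed by one numeric
#'   column per sample.
#' @param pheno_file TSV with per-sample metadata and phenotypes.
#' @param mapping named list remapping the required phenotype columns
#'   (`sample_id`, `genotype`, `age_months`, `replicate`,
#'   `aversion_index`, `abeta42`) and optionally `gene_id` to the file's
#'   actual headers.
#' @return an object of class `rpkm_cohort`: list with `expr` (RPKM
#'   matrix) and `samples`.
#' @export
import_deposited <- function(expr_file, pheno_file, mapping = list()) {
  map <- utils::modifyList(
    list(gene_id = "gene_id", sample_id = "sample_id", genotype = "genotype",
         age_months = "age_months", replicate = "replicate",
         aversion_index = "aversion_index", abeta42 = "abeta42"),
    mapping)
  expr_df <- read_tsv(expr_file)
  if (!map$gene_id %in% names(expr_df)) {
    stop2("parse error: ", expr_file, ": missing column ", map$gene_id)
  }
  expr <- as.matrix(expr_df[, setdiff(names(expr_df), map$gene_id),
                            drop = FALSE])
  rownames(expr) <- expr_df[[map$gene_id]]
  if (!is.numeric(expr) || any(expr < 0)) {
    stop2("parse error: ", expr_file, ": RPKM values must be numeric >= 0")
  }
  attr(expr, "scale") <- "RPKM"

  pheno <- read_tsv(pheno_file)
  need <- c("sample_id", "genotype", "age_months", "replicate",
            "aversion_index", "abeta42")
  miss <- need[!vapply(need, function(f) map[[f]] %in% names(pheno),
                       logical(1))]
  if (length(miss) > 0) {
    stop2("parse error: ", pheno_file, ": missing column(s) ",
          paste(vapply(miss, function(f) map[[f]], character(1)),
                collapse = ", "))
  }
  samples <- data.frame(lapply(stats::setNames(need, need),
                               function(f) pheno[[map[[f]]]]),
                        stringsAsFactors = FALSE)
  unmatched <- c(setdiff(samples$sample_id, colnames(expr)),
                 setdiff(colnames(expr), samples$sample_id))
  if (length(unmatched) > 0) {
    stop2("unalignable sample ids: ", paste(unmatched, collapse = ", "))
  }
  expr <- expr[, samples$sample_id, drop = FALSE]
  structure(list(expr = expr, samples = samples), class = "rpkm_cohort")
}
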