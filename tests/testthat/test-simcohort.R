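test_that("default design yields 30 samples and seeded determinism is bitwise", {
  cfg <- small_config(n_genes = 400, seed = 42)
  ch1 <- simulate_cohort(cfg)
  ch2 <- simulate_cohort(cfg)

  expect_equal(nrow(ch1$samples), 30) # 5 ages x 2 genotypes x 3 replicates
  expect_identical(ch1$counts, ch2$counts)
  expect_identical(ch1$samples, ch2$samples)
  expect_identical(ch1$truth, ch2$truth)

  ch3 <- simulate_cohort(small_config(n_genes = 400, seed = 43))
  expect_false(identical(ch1$counts, ch3$counts))
})

test_that("cohort invariants hold across seeds", {
  for (seed in 1:3) {
    ch <- simulate_cohort(small_config(n_genes = 500, seed = seed))
    expect_true(all(ch$counts >= 0))
    expect_identical(storage.mode(ch$counts), "integer")
    expect_true(all(ch$lengths >= 1))
    expect_true(all(colSums(ch$counts) > 0))
    expect_false(anyDuplicated(with(ch$samples,
                                    paste(genotype, age_months, replicate))) > 0)
    expect_true(all(ch$samples$aversion_index >= 0 &
                      ch$samples$aversion_index <= 1))
    expect_true(all(ch$samples$abeta42 >= 0))

    tg <- ch$truth$genes
    sig <- tg[tg$status == "signature", ]
    expect_true(all(sig$beta > 0))
    expect_true(all(sig$lfc < 0))
    expect_true(all(nzchar(sig$active_ages)))
    expect_true(all(tg$lfc[tg$status == "null"] == 0))
    expect_true(all(tg$beta[tg$status != "signature"] == 0))
  }
})

test_that("planted DE activity follows the age profile exactly", {
  prof <- c(1, 0.8, 0.5, 0.4, 0.2)
  cfg <- small_config(n_genes = 600, seed = 7, de_age_profile = prof,
                      n_up_total = 100, n_down_total = 140, n_signature = 20)
  ch <- simulate_cohort(cfg)
  tg <- ch$truth$genes
  act <- strsplit(tg$active_ages, ",", fixed = TRUE)
  for (a in seq_along(cfg$ages)) {
    age_chr <- as.character(cfg$ages[a])
    n_up_active <- sum(tg$status == "up" &
                         vapply(act, function(x) age_chr %in% x, logical(1)))
    n_down_active <- sum(tg$status %in% c("down", "signature") &
                           vapply(act, function(x) age_chr %in% x, logical(1)))
    expect_identical(n_up_active, as.integer(round(prof[a] * 100)))
    expect_identical(n_down_active, as.integer(round(prof[a] * 140)))
  }
  # signature genes are active wherever the profile is nonzero
  sig_act <- act[tg$status == "signature"]
  expect_true(all(lengths(sig_act) == sum(prof > 0)))
})

test_that("planted amyloid burden grows with age and couples to the latent", {
  cfg <- small_config(n_genes = 60)
  ab <- cfg$abeta_params
  planted_means <- ab$ad_intercept + ab$ad_slope * (cfg$ages - min(cfg$ages))
  expect_true(all(diff(planted_means) >= 0))

  cors <- logical(10)
  for (seed in 1:10) {
    ch <- simulate_cohort(small_config(n_genes = 60, seed = seed))
    ad <- ch$samples$genotype == "AD"
    cors[seed] <- cor(ch$truth$latent$L[ad], ch$samples$abeta42[ad]) < -0.5
  }
  expect_gte(sum(cors), 10)
})

test_that("count marginals match the NB parameterization var = mu + phi mu^2", {
  set.seed(99)
  mu <- matrix(100, nrow = 1, ncol = 50000)
  draws <- as.numeric(adsig:::sample_nb_counts(mu, phi = 0.1))
  expect_equal(mean(draws), 100, tolerance = 0.02)
  expect_equal(var(draws), 100 + 0.1 * 100^2, tolerance = 0.08)
})

test_that("invalid configurations raise errors naming the field", {
  expect_error(sim_config(n_genes = 0), "n_genes")
  expect_error(sim_config(n_genes = 100, n_up_total = 60, n_down_total = 50),
               "exceeds 'n_genes'")
  expect_error(small_config(n_signature = 1e6), "n_signature")
  expect_error(small_config(de_age_profile = c(1, 1, 1, 1, 2)),
               "de_age_profile")
  expect_error(small_config(dispersion = -1), "dispersion")
  expect_error(small_config(behavior_params = list(b0 = 1)), "behavior_params")
})

test_that("cohort TSV round trip is exact and violations are caught", {
  ch <- simulate_cohort(small_config(n_genes = 300, seed = 5))
  dir <- withr::local_tempdir()
  write_cohort(ch, dir)
  back <- read_cohort(dir)

  expect_identical(back$counts, ch$counts)
  expect_identical(back$lengths, ch$lengths)
  expect_equal(back$samples, ch$samples)
  expect_equal(back$truth$genes, ch$truth$genes)
  expect_equal(back$truth$latent, ch$truth$latent)

  # negative count -> parse error with file and line
  bad <- readLines(file.path(dir, "counts.tsv"))
  bad[3] <- sub("\t(\\d+)$", "\t-4", bad[3])
  writeLines(bad, file.path(dir, "counts.tsv"))
  expect_error(read_cohort(dir), "counts.tsv line 3")

  write_cohort(ch, dir)
  smp <- utils::read.delim(file.path(dir, "samples.tsv"))
  smp$replicate[2] <- smp$replicate[1]
  smp$sample_id[2] <- paste0(smp$sample_id[1], "b")
  utils::write.table(smp, file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  expect_error(read_cohort(dir), "duplicated \\(genotype, age, replicate\\)")
})

test_that("make_annotation plants recoverable enrichment and valid GMT", {
  ch <- simulate_cohort(small_config(n_genes = 500, seed = 3))

  # one term: format check through the GMT writer
  gmt1 <- make_annotation(ch$truth, n_terms = 1, enriched_fraction = 0,
                          seed = 1)
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(gmt1, path)
  lines <- readLines(path)
  expect_length(lines, 1)
  expect_gte(length(strsplit(lines, "\t")[[1]]), 3)
  expect_identical(read_gmt(path)$members[[1]], gmt1$members[[1]])

  # a term equal to the signature set attains the smallest ORA p-value
  tg <- ch$truth$genes
  sig <- tg$gene_id[tg$status == "signature"]
  down <- tg$gene_id[tg$status %in% c("down", "signature")]
  gmt2 <- make_annotation(ch$truth, n_terms = 20, enriched_fraction = 0,
                          seed = 2)
  gmt2 <- rbind(gmt2, data.frame(term_id = "SIG", description = "exact",
                                 members = I(list(sig))))
  class(gmt2) <- c("gmt", "data.frame")
  res <- ora(down, gmt2, universe = tg$gene_id)
  expect_identical(res$term_id[1], "SIG")

  # enriched_fraction = 0: no term reaches q < 0.05 in >= 9/10 seeds
  clean <- vapply(1:10, function(s) {
    g <- make_annotation(ch$truth, n_terms = 40, enriched_fraction = 0,
                         seed = s)
    min(ora(down, g, universe = tg$gene_id)$qvalue) > 0.05
  }, logical(1))
  expect_gte(sum(clean), 9)

  expect_error(make_annotation(ch$truth, n_terms = 0), "n_terms")
  expect_error(make_annotation(ch$truth, enriched_fraction = 2),
               "enriched_fraction")
})

test_that("null cohorts produce calibrated downstream DE", {
  frac_ok <- logical(6)
  n_declared <- integer(6)
  ages <- c(2, 7, 8, 11, 14)
  for (s in 1:6) {
    ch <- simulate_cohort(null_config(n_genes = 700, seed = 100 + s))
    de <- run_de(ch, ages[(s - 1) %% 5 + 1])
    frac <- mean(de$pvalue < 0.05)
    frac_ok[s] <- abs(frac - 0.05) <= 3 * sqrt(0.05 * 0.95 / nrow(de)) + 0.01
    n_declared[s] <- sum(de$significant)
  }
  expect_gte(sum(frac_ok), 5)
  expect_true(all(n_declared <= 0.005 * 700))
})
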