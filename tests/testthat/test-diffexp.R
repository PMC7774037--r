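test_that("quantile adjustment scales to the common library size", {
  set.seed(10)
  a <- matrix(rpois(300, 100), 100, 3)
  b <- matrix(rpois(300, 100), 100, 3)

  # equal library sizes: identity
  qa <- quantile_adjust(a, b, rep(1e5, 6))
  expect_equal(qa$pseudoA, a)
  expect_equal(qa$pseudoB, b)

  # zeros map to zeros
  a0 <- a; a0[1, ] <- 0L
  qa0 <- quantile_adjust(a0, b, c(9e4, 1e5, 1.2e5, 1e5, 1e5, 1e5))
  expect_equal(unname(qa0$pseudoA[1, ]), c(0, 0, 0))

  # a doubled-depth Poisson sample maps to about half its raw counts
  set.seed(11)
  mu <- 80
  a2 <- cbind(rpois(2000, mu), rpois(2000, mu), rpois(2000, 2 * mu))
  b2 <- matrix(rpois(6000, mu), 2000, 3)
  libs <- c(2000 * mu, 2000 * mu, 2000 * 2 * mu, rep(2000 * mu, 3))
  qa2 <- quantile_adjust(a2, b2, libs)
  ratio <- mean(qa2$pseudoA[, 3]) / mean(a2[, 3])
  common <- exp(mean(log(libs)))
  expect_equal(ratio, common / libs[3], tolerance = 1e-9)
  # after adjustment every sample sits at the common depth, so the doubled
  # sample's mean pseudo-count matches the other samples' (~half its raw mean)
  expect_lt(abs(mean(qa2$pseudoA[, 3]) / mean(qa2$pseudoA[, 1]) - 1), 0.05)

  expect_error(quantile_adjust(a, b, c(0, rep(1e5, 5))), "zero effective")
})

test_that("common dispersion recovery and degenerate inputs", {
  set.seed(12)
  sim_phi <- function(phi, n_genes = 800, seed = 1) {
    set.seed(seed)
    mu <- rlnorm(n_genes, log(100), 0.8)
    a <- matrix(rnbinom(n_genes * 3, mu = mu,
                        size = if (phi > 0) 1 / phi else Inf), n_genes, 3)
    b <- matrix(rnbinom(n_genes * 3, mu = mu,
                        size = if (phi > 0) 1 / phi else Inf), n_genes, 3)
    estimate_common_dispersion(a, b)$phi
  }
  rec <- vapply(1:5, function(s) sim_phi(0.2, seed = s), numeric(1))
  expect_gte(sum(rec >= 0.15 & rec <= 0.25), 4)

  pois <- vapply(1:5, function(s) sim_phi(0, seed = 10 + s), numeric(1))
  expect_gte(sum(pois <= 0.02), 4)

  flat <- estimate_common_dispersion(matrix(5, 1, 3), matrix(5, 1, 3))
  expect_identical(flat$phi, 0)
  expect_identical(flat$method, "poisson")

  expect_error(estimate_common_dispersion(matrix(0, 2, 2), matrix(0, 2, 2)),
               "all-zero")
})

test_that("NB exact test matches enumeration oracles and is monotone", {
  # phi = 0, equal group sizes: exact binomial two-sided test
  expect_equal(nb_exact_test(2, 3, 8, 3, 0), 112 / 1024, tolerance = 1e-10)
  for (total in c(1, 7, 30, 99, 200)) {
    for (sA in unique(round(c(0, total * 0.2, total / 2)))) {
      expect_equal(nb_exact_test(sA, 3, total - sA, 3, 0),
                   oracle_binom_two_sided(sA, total - sA),
                   tolerance = 1e-10)
    }
  }

  # symmetry
  expect_equal(nb_exact_test(17, 3, 17, 3, 0.3), 1)

  # overdispersion weakens the evidence
  expect_gt(nb_exact_test(0, 3, 30, 3, 0.5), nb_exact_test(0, 3, 30, 3, 0))

  # conditional pmf is a proper distribution
  for (phi in c(0, 0.1, 0.7)) {
    expect_equal(sum(adsig:::nb_exact_pmf(120, 3, 3, phi)), 1,
                 tolerance = 1e-9)
  }

  # p non-increasing in |sumA/nA - sumB/nB| at fixed total
  total <- 60
  p_seq <- vapply(30:10, function(sA) {
    nb_exact_test(sA, 3, total - sA, 3, 0.2)
  }, numeric(1))
  expect_true(all(diff(p_seq) <= 1e-12))

  # T = 0 convention
  expect_identical(nb_exact_test(0, 3, 0, 3, 0.1), 1)
})

test_that("BH adjustment equals hand step-up and is order-stable", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(13)
  for (i in 1:5) {
    p <- runif(50)
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_equal(q, p.adjust(p, "BH"), tolerance = 1e-12)
    perm <- sample(50)
    expect_equal(bh_adjust(p[perm]), q[perm], tolerance = 1e-15)
  }
})

test_that("per-age DE recovers planted effects with correct direction", {
  prof <- c(1, 0, 0, 0, 0) # effects only at 2 months
  ch <- simulate_cohort(small_config(
    n_genes = 800, seed = 21, n_up_total = 40, n_down_total = 40,
    n_signature = 0, lfc_range = c(2, 2), de_age_profile = prof))
  tg <- ch$truth$genes
  de2 <- run_de(ch, 2)

  planted_up <- tg$gene_id[tg$status == "up"]
  planted_down <- tg$gene_id[tg$status == "down"]
  hit_up <- de2$significant & de2$direction == "up" &
    de2$gene_id %in% planted_up
  hit_down <- de2$significant & de2$direction == "down" &
    de2$gene_id %in% planted_down
  expect_gte(sum(hit_up) / length(planted_up), 0.8)
  expect_gte(sum(hit_down) / length(planted_down), 0.8)

  # specificity: those genes are quiet at 14 months
  de14 <- run_de(ch, 14)
  frac_sig_late <- mean(de14$significant[de14$gene_id %in%
                                           c(planted_up, planted_down)])
  expect_lte(frac_sig_late, 0.1)

  wt_only <- ch
  wt_only$samples <- ch$samples[ch$samples$genotype == "WT" |
                                  ch$samples$age_months != 2, ]
  wt_only$counts <- ch$counts[, wt_only$samples$sample_id]
  expect_error(run_de(wt_only, 2), "age 2")
})

test_that("pooling uses directional union semantics", {
  mk <- function(gene, dir, sig = TRUE, age = 2) {
    data.frame(gene_id = gene, age_months = age,
               log2fc = ifelse(dir == "up", 1, -1), pvalue = 0.001,
               fdr = 0.001, direction = dir, significant = sig,
               stringsAsFactors = FALSE)
  }
  de_a <- rbind(mk("g1", "up"), mk("g2", "up"), mk("g3", "down"))
  de_b <- rbind(mk("g1", "down", age = 8), mk("g4", "down", age = 8),
                mk("g5", "up", age = 8, sig = FALSE))
  sets <- pool_degs(list(de_a, de_b))
  expect_setequal(sets$up, c("g1", "g2"))
  expect_setequal(sets$down, c("g1", "g3", "g4"))
  expect_setequal(sets$all, c("g1", "g2", "g3", "g4"))
  # conflicting-direction gene counted once in all
  expect_gt(length(sets$up) + length(sets$down), length(sets$all))

  empty <- pool_degs(list(mk("g1", "up", sig = FALSE)))
  expect_length(empty$all, 0)
  expect_length(empty$up, 0)

  disjoint <- pool_degs(list(mk("a", "up"), mk("b", "up"), mk("c", "up")))
  expect_setequal(disjoint$up, c("a", "b", "c"))
  expect_length(disjoint$down, 0)

  expect_error(pool_degs(list()), "at least one")
})
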