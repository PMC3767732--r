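test_that("paired t handles degenerate and symmetric difference patterns", {
  lower <- matrix(c(5, 5, 5, 5,
                    5, 6, 5, 6), 2, 4, byrow = TRUE)
  upper <- lower + rbind(rep(1, 4),            # constant differences
                         c(1, -1, 1, -1))      # sign-alternating differences
  x <- paired_expr(upper, lower)
  res <- paired_t(x, paired_ann(4))
  expect_true(res$degenerate[1])
  expect_equal(res$p[1], 1)
  expect_false(res$degenerate[2])
  expect_equal(res$t_stat[2], 0)
  expect_equal(res$p[2], 1)
  expect_equal(res$df, c(3, 3))
})

test_that("paired t needs two complete pairs", {
  x <- paired_expr(matrix(1:3, 3, 1), matrix(4:6, 3, 1))
  expect_error(paired_t(x, paired_ann(1)), "2 complete")
})

test_that("paired t holds its type-I error on null Gaussian differences", {
  withr::local_seed(31)
  m <- 2000; n <- 6
  lower <- matrix(rnorm(m * n, 8, 1), m, n)
  upper <- lower + matrix(rnorm(m * n, 0, 0.5), m, n)
  res <- paired_t(paired_expr(upper, lower), paired_ann(n))
  frac <- mean(res$p < 0.05)
  ci <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / m)
  expect_gt(frac, ci[1])
  expect_lt(frac, ci[2])
})

test_that("BH adjustment matches the brute-force step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")

  withr::local_seed(32)
  for (rep in 1:20) {
    m <- sample(1:12, 1)
    p <- round(runif(m), sample(1:3, 1))  # rounding forces ties
    expect_equal(bh_adjust(p), bh_oracle(p))
  }
})

test_that("q-values reduce to BH at pi0 = 1 and estimate pi0 near 1 under the null", {
  withr::local_seed(33)
  p <- runif(1000)
  expect_equal(storey_q(p, pi0 = 1), bh_adjust(p))
  pi0_hat <- sum(p > 0.5) / (1000 * 0.5)
  expect_gte(pi0_hat, 0.85)
  expect_lte(pi0_hat, 1.05)
  expect_equal(storey_q(rep(1, 12)), rep(1, 12))
  expect_error(storey_q(runif(5)), "at least 10")
})

test_that("q-values shrink below BH when signal depresses pi0", {
  withr::local_seed(34)
  p <- c(rbeta(300, 0.2, 5), runif(700))
  q <- storey_q(p)
  expect_true(all(q <= bh_adjust(p) + 1e-12))
})

test_that("moderated t collapses to the classical test in the degenerate limits", {
  withr::local_seed(35)
  n <- 5
  lower <- matrix(rnorm(20 * n, 8, 1), 20, n)
  upper <- lower + matrix(rnorm(20 * n, 0, 0.3), 20, n)
  x <- paired_expr(upper, lower)
  ann <- paired_ann(n)

  classical <- paired_t(x, ann)
  forced0 <- moderated_t(x, ann, d0 = 0, s0_sq = 1)
  expect_equal(tidy(forced0)$t_stat, classical$t_stat, tolerance = 1e-12)
  expect_equal(tidy(forced0)$p, classical$p, tolerance = 1e-12)

  forced_inf <- moderated_t(x, ann, d0 = Inf, s0_sq = 0.04)
  expect_true(all(abs(forced_inf$s2_post - 0.04) < 1e-12))

  # identical sample variances: the prior matches them and nothing moves
  d <- matrix(rep(c(-1, 0, 1, 2, -2) / 2, each = 20), 20, n, byrow = FALSE)
  x_eq <- paired_expr(matrix(8, 20, n) + d, matrix(8, 20, n))
  fit_eq <- moderated_t(x_eq, ann)
  v <- var(c(-1, 0, 1, 2, -2) / 2)
  expect_true(all(abs(fit_eq$s2_post - v) < 1e-10))
  expect_equal(tidy(fit_eq)$t_stat, paired_t(x_eq, ann)$t_stat, tolerance = 1e-8)
})

test_that("variance-prior moments recover known hyperparameters", {
  withr::local_seed(36)
  m <- 1000; n <- 7; d0 <- 4; s0_sq <- 0.05
  sigma2 <- d0 * s0_sq / rchisq(m, d0)
  diffs <- matrix(rnorm(m * n, 0, sqrt(sigma2)), m, n)
  x <- paired_expr(matrix(8, m, n) + diffs, matrix(8, m, n))
  fit <- moderated_t(x, paired_ann(n))
  expect_lt(abs(fit$d0 - d0) / d0, 0.25)
  expect_lt(abs(fit$s0_sq - s0_sq) / s0_sq, 0.25)
})

test_that("the variance prior agrees with the limma estimator", {
  withr::local_seed(37)
  m <- 500; df <- 6
  s2 <- 0.08 * 5 / rchisq(m, 5) * rchisq(m, df) / df
  ours <- lobeconcord:::fit_variance_prior(s2, df)
  theirs <- limma::fitFDist(s2, df1 = df)
  expect_lt(abs(ours$d0 - theirs$df2) / theirs$df2, 0.05)
  expect_lt(abs(ours$s0_sq - theirs$scale) / theirs$scale, 0.05)
})

test_that("symmetric fold change is direction-agnostic", {
  x <- tiny_expr(cbind(c(3, 2, 5, 0), c(3, 2, 5, 0),
                       c(2, 3, 5, 1), c(2, 3, 5, 1)),
                 sample_ids = c("a1", "a2", "b1", "b2"))
  ann <- tibble::tibble(sample_id = c("a1", "a2", "b1", "b2"),
                        subject_id = c("A1", "A2", "B1", "B2"),
                        site = "lower",
                        group = c("smoker", "smoker", "nonsmoker", "nonsmoker"))
  fc <- symmetric_fold_change(x, ann)
  expect_equal(fc$fc[1:3], c(1.5, 1.5, 1))
  expect_true(fc$degenerate[4])
  expect_true(is.na(fc$fc[4]))
})

test_that("signature derivation honours its thresholds and edge cases", {
  co <- generate_cohort(synthetic_config(n_subjects = 6, n_nonsmokers = 10,
                                         m_total = 400, m_sig = 40,
                                         n_absent = 20, seed = 38))
  norm <- normalize_per_gene(normalize_per_chip(co$expression))

  # thresholds disabled: every present-filtered probe comes back
  all_sig <- derive_signature(norm, co$detection, co$annotation,
                              fc_min = 1, p_bh_max = 1 + 1e-9)
  expect_setequal(all_sig, present_filter(co$expression, co$detection,
    groups = list(
      smoker = co$annotation$sample_id[co$annotation$group == "smoker"],
      nonsmoker = co$annotation$sample_id[co$annotation$group == "nonsmoker"])))

  # identical groups: nothing passes
  null_co <- generate_null_cohort(synthetic_config(n_subjects = 6, n_nonsmokers = 10,
                                                   m_total = 400, m_sig = 40,
                                                   n_absent = 0, seed = 39))
  null_norm <- normalize_per_gene(normalize_per_chip(null_co$expression))
  expect_warning(empty <- derive_signature(null_norm, null_co$detection, null_co$annotation),
                 "empty")
  expect_length(empty, 0)
})

test_that("signature derivation is invariant to sample order", {
  co <- generate_cohort(synthetic_config(n_subjects = 5, n_nonsmokers = 8,
                                         m_total = 300, m_sig = 30,
                                         n_absent = 0, seed = 40))
  norm <- normalize_per_gene(normalize_per_chip(co$expression))
  base <- derive_signature(norm, co$detection, co$annotation)

  withr::local_seed(41)
  perm <- sample(sample_ids(norm))
  norm2 <- norm[c("probe_id", perm)]
  attr(norm2, "scale") <- "linear"
  det2 <- co$detection[c("probe_id", perm)]
  again <- derive_signature(norm2, det2, co$annotation)
  expect_setequal(as.character(again), as.character(base))
})

test_that("classical and moderated tests agree on effect direction for signature probes", {
  co <- generate_cohort(synthetic_config(n_subjects = 6, n_nonsmokers = 12,
                                         m_total = 500, m_sig = 60,
                                         n_absent = 0, seed = 42))
  norm <- normalize_per_gene(normalize_per_chip(co$expression))
  sig <- derive_signature(norm, co$detection, co$annotation)
  lg <- log2_transform(filter_probes(norm, as.character(sig)))
  mod <- tidy(moderated_t(lg, co$annotation, design = "two_group"))
  cls <- tidy(moderated_t(lg, co$annotation, design = "two_group", d0 = 0, s0_sq = 1))
  expect_true(all(sign(mod$t_stat) == sign(cls$t_stat)))
})
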