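test_that("correlation distance matches the direct formula", {
  withr::local_seed(51)
  x <- tiny_expr(matrix(rnorm(20 * 6, 8, 1), 20, 6), scale = "log2")
  vals <- expr_values(x)
  for (method in c("pearson", "spearman")) {
    d <- as.matrix(correlation_distance(x, method = method))
    v <- if (method == "spearman") apply(vals, 2, rank) else vals
    for (i in 1:6) for (j in 1:6) {
      a <- v[, i] - mean(v[, i]); b <- v[, j] - mean(v[, j])
      expect_equal(d[i, j], 1 - sum(a * b) / sqrt(sum(a^2) * sum(b^2)),
                   tolerance = 1e-12)
    }
  }
})

test_that("correlation distance hits its exact endpoints", {
  x <- tiny_expr(cbind(c(1, 2, 3), c(1, 2, 3), c(3, 2, 1)),
                 sample_ids = c("a", "b", "c"), scale = "log2")
  d <- as.matrix(correlation_distance(x))
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 2)

  flat <- tiny_expr(cbind(c(1, 2, 3), c(2, 2, 2)),
                    sample_ids = c("ok", "flatline"), scale = "log2")
  expect_error(correlation_distance(flat), "flatline")
})

test_that("two samples merge once, at their distance", {
  d <- as.dist(matrix(c(0, 0.3, 0.3, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b"))))
  tree <- hierarchical_cluster(d)
  expect_equal(nrow(tree$merge), 1)
  expect_equal(tree$height, 0.3)
  expect_identical(tree$merge[1, ], c(-1L, -2L))
})

test_that("tight pairs merge before anything else", {
  dm <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  dm[1, 2] <- dm[2, 1] <- 0.1
  dm[3, 4] <- dm[4, 3] <- 0.2
  diag(dm) <- 0
  tree <- hierarchical_cluster(as.dist(dm))
  expect_identical(tree$merge[1, ], c(-1L, -2L))
  expect_identical(tree$merge[2, ], c(-3L, -4L))
})

test_that("clustering agrees with stats::hclust on tie-free instances", {
  withr::local_seed(52)
  canon <- function(m) t(apply(m, 1, function(r) r[order(r > 0, abs(r))]))
  for (rep in 1:10) {
    n <- 8
    dm <- matrix(0, n, n)
    dm[lower.tri(dm)] <- runif(n * (n - 1) / 2, 0.1, 1)
    dm <- dm + t(dm)
    rownames(dm) <- colnames(dm) <- paste0("s", 1:n)
    for (linkage in c("average", "complete")) {
      ours <- hierarchical_cluster(as.dist(dm), linkage)
      ref <- stats::hclust(as.dist(dm), method = linkage)
      expect_equal(ours$height, ref$height, tolerance = 1e-12)
      expect_equal(canon(ours$merge), canon(ref$merge))
    }
  }
})

test_that("clustering matches the naive set-based oracle, ties included", {
  withr::local_seed(53)
  for (rep in 1:15) {
    n <- sample(4:8, 1)
    dm <- matrix(0, n, n)
    dm[lower.tri(dm)] <- round(runif(n * (n - 1) / 2, 0.1, 1), 1)  # heavy ties
    dm <- dm + t(dm)
    rownames(dm) <- colnames(dm) <- paste0("s", 1:n)
    ours <- hierarchical_cluster(as.dist(dm))
    orc <- sibling_oracle(dm)
    expect_equal(sort(ours$height), orc$heights, tolerance = 1e-12)
    sib_ours <- list()
    for (k in seq_len(nrow(ours$merge))) {
      r <- ours$merge[k, ]
      if (all(r < 0)) sib_ours[[length(sib_ours) + 1]] <- sort(-r)
    }
    expect_equal(sib_ours[order(vapply(sib_ours, min, numeric(1)))],
                 orc$siblings[order(vapply(orc$siblings, min, numeric(1)))])
  }
})

test_that("non-symmetric distance matrices are rejected", {
  dm <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(hierarchical_cluster(dm), "symmetric")
})

test_that("pairing count finds sibling pairs and excludes half-subjects", {
  ann <- paired_ann(2)
  dm <- matrix(1, 4, 4, dimnames = list(ann$sample_id, ann$sample_id))
  dm[1, 2] <- dm[2, 1] <- 0.05
  dm[3, 4] <- dm[4, 3] <- 0.05
  diag(dm) <- 0
  tree <- hierarchical_cluster(as.dist(dm))
  k <- pairing_count(tree, ann)
  expect_equal(as.integer(k), 2L)
  expect_equal(attr(k, "n_pairs"), 2L)

  ann3 <- rbind(ann, tibble::tibble(sample_id = "SM99_upper", subject_id = "SM99",
                                    site = "upper", group = "smoker"))
  dm5 <- matrix(1, 5, 5, dimnames = list(ann3$sample_id, ann3$sample_id))
  diag(dm5) <- 0
  tree5 <- hierarchical_cluster(as.dist(dm5))
  expect_warning(k5 <- pairing_count(tree5, ann3), "SM99")
  expect_equal(attr(k5, "n_pairs"), 2L)
})

test_that("pairing count matches exhaustive enumeration on tiny cohorts", {
  withr::local_seed(54)
  for (rep in 1:30) {
    n_subj <- sample(2:4, 1)
    n <- 2 * n_subj
    ann <- paired_ann(n_subj)
    dm <- matrix(0, n, n)
    vals <- if (rep <= 10) rep(0.5, n * (n - 1) / 2)     # adversarial: all equal
            else round(runif(n * (n - 1) / 2, 0.1, 1), 1)
    dm[lower.tri(dm)] <- vals
    dm <- dm + t(dm)
    rownames(dm) <- colnames(dm) <- ann$sample_id
    tree <- hierarchical_cluster(as.dist(dm))
    expect_equal(as.integer(pairing_count(tree, ann)),
                 oracle_pairing_count(dm, n_subj))
  }
})

test_that("pairing count is invariant to site relabeling and sample order", {
  co <- generate_cohort(synthetic_config(n_subjects = 5, n_nonsmokers = 0,
                                         m_total = 300, m_sig = 50,
                                         n_absent = 0, seed = 55))
  lg <- log2_transform(normalize_per_gene(normalize_per_chip(co$expression)))
  tree <- hierarchical_cluster(correlation_distance(lg, co$signature))
  base <- as.integer(pairing_count(tree, co$annotation))

  flipped <- co$annotation
  flipped$site <- ifelse(flipped$site == "upper", "lower", "upper")
  expect_equal(as.integer(pairing_count(tree, flipped)), base)

  withr::local_seed(56)
  perm <- sample(sample_ids(lg))
  lg2 <- lg[c("probe_id", perm)]
  attr(lg2, "scale") <- "log2"
  tree2 <- hierarchical_cluster(correlation_distance(lg2, co$signature))
  expect_equal(as.integer(pairing_count(tree2, co$annotation)), base)
})

test_that("random probe lists respect exclusions, size and reproducibility", {
  universe <- sprintf("p%03d", 1:40)
  exclude <- sprintf("p%03d", 1:5)

  whole <- random_probe_lists(universe, exclude, size = 35, B = 3, seed = 57)
  expect_true(all(vapply(whole, function(l) setequal(l, setdiff(universe, exclude)),
                         logical(1))))

  lists <- random_probe_lists(universe, exclude, size = 10, B = 50, seed = 57)
  expect_true(all(vapply(lists, function(l) !any(l %in% exclude), logical(1))))
  expect_true(all(vapply(lists, function(l) !anyDuplicated(l), logical(1))))

  again <- random_probe_lists(universe, exclude, size = 10, B = 50, seed = 57)
  expect_identical(lists, again)
  expect_error(random_probe_lists(universe, exclude, size = 36, B = 1), "need 36")
})

test_that("per-probe inclusion frequencies are uniform across random lists", {
  universe <- sprintf("p%03d", 1:40)
  exclude <- sprintf("p%03d", 1:5)
  lists <- random_probe_lists(universe, exclude, size = 5, B = 2000, seed = 58)
  counts <- table(factor(unlist(lists), levels = setdiff(universe, exclude)))
  expected <- 2000 * 5 / 35
  stat <- sum((counts - expected)^2 / expected)
  expect_lt(stat, qchisq(0.99, df = 34))
})

test_that("the add-one empirical p follows its arithmetic definition", {
  expect_equal(empirical_p(c(0, 1, 2, 3), 2, "ge"), 0.6)
  expect_equal(empirical_p(rep(0, 100), 0, "ge"), 1)
  expect_equal(empirical_p(0:3, 0, "le"), 2 / 5)
})

test_that("the pairing permutation test assembles a coherent null result", {
  co <- generate_cohort(synthetic_config(n_subjects = 4, n_nonsmokers = 0,
                                         m_total = 400, m_sig = 40,
                                         n_absent = 0, seed = 59))
  lg <- log2_transform(normalize_per_gene(normalize_per_chip(co$expression)))
  res <- pairing_permutation_test(lg, co$annotation, co$signature,
                                  universe = lg$probe_id, B = 20, seed = 60)
  expect_s3_class(res, "pairing_null")
  expect_length(res$null_counts, 20)
  expect_true(all(res$null_counts >= 0 & res$null_counts <= res$n_pairs))
  expect_equal(res$empirical_p,
               (1 + sum(res$null_counts >= res$observed_k)) / 21)
  expect_gte(res$observed_k, 0)
  expect_lte(res$observed_k, res$n_pairs)
  g <- glance(res)
  expect_identical(g$B, 20L)
  expect_equal(nrow(tidy(res)), 20)
})
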