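# PCA of samples in signature space and the paired vector-length statistic.

#' Principal-component scores of samples over a probe list
#'
#' Probes are mean-centered across samples (no variance scaling) and the
#' sample scores come from the singular value decomposition of the centered
#' samples-by-probes matrix.  The sign of each component is fixed so that its
#' largest-magnitude probe loading is positive.
#'
#' @param x Log2-scale expression table.
#' @param probes Optional probe restriction.
#' @param k Number of components (default 3); must not exceed
#'   `min(#samples - 1, #probes)`.
#' @return An `expr_pca` object: `scores` tibble (`sample_id`, `PC1`...),
#'   `var_explained` fractions, probe `loadings`, and the centering vector.
#' @export
pca_scores <- function(x, probes = NULL, k = 3) {
  x <- filter_probes(x, probes)
  vals <- t(expr_values(x))        # samples x probes
  kmax <- min(nrow(vals) - 1, ncol(vals))
  if (k > kmax) abort(sprintf("k = %d exceeds the maximum of %d components.", k, kmax))
  center <- colMeans(vals)
  cen <- sweep(vals, 2, center)
  sv <- svd(cen)
  total_var <- sum(sv$d^2)
  keep <- seq_len(k)
  scores <- sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], nrow = k)
  loadings <- sv$v[, keep, drop = FALSE]
  for (j in keep) {
    top <- which.max(abs(loadings[, j]))
    if (loadings[top, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  colnames(scores) <- paste0("PC", keep)
  rownames(loadings) <- x$probe_id
  colnames(loadings) <- paste0("PC", keep)
  structure(list(scores = dplyr::bind_cols(tibble(sample_id = rownames(vals)),
                                           as_tibble(scores)),
                 var_explained = sv$d[keep]^2 / total_var,
                 loadings = loadings, center = center, k = k),
            class = "expr_pca")
}

#' @export
tidy.expr_pca <- function(x, ...) x$scores

#' @export
glance.expr_pca <- function(x, ...) {
  tibble(k = x$k, var_explained_total = sum(x$var_explained),
         n_samples = nrow(x$scores), n_probes = nrow(x$loadings))
}

#' @export
print.expr_pca <- function(x, ...) {
  cat(sprintf("PCA scores: %d samples x %d components (%.1f%% of variance)\n",
              nrow(x$scores), x$k, 100 * sum(x$var_explained)))
  invisible(x)
}

#' @param object An `expr_pca` object.
#' @param ann Optional annotation; when given, points are coloured by site
#'   and each subject's two samples are connected.
#' @param ... Ignored.
#' @describeIn pca_scores Scatter of the first two component scores.
#' @export
autoplot.expr_pca <- function(object, ann = NULL, ...) {
  df <- object$scores
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  if (!is.null(ann)) {
    ann <- validate_annotation(ann)
    df <- dplyr::left_join(df, ann, by = "sample_id")
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
      ggplot2::geom_line(ggplot2::aes(group = .data$subject_id), colour = "grey60") +
      ggplot2::geom_point(ggplot2::aes(colour = .data$site), size = 2)
  } else {
    p <- p + ggplot2::geom_point(size = 2)
  }
  p + ggplot2::labs(
    x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
    y = sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2])) +
    ggplot2::theme_minimal()
}

#' Euclidean length of each subject's upper-lower vector
#'
#' For each paired subject, the Euclidean norm of (upper - lower) over the
#' listed probes: the distance between that subject's two samples in
#' multivariate probe space.
#'
#' @inheritParams pca_scores
#' @param ann Sample annotation defining the pairing; subjects with a
#'   missing site are skipped with a warning.
#' @return Tibble with `subject_id` and `length`.
#' @export
paired_vector_lengths <- function(x, ann, probes = NULL) {
  x <- filter_probes(x, probes)
  ps <- paired_site_values(x, ann)
  if (length(ps$subjects) == 0) abort("No complete upper/lower pairs in the data.")
  d <- ps$upper - ps$lower
  tibble(subject_id = ps$subjects,
         length = unname(sqrt(colSums(d^2))))
}

#' Random-list null for the median paired vector length
#'
#' The observed median vector length over the signature probes is compared
#' with the medians obtained from `B` random probe lists of the same size
#' (signature excluded).  Besides the null medians, the summary holds their
#' 0.05/0.25/0.5/0.75/0.95 quantiles (the boxplot whiskers and box of the
#' usual display) and the one-sided add-one proportion
#' `(1 + #\{null <= observed\}) / (B + 1)` — small when the signature pairs
#' sit closer together than random probe sets.
#'
#' @inheritParams pairing_permutation_test
#' @return A `vector_length_null` object.
#' @export
vector_length_null <- function(x, ann, signature, universe, B = 100, seed = NULL) {
  lengths_obs <- paired_vector_lengths(x, ann, signature)
  observed_median <- median(lengths_obs$length)
  lists <- random_probe_lists(universe, exclude = signature,
                              size = length(signature), B = B, seed = seed)
  null_medians <- vapply(lists, function(p) {
    median(paired_vector_lengths(x, ann, p)$length)
  }, numeric(1))
  qs <- quantile(null_medians, probs = c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE)
  structure(list(lengths = lengths_obs,
                 observed_median = observed_median,
                 null_medians = null_medians,
                 null_quantiles = setNames(qs, c("q05", "q25", "q50", "q75", "q95")),
                 B = as.integer(B),
                 empirical_proportion = empirical_p(null_medians, observed_median, "le"),
                 signature_size = length(signature), seed = seed),
            class = "vector_length_null")
}

#' @export
print.vector_length_null <- function(x, ...) {
  cat(sprintf("Median paired vector length: %.4g over %d pairs (signature of %d probes)\n",
              x$observed_median, nrow(x$lengths), x$signature_size))
  cat(sprintf("Null medians over %d random lists: median %.4g [5%%: %.4g, 95%%: %.4g]; P(null <= obs) = %.4g\n",
              x$B, x$null_quantiles[["q50"]], x$null_quantiles[["q05"]],
              x$null_quantiles[["q95"]], x$empirical_proportion))
  invisible(x)
}

#' @export
tidy.vector_length_null <- function(x, ...) {
  tibble(replicate = seq_len(x$B), null_median = x$null_medians)
}

#' @export
glance.vector_length_null <- function(x, ...) {
  tibble(observed_median = x$observed_median, B = x$B,
         null_q05 = x$null_quantiles[["q05"]], null_q25 = x$null_quantiles[["q25"]],
         null_q50 = x$null_quantiles[["q50"]], null_q75 = x$null_quantiles[["q75"]],
         null_q95 = x$null_quantiles[["q95"]],
         empirical_proportion = x$empirical_proportion,
         signature_size = x$signature_size)
}

#' @param object A `vector_length_null` object.
#' @param ... Ignored.
#' @describeIn vector_length_null Box of the null medians (whiskers at the
#'   0.05/0.95 quantiles) with the observed median marked in red.
#' @export
autoplot.vector_length_null <- function(object, ...) {
  q <- object$null_quantiles
  box <- tibble(x = 1, ymin = q[["q05"]], lower = q[["q25"]], middle = q[["q50"]],
                upper = q[["q75"]], ymax = q[["q95"]])
  ggplot2::ggplot(box, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_boxplot(ggplot2::aes(ymin = .data$ymin, lower = .data$lower,
                                       middle = .data$middle, upper = .data$upper,
                                       ymax = .data$ymax),
                          stat = "identity", width = 0.3, fill = "grey85") +
    ggplot2::geom_point(ggplot2::aes(y = object$observed_median), colour = "red", size = 3) +
    ggplot2::scale_x_continuous(breaks = NULL) +
    ggplot2::labs(x = NULL, y = "median paired vector length",
                  title = sprintf("Observed median vs %d random lists", object$B)) +
    ggplot2::theme_minimal()
}
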