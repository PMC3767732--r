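# Correlation-distance hierarchical clustering of samples, the upper/lower
# sibling-pairing count, and its empirical null over random probe lists.

#' Correlation distance between samples over a probe list
#'
#' `d(i, j) = 1 - cor(i, j)` across the listed probes, with Pearson or
#' Spearman (average-rank ties) correlation.
#'
#' @param x Log2-scale expression table.
#' @param probes Optional probe restriction (e.g. a signature list).
#' @param method `"pearson"` or `"spearman"`.
#' @return A `stats::dist` object over the samples (zero diagonal implied,
#'   symmetric by construction).
#' @export
correlation_distance <- function(x, probes = NULL, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  x <- filter_probes(x, probes)
  vals <- expr_values(x)
  if (nrow(vals) < 2) abort("Need at least 2 probes to correlate samples.")
  sds <- apply(vals, 2, sd)
  if (any(sds == 0)) {
    abort(paste0("Zero-variance sample(s) over the probe list: ",
                 paste(colnames(vals)[sds == 0], collapse = ", ")))
  }
  co <- cor(vals, method = method)
  d <- stats::as.dist(1 - co)
  attr(d, "method") <- paste0("1-", method)
  d
}

#' Agglomerative hierarchical clustering with deterministic tie-breaking
#'
#' A naive O(n^3) agglomeration with average or complete linkage.  At every
#' step the pair of clusters at minimal distance merges; ties are broken in
#' favour of the pair occupying the lowest original sample positions (a
#' merged cluster keeps the slot of its lowest-positioned founding member),
#' which makes runs bit-reproducible.
#' Returns a `stats::hclust`-compatible object, so the usual plotting and
#' `ape::as.phylo()` conversion apply.
#'
#' @param d A `dist` object or symmetric numeric matrix with labels.
#' @param linkage `"average"` or `"complete"`.
#' @return An object of class `hclust` (merge, height, order, labels).
#' @export
hierarchical_cluster <- function(d, linkage = c("average", "complete")) {
  linkage <- match.arg(linkage)
  if (inherits(d, "dist")) {
    dm <- as.matrix(d)
  } else if (is.matrix(d)) {
    if (!isSymmetric(unname(d), tol = 1e-12)) abort("Distance matrix must be symmetric.")
    dm <- d
  } else {
    abort("`d` must be a dist object or a symmetric matrix.")
  }
  n <- nrow(dm)
  if (n < 2) abort("Need at least 2 samples to cluster.")
  labels <- rownames(dm) %||% as.character(seq_len(n))
  diag(dm) <- Inf

  # active clusters indexed by creation order; negative code = singleton leaf
  code <- -seq_len(n)
  size <- rep(1L, n)
  active <- rep(TRUE, n)
  cur <- dm
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)

  for (step in seq_len(n - 1)) {
    idx <- which(active)
    sub <- cur[idx, idx, drop = FALSE]
    best <- Inf
    bi <- bj <- 0L
    for (a in seq_along(idx)) {
      for (b in seq_along(idx)) {
        if (b <= a) next
        if (sub[a, b] < best) {
          best <- sub[a, b]
          bi <- idx[a]
          bj <- idx[b]
        }
      }
    }
    pair <- sort_merge_pair(code[bi], code[bj])
    merge[step, ] <- pair
    height[step] <- best
    # linkage update against every other active cluster
    others <- setdiff(idx, c(bi, bj))
    newd <- rep(Inf, ncol(cur))
    for (k in others) {
      newd[k] <- switch(linkage,
        average = (size[bi] * cur[bi, k] + size[bj] * cur[bj, k]) / (size[bi] + size[bj]),
        complete = max(cur[bi, k], cur[bj, k])
      )
    }
    # the merged cluster replaces slot bi (keeps earliest-created priority)
    cur[bi, ] <- newd
    cur[, bi] <- newd
    cur[bi, bi] <- Inf
    active[bj] <- FALSE
    code[bi] <- step
    size[bi] <- size[bi] + size[bj]
  }

  tree <- structure(list(merge = merge, height = height,
                         order = dendrogram_leaf_order(merge),
                         labels = labels, method = linkage,
                         call = match.call(),
                         dist.method = attr(d, "method") %||% "unknown"),
                    class = "hclust")
  tree
}

# hclust row convention: singletons before merged clusters, ascending within kind
sort_merge_pair <- function(a, b) {
  both_neg <- a < 0 && b < 0
  if ((both_neg && abs(a) > abs(b)) || (a > 0 && b < 0) || (a > 0 && b > 0 && a > b)) {
    c(b, a)
  } else {
    c(a, b)
  }
}

dendrogram_leaf_order <- function(merge) {
  expand <- function(i) {
    if (i < 0) return(-i)
    c(expand(merge[i, 1]), expand(merge[i, 2]))
  }
  expand(nrow(merge))
}

#' Count upper/lower sample pairs that are dendrogram siblings
#'
#' A subject's two samples "cluster together" when they are siblings: their
#' first merge in the dendrogram is with each other, before either joins any
#' other cluster.  Subjects represented at only one site are excluded from
#' the denominator with a warning.
#'
#' @param tree An `hclust`-class dendrogram whose labels are sample ids.
#' @param ann Sample annotation.
#' @return Integer sibling-pair count, with the number of evaluable pairs in
#'   the `"n_pairs"` attribute.
#' @export
pairing_count <- function(tree, ann) {
  ann <- validate_annotation(ann)
  labels <- tree$labels
  if (is.null(labels)) abort("Dendrogram has no leaf labels.")
  miss <- setdiff(labels, ann$sample_id)
  if (length(miss) > 0) {
    abort(paste0("Leaf sample(s) missing from annotation: ", paste(miss, collapse = ", ")))
  }
  leaf_ann <- ann[match(labels, ann$sample_id), ]
  sub_tab <- table(leaf_ann$subject_id)
  counts_site <- tapply(leaf_ann$site, leaf_ann$subject_id,
                        function(s) all(c("upper", "lower") %in% s))
  paired <- names(counts_site)[counts_site]
  lone <- setdiff(names(sub_tab), paired)
  lone <- lone[lone %in% leaf_ann$subject_id[leaf_ann$group == "smoker"]]
  if (length(lone) > 0) {
    warn(paste0("Subject(s) with a missing site excluded from pairing: ",
                paste(lone, collapse = ", ")))
  }
  k <- 0L
  for (row in seq_len(nrow(tree$merge))) {
    a <- tree$merge[row, 1]
    b <- tree$merge[row, 2]
    if (a < 0 && b < 0) {
      sa <- leaf_ann$subject_id[-a]
      sb <- leaf_ann$subject_id[-b]
      if (sa == sb && leaf_ann$site[-a] != leaf_ann$site[-b]) k <- k + 1L
    }
  }
  structure(as.integer(k), n_pairs = length(paired))
}

#' Random same-size probe lists from a filtered universe
#'
#' Samples `B` lists uniformly without replacement from `universe` minus
#' `exclude`; with `exclude` set to the signature this reproduces the
#' "random gene lists of equal size, signature excluded" null construction.
#'
#' @param universe Character vector of eligible probe ids.
#' @param exclude Probe ids never to include (default none).
#' @param size Probes per list.
#' @param B Number of lists.
#' @param seed Optional integer seed (the global RNG state is left alone).
#' @return List of `B` character vectors.
#' @export
random_probe_lists <- function(universe, exclude = character(), size, B, seed = NULL) {
  eligible <- setdiff(universe, exclude)
  if (length(eligible) < size) {
    abort(sprintf("Universe minus exclusions has %d probes, need %d.",
                  length(eligible), size))
  }
  draw <- function() replicate(B, sample(eligible, size), simplify = FALSE)
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Add-one empirical p-value
#'
#' `(1 + #\{null beats observed\}) / (B + 1)`: the observed statistic is
#' counted as one more draw from the null, so the p-value is never zero and
#' zero exceedances among B = 100 lists give 1/101, consistent with
#' reporting a bound rather than p = 0.
#'
#' @param null_stats Numeric vector of null statistics (length B).
#' @param observed Observed statistic.
#' @param direction `"ge"`: extreme means null >= observed (e.g. pairing
#'   counts); `"le"`: null <= observed (e.g. vector-length medians).
#' @return The empirical p-value in (0, 1\].
#' @export
empirical_p <- function(null_stats, observed, direction = c("ge", "le")) {
  direction <- match.arg(direction)
  if (length(null_stats) == 0) abort("Need at least one null statistic.")
  hits <- if (direction == "ge") sum(null_stats >= observed) else sum(null_stats <= observed)
  (1 + hits) / (length(null_stats) + 1)
}

#' Sibling-pairing permutation test against random probe lists
#'
#' Computes the observed sibling-pairing count on the signature list, then
#' the same count on `B` random lists of identical size drawn from the
#' filtered universe (signature excluded).  The empirical p-value uses the
#' add-one convention `(1 + #\{null >= observed\}) / (B + 1)`, so it is never
#' zero; with B = 100 and no null reaching the observed count it equals
#' 1/101.
#'
#' @param x Log2-scale expression table containing the paired samples.
#' @param ann Sample annotation.
#' @param signature Character vector of signature probe ids.
#' @param universe Eligible probe universe (e.g. the present-filtered ids).
#' @param B Number of random lists (default 100).
#' @param method Correlation type for the distance.
#' @param linkage Linkage for the clustering.
#' @param seed Optional integer seed for the random lists.
#' @return A `pairing_null` object: observed count, null counts, empirical p.
#' @export
pairing_permutation_test <- function(x, ann, signature, universe, B = 100,
                                     method = c("pearson", "spearman"),
                                     linkage = c("average", "complete"),
                                     seed = NULL) {
  method <- match.arg(method)
  linkage <- match.arg(linkage)
  count_for <- function(probes) {
    tree <- hierarchical_cluster(correlation_distance(x, probes, method), linkage)
    pairing_count(tree, ann)
  }
  observed <- count_for(signature)
  lists <- random_probe_lists(universe, exclude = signature,
                              size = length(signature), B = B, seed = seed)
  null_counts <- vapply(lists, function(p) as.integer(count_for(p)), integer(1))
  structure(list(observed_k = as.integer(observed),
                 n_pairs = attr(observed, "n_pairs"),
                 null_counts = null_counts,
                 B = as.integer(B),
                 empirical_p = empirical_p(null_counts, observed, "ge"),
                 method = method, linkage = linkage,
                 signature_size = length(signature), seed = seed),
            class = "pairing_null")
}

#' @export
print.pairing_null <- function(x, ...) {
  cat(sprintf("Sibling pairing: %d of %d pairs (signature of %d probes, %s/%s)\n",
              x$observed_k, x$n_pairs, x$signature_size, x$method, x$linkage))
  cat(sprintf("Null over %d random lists: max %d, empirical p = %.4g\n",
              x$B, max(x$null_counts), x$empirical_p))
  invisible(x)
}

#' @export
tidy.pairing_null <- function(x, ...) {
  tibble(replicate = seq_len(x$B), pairing_count = x$null_counts)
}

#' @export
glance.pairing_null <- function(x, ...) {
  tibble(observed_k = x$observed_k, n_pairs = x$n_pairs, B = x$B,
         null_max = max(x$null_counts), null_median = median(x$null_counts),
         empirical_p = x$empirical_p, method = x$method, linkage = x$linkage,
         signature_size = x$signature_size)
}

#' @param object A `pairing_null` object.
#' @param ... Ignored.
#' @describeIn pairing_permutation_test Null-distribution histogram with the
#'   observed count marked.
#' @export
autoplot.pairing_null <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pairing_count)) +
    ggplot2::geom_bar(fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$observed_k, colour = "red",
                        linetype = 2) +
    ggplot2::labs(x = "sibling pairs on random lists",
                  y = "number of lists",
                  title = sprintf("Observed %d of %d pairs; empirical p = %.3g",
                                  object$observed_k, object$n_pairs,
                                  object$empirical_p)) +
    ggplot2::theme_minimal()
}

#' Export a dendrogram as a newick string
#'
#' @param tree An `hclust`-class dendrogram.
#' @param path Optional file to write to.
#' @return The newick string, invisibly when writing to a file.
#' @export
dendrogram_newick <- function(tree, path = NULL) {
  phy <- ape::as.phylo(tree)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}
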