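# Small fixtures and independent oracles shared across test files.

# tiny expression table from a plain matrix
tiny_expr <- function(values, probe_ids = NULL, sample_ids = NULL,
                      scale = "linear") {
  values <- as.matrix(values)
  rownames(values) <- probe_ids %||% sprintf("g%02d", seq_len(nrow(values)))
  colnames(values) <- sample_ids %||% sprintf("s%02d", seq_len(ncol(values)))
  expression_table(values, scale = scale)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# annotation for n paired subjects (samples <subj>_upper / <subj>_lower)
paired_ann <- function(n) {
  subj <- sprintf("SM%02d", seq_len(n))
  tibble::tibble(
    sample_id = as.vector(rbind(paste0(subj, "_upper"), paste0(subj, "_lower"))),
    subject_id = rep(subj, each = 2),
    site = rep(c("upper", "lower"), n),
    group = "smoker"
  )
}

# log2-scale expression table for paired subjects from upper/lower matrices
paired_expr <- function(upper, lower, probe_ids = NULL) {
  n <- ncol(upper)
  vals <- matrix(0, nrow(upper), 2 * n)
  vals[, seq(1, 2 * n, 2)] <- upper
  vals[, seq(2, 2 * n, 2)] <- lower
  subj <- sprintf("SM%02d", seq_len(n))
  colnames(vals) <- as.vector(rbind(paste0(subj, "_upper"), paste0(subj, "_lower")))
  rownames(vals) <- probe_ids %||% sprintf("g%02d", seq_len(nrow(vals)))
  expression_table(vals, scale = "log2")
}

# brute-force BH step-up: adj_(i) = min_{j >= i} m * p_(j) / j, capped at 1
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    js <- seq(i, m)
    adj[o[i]] <- min(1, min(m * p[o[js]] / js))
  }
  adj
}

# independent naive agglomeration returning the set of sibling leaf pairs
# and the merge heights; written against cluster *sets*, not merge codes
sibling_oracle <- function(dm, linkage = "average") {
  n <- nrow(dm)
  clusters <- lapply(seq_len(n), identity)
  d <- dm
  diag(d) <- Inf
  sibs <- list()
  heights <- numeric(0)
  while (length(clusters) > 1) {
    k <- length(clusters)
    best <- Inf; bi <- bj <- 0
    for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
      dij <- cluster_dist(d, clusters[[i]], clusters[[j]], linkage)
      if (dij < best) { best <- dij; bi <- i; bj <- j }
    }
    if (length(clusters[[bi]]) == 1 && length(clusters[[bj]]) == 1) {
      sibs[[length(sibs) + 1]] <- sort(c(clusters[[bi]], clusters[[bj]]))
    }
    heights <- c(heights, best)
    merged <- c(clusters[[bi]], clusters[[bj]])
    clusters <- c(clusters[-c(bi, bj)], list(merged))
    # contract: candidate pairs are scanned by lowest contained leaf index
    clusters <- clusters[order(vapply(clusters, min, numeric(1)))]
  }
  list(siblings = sibs, heights = sort(heights))
}

cluster_dist <- function(d, a, b, linkage) {
  vals <- d[a, b, drop = FALSE]
  if (linkage == "average") mean(vals) else max(vals)
}

# oracle sibling-pair count for a paired design with samples in helper order
oracle_pairing_count <- function(dm, n_subj, linkage = "average") {
  sibs <- sibling_oracle(dm, linkage)$siblings
  sum(vapply(sibs, function(p) ceiling(p[1] / 2) == ceiling(p[2] / 2), logical(1)))
}
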