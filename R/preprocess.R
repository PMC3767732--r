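# Median normalization, log transform and present-call filtering.
#
# The normalization follows the classic GeneSpring/MAS5 recipe: each chip is
# divided by its own median intensity, then each probe by its median across
# samples.  Both steps operate on linear-scale intensities; downstream
# correlation / clustering / PCA work on log2 of the normalized values.

#' Per-chip median normalization
#'
#' Divides every sample (column) by that sample's median intensity, so that
#' afterwards every column median equals 1.  Idempotent.
#'
#' @param x A linear-scale expression table.
#' @return The normalized expression table (still linear scale).
#' @export
normalize_per_chip <- function(x) {
  validate_expression(x)
  if (expr_scale(x) != "linear") abort("Per-chip normalization needs linear-scale intensities.")
  for (s in sample_ids(x)) {
    med <- median(x[[s]])
    if (!is.finite(med) || med <= 0) {
      abort(sprintf("Sample '%s' has non-positive median intensity (%g).", s, med))
    }
    x[[s]] <- x[[s]] / med
  }
  x
}

#' Per-gene median normalization
#'
#' Divides every probe (row) by its median across all samples.  Probes whose
#' median is zero cannot be scaled; they are left untouched, flagged in the
#' `"zero_median_probes"` attribute and reported.
#'
#' @param x A linear-scale expression table, typically already per-chip
#'   normalized.
#' @return Normalized expression table; every non-degenerate row has median 1.
#' @export
normalize_per_gene <- function(x) {
  validate_expression(x)
  if (expr_scale(x) != "linear") abort("Per-gene normalization needs linear-scale intensities.")
  vals <- expr_values(x)
  med <- apply(vals, 1, median)
  zero <- med <= 0
  if (any(zero)) {
    inform(sprintf("normalize_per_gene: %d probe(s) with zero median left unscaled (%s%s)",
                   sum(zero), paste(head(rownames(vals)[zero], 5), collapse = ", "),
                   if (sum(zero) > 5) ", ..." else ""))
  }
  scaled <- vals / ifelse(zero, 1, med)
  out <- expression_table(scaled, scale = "linear")
  attr(out, "zero_median_probes") <- rownames(vals)[zero]
  out
}

#' Floored log2 transform
#'
#' Replaces every linear intensity v by log2(max(v, floor)); the floor keeps
#' zeros and near-zero intensities from producing -Inf.
#'
#' @param x A linear-scale expression table.
#' @param floor Positive lower clamp applied before taking logs.
#' @return A log2-scale expression table.
#' @export
log2_transform <- function(x, floor = 0.01) {
  validate_expression(x)
  if (expr_scale(x) != "linear") abort("Input is already on the log2 scale.")
  if (!is.numeric(floor) || length(floor) != 1 || floor <= 0) abort("`floor` must be a positive number.")
  for (s in sample_ids(x)) x[[s]] <- log2(pmax(x[[s]], floor))
  attr(x, "scale") <- "log2"
  x
}

#' Fallback present calls from intensity
#'
#' When no detection-call matrix is available, a value is called present when
#' it exceeds its sample's `percentile`-th intensity percentile.  Cohorts
#' generated by [generate_cohort()] carry explicit calls, so this rule is only
#' a convenience for matrices that arrive without one.
#'
#' @param x A linear-scale expression table.
#' @param percentile Per-sample percentile (0-100) used as the threshold.
#' @return A detection tibble (probe_id + logical sample columns).
#' @export
detect_present <- function(x, percentile = 10) {
  validate_expression(x)
  det <- tibble(probe_id = x$probe_id)
  for (s in sample_ids(x)) {
    thr <- quantile(x[[s]], probs = percentile / 100, names = FALSE)
    det[[s]] <- x[[s]] > thr
  }
  det
}

#' Present-call filter
#'
#' Keeps a probe when, in at least one of the given sample groups, the
#' fraction of present calls reaches `min_fraction` (comparison is `>=`; the
#' equivalent count requirement is `ceiling(min_fraction * group size)`).
#' With the site groups this is the "present in at least 20% of the upper or
#' lower lobe samples" rule; with smoker/nonsmoker groups, its case/control
#' analogue.
#'
#' @param x Expression table (used only for the probe universe and axis
#'   checks).
#' @param detection Detection tibble matching `x`'s axes, or `NULL` to fall
#'   back on [detect_present()].
#' @param groups Named list of non-empty character vectors of sample ids.
#' @param min_fraction Minimum present fraction within a group (default 0.2).
#' @param fallback_percentile Passed to [detect_present()] when `detection`
#'   is `NULL`.
#' @return Character vector of retained probe ids, in `x`'s probe order, with
#'   the groups' OR rule applied.
#' @export
present_filter <- function(x, detection = NULL, groups, min_fraction = 0.2,
                           fallback_percentile = 10) {
  validate_expression(x)
  if (!is.list(groups) || length(groups) == 0) abort("`groups` must be a non-empty list.")
  if (is.null(detection)) detection <- detect_present(x, percentile = fallback_percentile)
  if (!identical(detection$probe_id, x$probe_id)) {
    abort("Detection matrix probes do not match the expression table.")
  }
  for (g in seq_along(groups)) {
    ids <- groups[[g]]
    if (length(ids) == 0) abort("Empty sample group in present filter.")
    miss <- setdiff(ids, names(detection))
    if (length(miss) > 0) {
      abort(paste0("Sample(s) absent from detection matrix: ", paste(miss, collapse = ", ")))
    }
  }
  keep <- rep(FALSE, nrow(x))
  for (ids in groups) {
    frac <- rowMeans(as.matrix(detection[ids]))
    keep <- keep | (frac >= min_fraction)
  }
  x$probe_id[keep]
}
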