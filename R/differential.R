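# Paired and two-group differential tests, FDR control, signature derivation.

#' Subset an expression table to a probe list
#'
#' @param x Expression table.
#' @param probes Character vector of probe ids; every id must resolve.
#' @return Expression table restricted to those probes (matrix order kept).
#' @export
filter_probes <- function(x, probes) {
  if (is.null(probes)) return(x)
  miss <- setdiff(probes, x$probe_id)
  if (length(miss) > 0) {
    abort(paste0("Probe id(s) not in expression table: ",
                 paste(head(miss, 5), collapse = ", "),
                 if (length(miss) > 5) ", ..." else ""))
  }
  sc <- expr_scale(x)
  out <- x[x$probe_id %in% probes, ]
  attr(out, "scale") <- sc
  out
}

# upper/lower matrices for the paired subjects, columns aligned by subject
paired_site_values <- function(x, ann) {
  ann <- validate_annotation(ann)
  present <- ann[ann$sample_id %in% sample_ids(x), ]
  subj <- sort(unique(present$subject_id))
  complete <- vapply(subj, function(s) {
    all(c("upper", "lower") %in% present$site[present$subject_id == s])
  }, logical(1))
  incomplete <- subj[!complete &
                       subj %in% present$subject_id[present$group == "smoker"]]
  if (length(incomplete) > 0) {
    warn(paste0("Subject(s) without a complete upper/lower pair skipped: ",
                paste(incomplete, collapse = ", ")))
  }
  subj <- subj[complete]
  vals <- expr_values(x)
  up <- vapply(subj, function(s) present$sample_id[present$subject_id == s & present$site == "upper"], character(1))
  lo <- vapply(subj, function(s) present$sample_id[present$subject_id == s & present$site == "lower"], character(1))
  list(subjects = subj, upper = vals[, up, drop = FALSE], lower = vals[, lo, drop = FALSE])
}

#' Classical paired t-test per probe
#'
#' For every probe, a two-sided paired t-test on the per-subject
#' (upper - lower) log2 differences, with n - 1 degrees of freedom.  Probes
#' whose differences have zero variance are flagged `degenerate` and assigned
#' p = 1.
#'
#' @param x Log2-scale expression table.
#' @param ann Sample annotation defining the pairing.
#' @param probes Optional probe list restriction.
#' @return A tibble with columns `probe_id`, `effect` (mean paired log2
#'   difference), `t_stat`, `df`, `p`, `p_bh`, `q`, `degenerate`.
#' @export
paired_t <- function(x, ann, probes = NULL) {
  if (expr_scale(x) != "log2") abort("paired_t expects log2-scale values.")
  x <- filter_probes(x, probes)
  ps <- paired_site_values(x, ann)
  n <- length(ps$subjects)
  if (n < 2) abort("Need at least 2 complete upper/lower pairs.")
  d <- ps$upper - ps$lower
  eff <- rowMeans(d)
  sdd <- apply(d, 1, sd)
  degen <- sdd == 0
  t_stat <- ifelse(degen, NA_real_, eff / (sdd / sqrt(n)))
  p <- ifelse(degen, 1, 2 * pt(-abs(t_stat), df = n - 1))
  res <- tibble(probe_id = rownames(d), effect = unname(eff),
                t_stat = unname(t_stat), df = n - 1, p = unname(p))
  res$p_bh <- bh_adjust(res$p)
  res$q <- if (nrow(res) >= 10) storey_q(res$p) else NA_real_
  res$degenerate <- degen
  res
}

# scaled chi-square / F moment fit of (d0, s0^2) across probe variances
fit_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 3) abort("Need at least 3 positive probe variances to estimate the prior.")
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- var(e) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # no excess dispersion of log s^2: all true variances equal s0^2, whose
    # maximum-likelihood estimate is then the plain mean of the s^2
    d0 <- Inf
    s0_sq <- mean(s2[ok])
  }
  list(d0 = d0, s0_sq = s0_sq)
}

# Newton solve of trigamma(y) == x, decreasing in y
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (!is.finite(y) || y <= 0) {
      y <- 1 / x
      break
    }
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Empirical-Bayes moderated t-test
#'
#' Shrinks every probe's sample variance towards a common prior estimated
#' from all probes: the posterior variance is
#' `(d0 * s0^2 + d * s^2) / (d0 + d)`, a convex combination of the prior
#' `s0^2` (weight `d0/(d0+d)`) and the probe variance `s^2` (weight
#' `d/(d0+d)`), and the t-statistic built from it has `d0 + d` degrees of
#' freedom.  The hyperparameters `(d0, s0^2)` are estimated by matching the
#' first two moments of `log s^2` to a scaled chi-square model.
#'
#' @inheritParams paired_t
#' @param design `"paired"` (upper vs lower differences within subject) or
#'   `"two_group"` (smoker vs nonsmoker, pooled variance).
#' @param d0,s0_sq Optional forced hyperparameters; `d0 = 0` reproduces the
#'   classical test, `d0 = Inf` uses the prior variance alone.
#' @return An object of class `moderated_fit`; `tidy()` returns the per-probe
#'   table, `glance()` the hyperparameters.
#' @export
moderated_t <- function(x, ann, probes = NULL, design = c("paired", "two_group"),
                        d0 = NULL, s0_sq = NULL) {
  design <- match.arg(design)
  if (expr_scale(x) != "log2") abort("moderated_t expects log2-scale values.")
  x <- filter_probes(x, probes)
  if (nrow(x) < 3) abort("Need at least 3 probes to estimate variance hyperparameters.")
  if (design == "paired") {
    ps <- paired_site_values(x, ann)
    n <- length(ps$subjects)
    if (n < 2) abort("Need at least 2 complete upper/lower pairs.")
    d <- ps$upper - ps$lower
    eff <- rowMeans(d)
    s2 <- apply(d, 1, var)
    df_resid <- n - 1
    se_scale <- 1 / sqrt(n)
    ids <- rownames(d)
  } else {
    ann <- validate_annotation(ann)
    vals <- expr_values(x)
    ga <- intersect(ann$sample_id[ann$group == "smoker"], colnames(vals))
    gb <- intersect(ann$sample_id[ann$group == "nonsmoker"], colnames(vals))
    if (length(ga) < 2 || length(gb) < 2) abort("Both groups need at least 2 samples.")
    a <- vals[, ga, drop = FALSE]
    b <- vals[, gb, drop = FALSE]
    eff <- rowMeans(a) - rowMeans(b)
    va <- apply(a, 1, var)
    vb <- apply(b, 1, var)
    df_resid <- length(ga) + length(gb) - 2
    s2 <- ((length(ga) - 1) * va + (length(gb) - 1) * vb) / df_resid
    se_scale <- sqrt(1 / length(ga) + 1 / length(gb))
    ids <- rownames(vals)
  }
  prior <- if (is.null(d0) || is.null(s0_sq)) fit_variance_prior(s2, df_resid) else list(d0 = d0, s0_sq = s0_sq)
  w <- if (is.infinite(prior$d0)) 1 else prior$d0 / (prior$d0 + df_resid)
  s2_post <- w * prior$s0_sq + (1 - w) * s2
  df_total <- prior$d0 + df_resid
  degen <- s2_post <= 0
  t_stat <- ifelse(degen, NA_real_, eff / (sqrt(s2_post) * se_scale))
  p <- ifelse(degen, 1,
              if (is.infinite(df_total)) 2 * stats::pnorm(-abs(t_stat))
              else 2 * pt(-abs(t_stat), df = df_total))
  tab <- tibble(probe_id = ids, effect = unname(eff), t_stat = unname(t_stat),
                df = df_total, p = unname(p))
  tab$p_bh <- bh_adjust(tab$p)
  tab$q <- if (nrow(tab) >= 10) storey_q(tab$p) else NA_real_
  tab$degenerate <- degen
  structure(list(table = tab, d0 = prior$d0, s0_sq = prior$s0_sq,
                 s2 = s2, s2_post = s2_post, df_resid = df_resid,
                 design = design),
            class = "moderated_fit")
}

#' @export
tidy.moderated_fit <- function(x, ...) x$table

#' @export
glance.moderated_fit <- function(x, ...) {
  tibble(d0 = x$d0, s0_sq = x$s0_sq, df_resid = x$df_resid,
         n_probes = nrow(x$table), design = x$design)
}

#' @export
print.moderated_fit <- function(x, ...) {
  cat(sprintf("Moderated %s fit: %d probes, d0 = %.3g, s0^2 = %.3g, residual df = %g\n",
              x$design, nrow(x$table), x$d0, x$s0_sq, x$df_resid))
  invisible(x)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Adjusted p-values, capped at 1, monotone in p-value rank.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0 | p > 1)) {
    abort("p-values must be numeric in [0, 1].")
  }
  p.adjust(p, method = "BH")
}

#' Storey q-values with the single-lambda pi0 estimator
#'
#' Estimates the null proportion as
#' `pi0 = #\{p > lambda\} / (m * (1 - lambda))` (clipped into (0, 1\]) and
#' returns `q = pi0 * p_bh`, which equals the rank-monotone
#' `pi0 * m * p_(i) / i` rule.  Forcing `pi0 = 1` reduces to BH.
#'
#' @inheritParams bh_adjust
#' @param lambda Tuning point of the pi0 estimator (default 0.5).
#' @param pi0 Optional forced null proportion.
#' @return Vector of q-values.
#' @export
storey_q <- function(p, lambda = 0.5, pi0 = NULL) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0 | p > 1)) {
    abort("p-values must be numeric in [0, 1].")
  }
  m <- length(p)
  if (m < 10) abort("q-value estimation needs at least 10 p-values.")
  if (is.null(pi0)) pi0 <- sum(p > lambda) / (m * (1 - lambda))
  pi0 <- min(1, max(pi0, 1 / m))
  pmin(pi0 * p.adjust(p, method = "BH"), 1)
}

#' Direction-agnostic fold change between two groups
#'
#' For each probe, `max(mean_a / mean_b, mean_b / mean_a)` of the linear
#' group means, so the value is always >= 1 whichever way the change goes.
#' Probes with a non-positive group mean get `NA` and a flag.
#'
#' @param x Linear-scale expression table (typically median-normalized).
#' @param ann Sample annotation.
#' @param groups Length-2 character vector of group labels (default
#'   smoker/nonsmoker).
#' @param probes Optional probe restriction.
#' @return Tibble with `probe_id`, `mean_a`, `mean_b`, `fc`, `degenerate`.
#' @export
symmetric_fold_change <- function(x, ann, groups = c("smoker", "nonsmoker"),
                                  probes = NULL) {
  if (expr_scale(x) != "linear") abort("Fold changes are computed on linear-scale values.")
  if (length(groups) != 2) abort("`groups` must name exactly two groups.")
  ann <- validate_annotation(ann)
  x <- filter_probes(x, probes)
  vals <- expr_values(x)
  ga <- intersect(ann$sample_id[ann$group == groups[1]], colnames(vals))
  gb <- intersect(ann$sample_id[ann$group == groups[2]], colnames(vals))
  if (length(ga) == 0 || length(gb) == 0) abort("Both groups need at least one sample.")
  ma <- rowMeans(vals[, ga, drop = FALSE])
  mb <- rowMeans(vals[, gb, drop = FALSE])
  degen <- ma <= 0 | mb <= 0
  fc <- ifelse(degen, NA_real_, pmax(ma / mb, mb / ma))
  tibble(probe_id = rownames(vals), mean_a = unname(ma), mean_b = unname(mb),
         fc = unname(fc), degenerate = unname(degen))
}

#' Derive a smoking-responsive signature from a case/control contrast
#'
#' Applies the published recipe: restrict to probes present in at least
#' `min_fraction` of the smoker or the nonsmoker samples, test smokers
#' against nonsmokers on log2 values, and keep probes with symmetric fold
#' change >= `fc_min` (non-strict) and BH-adjusted p < `p_bh_max` (strict).
#'
#' @param x Linear-scale expression table, already median-normalized.
#' @param detection Optional detection tibble; `NULL` falls back on
#'   [detect_present()].
#' @param ann Sample annotation with both smoker and nonsmoker samples.
#' @param fc_min Minimum symmetric fold change (default 1.5).
#' @param p_bh_max Strict upper bound on BH-adjusted p (default 0.01).
#' @param min_fraction Present-call fraction for the filter (default 0.2).
#' @param method `"moderated"` (default) or `"classical"` two-group test.
#' @param log_floor Floor for the log2 transform.
#' @param name Name attached to the returned list.
#' @return Character vector of signature probe ids (possibly empty, with a
#'   warning), with `name` and the fitted test in attributes.
#' @export
derive_signature <- function(x, detection = NULL, ann, fc_min = 1.5,
                             p_bh_max = 0.01, min_fraction = 0.2,
                             method = c("moderated", "classical"),
                             log_floor = 0.01, name = "derived-signature") {
  method <- match.arg(method)
  ann <- validate_annotation(ann)
  sm <- intersect(ann$sample_id[ann$group == "smoker"], sample_ids(x))
  ns <- intersect(ann$sample_id[ann$group == "nonsmoker"], sample_ids(x))
  if (length(sm) == 0 || length(ns) == 0) abort("Need both smoker and nonsmoker samples.")
  universe <- present_filter(x, detection, groups = list(smoker = sm, nonsmoker = ns),
                             min_fraction = min_fraction)
  xf <- filter_probes(x, universe)
  fit <- if (method == "moderated") {
    moderated_t(log2_transform(xf, floor = log_floor), ann, design = "two_group")
  } else {
    moderated_t(log2_transform(xf, floor = log_floor), ann, design = "two_group",
                d0 = 0, s0_sq = 1)
  }
  fc <- symmetric_fold_change(xf, ann)
  tab <- dplyr::inner_join(fit$table, fc[c("probe_id", "fc")], by = "probe_id")
  keep <- !is.na(tab$fc) & tab$fc >= fc_min & tab$p_bh < p_bh_max
  ids <- tab$probe_id[keep]
  if (length(ids) == 0) warn("derive_signature: no probe passed the thresholds; empty signature.")
  attr(ids, "name") <- name
  attr(ids, "universe_size") <- length(universe)
  attr(ids, "fit") <- fit
  ids
}
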