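# Synthetic paired-cohort generator.
#
# Emulates the structure of a paired upper/lower-lobe small-airway microarray
# study: n paired smokers, a nonsmoker reference cohort, and a planted block
# of smoking-responsive probes.  On the log2 scale a value is
#
#   x[g, s] = mu_g + resp_g * (r_i * beta_g + delta_{i,g})
#             + a_{i,g} + c_{l,g} + eps_{g,s}
#
# with mu_g the baseline abundance, beta_g the canonical response of a
# responsive probe, r_i the subject's overall response magnitude (0 for
# nonsmokers), delta_{i,g} the subject-specific deviation of the response
# pattern (which genes respond, and by how much, differs between smokers;
# shared by a subject's two sites), a_{i,g} a weak genome-wide subject
# background, c_{l,g} a site effect and eps residual array noise.  The
# returned matrix is 2^x (linear intensities).

#' Parameters of the synthetic paired cohort
#'
#' Defaults encode the study conditions the generator emulates: 11 paired
#' smokers, 60 nonsmokers, 529 responsive probes among 5000 (scalable to
#' array size), canonical responses of 1.5-4 fold (0.58-2 log2) with
#' subject response magnitudes between 0.3 and 1.5, and noise scales chosen
#' so that within-subject signature-space correlation (about 0.9) dominates
#' between-subject correlation while random probe lists carry only weak
#' subject structure.
#'
#' @param n_subjects Paired smoker subjects (two samples each).
#' @param n_nonsmokers Nonsmoker subjects (one sample each).
#' @param m_total Total probes, including the guaranteed-absent block.
#' @param m_sig Planted smoking-responsive probes.
#' @param mu_mean,mu_sd Baseline log2 abundance distribution.
#' @param beta_min,beta_max Canonical response magnitude range (log2); the
#'   sign of each responsive probe is random.
#' @param r_min,r_max Subject response-magnitude range.
#' @param sigma_resp SD of the subject-specific response deviation (log2).
#' @param sigma_site SD of the per-site effect (log2).
#' @param sigma_subj_bg SD of the genome-wide subject background (log2).
#' @param sigma_e Residual array noise SD (log2).
#' @param present_prob Probability a probe x sample value is called present.
#' @param n_absent Trailing block of probes with all-absent calls, to give
#'   the present filter something deterministic to drop.
#' @param seed Default seed used by [generate_cohort()].
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_subjects = 11, n_nonsmokers = 60,
                             m_total = 5000, m_sig = 529,
                             mu_mean = 6, mu_sd = 1.5,
                             beta_min = 0.58, beta_max = 2.0,
                             r_min = 0.3, r_max = 1.5,
                             sigma_resp = 0.5,
                             sigma_site = 0.05, sigma_subj_bg = 0.05,
                             sigma_e = 0.25,
                             present_prob = 0.85, n_absent = 50,
                             seed = NULL) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_nonsmokers = as.integer(n_nonsmokers),
              m_total = as.integer(m_total), m_sig = as.integer(m_sig),
              mu_mean = mu_mean, mu_sd = mu_sd,
              beta_min = beta_min, beta_max = beta_max,
              r_min = r_min, r_max = r_max,
              sigma_resp = sigma_resp, sigma_site = sigma_site,
              sigma_subj_bg = sigma_subj_bg, sigma_e = sigma_e,
              present_prob = present_prob, n_absent = as.integer(n_absent),
              seed = seed)
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  if (cfg$n_subjects < 1) abort("Need at least one paired subject.")
  if (cfg$n_nonsmokers < 0) abort("n_nonsmokers cannot be negative.")
  if (cfg$m_sig < 0 || cfg$n_absent < 0) abort("Probe counts cannot be negative.")
  if (cfg$m_sig + cfg$n_absent > cfg$m_total) {
    abort("m_sig + n_absent exceeds m_total.")
  }
  sds <- c(cfg$mu_sd, cfg$sigma_resp, cfg$sigma_site, cfg$sigma_subj_bg, cfg$sigma_e)
  if (any(sds < 0)) abort("All SDs must be >= 0.")
  if (cfg$beta_min > cfg$beta_max || cfg$r_min > cfg$r_max) {
    abort("Range parameters must satisfy min <= max.")
  }
  if (cfg$present_prob < 0 || cfg$present_prob > 1) abort("present_prob must be in [0, 1].")
  invisible(cfg)
}

#' Generate a synthetic paired cohort
#'
#' Draws expression, detection calls, annotation and the planted signature
#' under the model described in [synthetic_config()].  Smoker subjects get
#' one upper and one lower sample; nonsmokers a single (lower) sample with
#' zero response.  Bit-reproducible given the config and seed; the global
#' RNG state is untouched.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed; defaults to the config's seed and must be
#'   supplied in one of the two places.
#' @return A `synthetic_cohort` list: `expression` (linear-scale table),
#'   `detection`, `annotation`, `signature` (planted probe ids), `config`.
#' @export
generate_cohort <- function(config = synthetic_config(), seed = config$seed) {
  validate_synthetic_config(config)
  if (is.null(seed)) abort("A seed is required (in the config or as an argument).")
  withr::with_seed(as.integer(seed), generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  m <- cfg$m_total
  probe_ids <- sprintf("P%05d", seq_len(m))
  absent_idx <- if (cfg$n_absent > 0) seq(m - cfg$n_absent + 1, m) else integer(0)
  eligible <- setdiff(seq_len(m), absent_idx)

  mu <- stats::rnorm(m, cfg$mu_mean, cfg$mu_sd)
  sig_idx <- sort(sample(eligible, cfg$m_sig))
  beta <- numeric(m)
  beta[sig_idx] <- sample(c(-1, 1), cfg$m_sig, replace = TRUE) *
    stats::runif(cfg$m_sig, cfg$beta_min, cfg$beta_max)
  r <- stats::runif(cfg$n_subjects, cfg$r_min, cfg$r_max)
  c_site <- list(upper = stats::rnorm(m, 0, cfg$sigma_site),
                 lower = stats::rnorm(m, 0, cfg$sigma_site))

  n_samples <- 2 * cfg$n_subjects + cfg$n_nonsmokers
  vals <- matrix(0, m, n_samples)
  sample_id <- character(n_samples)
  subject_id <- character(n_samples)
  site <- character(n_samples)
  group <- character(n_samples)

  col <- 0
  for (i in seq_len(cfg$n_subjects)) {
    subj <- sprintf("SM%02d", i)
    a <- stats::rnorm(m, 0, cfg$sigma_subj_bg)
    delta <- numeric(m)
    delta[sig_idx] <- stats::rnorm(cfg$m_sig, 0, cfg$sigma_resp)
    base <- mu + r[i] * beta + delta + a
    for (l in c("upper", "lower")) {
      col <- col + 1
      vals[, col] <- base + c_site[[l]] + stats::rnorm(m, 0, cfg$sigma_e)
      sample_id[col] <- paste0(subj, "_", l)
      subject_id[col] <- subj
      site[col] <- l
      group[col] <- "smoker"
    }
  }
  for (j in seq_len(cfg$n_nonsmokers)) {
    col <- col + 1
    subj <- sprintf("NS%02d", j)
    a <- stats::rnorm(m, 0, cfg$sigma_subj_bg)
    vals[, col] <- mu + a + c_site$lower + stats::rnorm(m, 0, cfg$sigma_e)
    sample_id[col] <- subj
    subject_id[col] <- subj
    site[col] <- "lower"
    group[col] <- "nonsmoker"
  }

  lin <- 2^vals
  rownames(lin) <- probe_ids
  colnames(lin) <- sample_id

  det_mat <- matrix(stats::runif(m * n_samples) < cfg$present_prob, m, n_samples)
  det_mat[absent_idx, ] <- FALSE
  detection <- tibble(probe_id = probe_ids)
  for (s in seq_len(n_samples)) detection[[sample_id[s]]] <- det_mat[, s]

  structure(list(
    expression = expression_table(lin, scale = "linear"),
    detection = detection,
    annotation = tibble(sample_id = sample_id, subject_id = subject_id,
                        site = site, group = group),
    signature = probe_ids[sig_idx],
    config = cfg
  ), class = "synthetic_cohort")
}

#' Generate a null cohort with no subject-level structure
#'
#' Same machinery as [generate_cohort()] but with every response magnitude
#' forced to zero and no subject background or response deviation, so
#' nothing beyond chance links a subject's two samples.
#'
#' @inheritParams generate_cohort
#' @return A `synthetic_cohort`; its `signature` slot still records the
#'   would-be responsive probes (they carry no signal).
#' @export
generate_null_cohort <- function(config = synthetic_config(), seed = config$seed) {
  validate_synthetic_config(config)
  cfg <- config
  cfg$r_min <- 0
  cfg$r_max <- 0
  cfg$sigma_subj_bg <- 0
  cfg$sigma_resp <- 0
  if (is.null(seed)) abort("A seed is required (in the config or as an argument).")
  withr::with_seed(as.integer(seed), generate_cohort_impl(cfg))
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Synthetic cohort: %d paired smokers + %d nonsmokers, %d probes (%d responsive, %d always-absent)\n",
              cfg$n_subjects, cfg$n_nonsmokers, cfg$m_total, cfg$m_sig, cfg$n_absent))
  invisible(x)
}

#' Write the four cohort artifacts to a directory
#'
#' Emits `expression.tsv`, `detection.tsv`, `annotation.tsv` and
#' `signature.txt` in the package's plain-text formats.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_expression(cohort$expression, file.path(dir, "expression.tsv"))
  write_detection(cohort$detection, file.path(dir, "detection.tsv"))
  write_annotation(cohort$annotation, file.path(dir, "annotation.tsv"))
  write_probe_list(cohort$signature, file.path(dir, "signature.txt"))
  invisible(dir)
}
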