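# End-to-end orchestration: cohort -> preprocess -> signature -> concordance
# -> multivariate -> report.

default_pipeline_config <- function() {
  list(
    cohort = list(type = "synthetic"),
    analysis = list(
      min_fraction = 0.2,
      log_floor = 0.01,
      fc_min = 1.5,
      p_bh_max = 0.01,
      B = 100,
      methods = c("pearson", "spearman"),
      linkage = "average",
      k = 3,
      signature_source = NULL   # planted | derived | file (auto-chosen)
    )
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

log_line <- function(stage, ...) {
  kv <- c(...)
  inform(paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " stage=", stage,
                if (length(kv) > 0) paste0(" ", paste(names(kv), kv, sep = "=", collapse = " ")) else ""))
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

#' Run the full paired-concordance pipeline
#'
#' Orchestrates the stages in order: obtain a cohort (synthetic by default,
#' or files named in the config), median-normalize, derive or load the
#' signature, run the sibling-pairing permutation test under every requested
#' correlation method, compute PCA scores and the vector-length null, and
#' write per-stage outputs plus a single machine-readable `report.json`.
#' With the same config and seed the report is byte-identical across runs.
#'
#' @param config A config list or path to a YAML file.  Recognised blocks:
#'   `cohort` (either `type: synthetic` plus [synthetic_config()] overrides,
#'   or paths `expression`, `annotation`, optionally `detection`,
#'   `signature`, with `scale`) and `analysis` (`min_fraction`, `log_floor`,
#'   `fc_min`, `p_bh_max`, `B`, `methods`, `linkage`, `k`,
#'   `signature_source`).
#' @param out_dir Directory for result files (created if needed).
#' @param seed Master integer seed; every stochastic stage derives its own
#'   seed from it.  Mandatory.
#' @return The report, as a list (also written to `out_dir/report.json`).
#' @export
run_pipeline <- function(config = list(), out_dir, seed) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_pipeline_config(), config)
  if (missing(seed) || is.null(seed)) abort("`seed` is mandatory.")
  seed <- as.integer(seed)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  an <- cfg$analysis
  an$methods <- match.arg(as.character(an$methods), c("pearson", "spearman"),
                          several.ok = TRUE)

  ## stage: cohort -----------------------------------------------------------
  cohort <- run_stage("cohort", {
    if (identical(cfg$cohort$type %||% "synthetic", "synthetic")) {
      sc_args <- cfg$cohort[setdiff(names(cfg$cohort), c("type", "seed"))]
      sc <- do.call(synthetic_config, sc_args)
      log_line("cohort", c(type = "synthetic", seed = seed))
      generate_cohort(sc, seed = seed)
    } else {
      log_line("cohort", c(type = "files", expression = cfg$cohort$expression))
      expr <- read_expression(cfg$cohort$expression, scale = cfg$cohort$scale %||% "linear")
      list(expression = expr,
           annotation = read_annotation(cfg$cohort$annotation),
           detection = if (!is.null(cfg$cohort$detection)) read_detection(cfg$cohort$detection),
           signature = if (!is.null(cfg$cohort$signature)) read_probe_list(cfg$cohort$signature),
           config = NULL)
    }
  })
  ann <- cohort$annotation
  paired_ids <- ann$sample_id[ann$subject_id %in% paired_subjects(ann)]

  ## stage: preprocess -------------------------------------------------------
  prep <- run_stage("preprocess", {
    norm_all <- normalize_per_gene(normalize_per_chip(cohort$expression))
    paired_lin <- cohort$expression[c("probe_id", paired_ids)]
    attr(paired_lin, "scale") <- "linear"
    norm_paired <- normalize_per_gene(normalize_per_chip(paired_lin))
    log_paired <- log2_transform(norm_paired, floor = an$log_floor)
    det_paired <- if (!is.null(cohort$detection)) cohort$detection[c("probe_id", paired_ids)]
    upper <- intersect(ann$sample_id[ann$site == "upper"], paired_ids)
    lower <- intersect(ann$sample_id[ann$site == "lower"], paired_ids)
    universe <- present_filter(paired_lin, det_paired,
                               groups = list(upper = upper, lower = lower),
                               min_fraction = an$min_fraction)
    log_line("preprocess", c(n_probes = nrow(cohort$expression),
                             n_filtered = length(universe),
                             min_fraction = an$min_fraction,
                             log_floor = an$log_floor))
    list(norm_all = norm_all, log_paired = log_paired, universe = universe)
  })

  ## stage: signature --------------------------------------------------------
  synthetic_cohort <- identical(cfg$cohort$type %||% "synthetic", "synthetic")
  sig_source <- an$signature_source %||%
    (if (is.null(cohort$signature)) "derived"
     else if (synthetic_cohort) "planted" else "file")
  signature <- run_stage("signature", {
    sig <- switch(sig_source,
      planted = cohort$signature,
      file = cohort$signature,
      derived = derive_signature(prep$norm_all, cohort$detection, ann,
                                 fc_min = an$fc_min, p_bh_max = an$p_bh_max,
                                 min_fraction = an$min_fraction,
                                 log_floor = an$log_floor),
      abort("Unknown signature_source.")
    )
    if (is.null(sig) || length(sig) == 0) abort("No signature available.")
    sig <- intersect(sig, prep$universe)
    log_line("signature", c(source = sig_source, size = length(sig)))
    write_probe_list(sig, file.path(out_dir, "signature.txt"))
    sig
  })

  ## stage: paired differential ---------------------------------------------
  paired_diff <- run_stage("paired_differential", {
    res <- paired_t(filter_probes(prep$log_paired, prep$universe), ann)
    write_results(res, file.path(out_dir, "paired_differential.tsv"))
    log_line("paired_differential",
             c(n_probes = nrow(res), n_bh_significant = sum(res$p_bh < 0.05)))
    res
  })

  ## stage: concordance ------------------------------------------------------
  pairing <- run_stage("concordance", {
    out <- list()
    for (i in seq_along(an$methods)) {
      method <- an$methods[i]
      pt <- pairing_permutation_test(prep$log_paired, ann, signature,
                                     prep$universe, B = an$B, method = method,
                                     linkage = an$linkage, seed = seed + i)
      tree <- hierarchical_cluster(
        correlation_distance(prep$log_paired, signature, method), an$linkage)
      dendrogram_newick(tree, file.path(out_dir, paste0("dendrogram_", method, ".nwk")))
      write_results(pt, file.path(out_dir, paste0("pairing_", method, ".json")))
      log_line("concordance", c(method = method, observed_k = pt$observed_k,
                                empirical_p = signif(pt$empirical_p, 4)))
      out[[method]] <- pt
    }
    out
  })

  ## stage: multivariate -----------------------------------------------------
  multiv <- run_stage("multivariate", {
    pca <- pca_scores(prep$log_paired, signature, k = an$k)
    readr::write_tsv(pca$scores, file.path(out_dir, "pca_scores.tsv"), progress = FALSE)
    vl <- vector_length_null(prep$log_paired, ann, signature, prep$universe,
                             B = an$B, seed = seed + 100)
    write_results(vl, file.path(out_dir, "vector_length.json"))
    log_line("multivariate", c(k = an$k,
                               observed_median = signif(vl$observed_median, 4)))
    list(pca = pca, vl = vl)
  })

  ## stage: report -----------------------------------------------------------
  report <- run_stage("report", {
    rep <- list(
      parameters = list(seed = seed, analysis = an,
                        cohort = if (!is.null(cohort$config)) unclass(cohort$config) else cfg$cohort),
      n_probes_total = nrow(cohort$expression),
      n_probes_filtered = length(prep$universe),
      signature_source = sig_source,
      signature_size = length(signature),
      paired_differential = list(
        n_tested = nrow(paired_diff),
        n_bh_significant_05 = sum(paired_diff$p_bh < 0.05),
        min_p_bh = min(paired_diff$p_bh)
      ),
      pairing = lapply(pairing, function(pt) {
        list(observed_k = pt$observed_k, n_pairs = pt$n_pairs, B = pt$B,
             null_max = max(pt$null_counts), empirical_p = pt$empirical_p)
      }),
      vector_length = list(
        observed_median = multiv$vl$observed_median,
        null_quantiles = as.list(multiv$vl$null_quantiles),
        empirical_proportion = multiv$vl$empirical_proportion
      ),
      pca_variance_fractions = multiv$pca$var_explained
    )
    jsonlite::write_json(rep, file.path(out_dir, "report.json"),
                         digits = NA, auto_unbox = TRUE, pretty = TRUE)
    log_line("report", c(path = file.path(out_dir, "report.json")))
    rep
  })
  invisible(report)
}
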