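# Expression tables, sample annotation, probe lists: construction, validation, I/O.
#
# An expression table is a tibble whose first column is `probe_id` and whose
# remaining columns are numeric sample intensities, with a "scale" attribute
# ("linear" or "log2").  Linear-scale intensities must be non-negative.

VALID_SITES <- c("upper", "lower")
VALID_GROUPS <- c("smoker", "nonsmoker")

#' Build an expression table from a probe-by-sample matrix
#'
#' @param values Numeric matrix, probes in rows (rownames are probe ids),
#'   samples in columns (colnames are sample ids).
#' @param scale `"linear"` (non-negative intensities) or `"log2"`.
#'
#' @return A tibble with a `probe_id` column, one numeric column per sample,
#'   and a `scale` attribute.
#' @export
expression_table <- function(values, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix.")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must carry probe ids as rownames and sample ids as colnames.")
  }
  out <- tibble(probe_id = rownames(values))
  out <- dplyr::bind_cols(out, as_tibble(`dimnames<-`(values, list(NULL, colnames(values)))))
  attr(out, "scale") <- scale
  validate_expression(out)
}

#' Validate an expression table
#'
#' Checks the structural invariants: unique probe and sample ids, all-numeric
#' finite values, non-negative values on the linear scale.
#'
#' @param x An expression table (see [expression_table()]).
#' @return `x`, invisibly unchanged, or an error describing the violation.
#' @export
validate_expression <- function(x) {
  if (!is.data.frame(x) || names(x)[1] != "probe_id") {
    abort("An expression table must have `probe_id` as its first column.")
  }
  scale <- expr_scale(x)
  dup <- x$probe_id[duplicated(x$probe_id)]
  if (length(dup) > 0) {
    abort(paste0("Duplicated probe id(s): ", paste(unique(dup), collapse = ", ")))
  }
  sam <- setdiff(names(x), "probe_id")
  if (length(sam) == 0) abort("Expression table has no sample columns.")
  if (anyDuplicated(sam)) abort("Duplicated sample ids.")
  vals <- expr_values(x)
  if (!is.numeric(vals)) abort("Sample columns must be numeric.")
  if (any(!is.finite(vals))) abort("Expression values must all be finite.")
  if (scale == "linear" && any(vals < 0)) {
    abort("Linear-scale expression values must be non-negative.")
  }
  x
}

#' @rdname validate_expression
#' @export
expr_scale <- function(x) {
  sc <- attr(x, "scale", exact = TRUE) %||% "linear"
  if (!sc %in% c("linear", "log2")) abort("Unknown expression scale.")
  sc
}

#' Extract the numeric probe-by-sample matrix from an expression table
#'
#' @param x An expression table.
#' @return Numeric matrix with probe ids as rownames, sample ids as colnames.
#' @export
expr_values <- function(x) {
  sam <- setdiff(names(x), "probe_id")
  m <- as.matrix(x[sam])
  rownames(m) <- x$probe_id
  m
}

#' @rdname expr_values
#' @export
sample_ids <- function(x) setdiff(names(x), "probe_id")

#' Read a tab-delimited probe-by-sample expression matrix
#'
#' The first column holds probe ids, the header row holds sample ids, fields
#' are tab-separated with "." as the decimal point (UTF-8, no quoting).
#'
#' @param path Path to the TSV file.
#' @inheritParams expression_table
#' @return An expression table; input row and column order is preserved.
#' @export
read_expression <- function(path, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(raw) < 2) abort("Expression file needs a probe id column and at least one sample.")
  names(raw)[1] <- "probe_id"
  for (j in seq(2, ncol(raw))) {
    num <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- which(is.na(num) & !is.na(raw[[j]]))
    if (length(bad) > 0) {
      abort(sprintf("Non-numeric value '%s' at row %d, column '%s' of %s",
                    raw[[j]][bad[1]], bad[1], names(raw)[j], path))
    }
    raw[[j]] <- num
  }
  attr(raw, "scale") <- scale
  validate_expression(raw)
}

#' Write an expression table to TSV
#'
#' @param x An expression table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  validate_expression(x)
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Read or validate a sample annotation table
#'
#' The annotation maps each sample to a subject, a sampling site
#' (`upper`/`lower`) and a group (`smoker`/`nonsmoker`), and thereby defines
#' the upper/lower pairing: a paired subject has exactly one sample per site.
#'
#' @param path Tab-delimited file with columns `sample_id`, `subject_id`,
#'   `site`, `group`.
#' @return A tibble with those four character columns.
#' @export
read_annotation <- function(path) {
  ann <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  validate_annotation(ann)
}

#' @rdname read_annotation
#' @param ann Annotation data frame to validate.
#' @export
validate_annotation <- function(ann) {
  need <- c("sample_id", "subject_id", "site", "group")
  miss <- setdiff(need, names(ann))
  if (length(miss) > 0) abort(paste0("Annotation is missing column(s): ", paste(miss, collapse = ", ")))
  ann <- as_tibble(ann[need])
  if (anyDuplicated(ann$sample_id)) abort("Duplicated sample_id in annotation.")
  bad_site <- setdiff(unique(ann$site), VALID_SITES)
  if (length(bad_site) > 0) abort(paste0("Unknown site token(s): ", paste(bad_site, collapse = ", ")))
  bad_grp <- setdiff(unique(ann$group), VALID_GROUPS)
  if (length(bad_grp) > 0) abort(paste0("Unknown group token(s): ", paste(bad_grp, collapse = ", ")))
  dup <- ann |>
    dplyr::count(.data$subject_id, .data$site) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("Subject '%s' has %d '%s' samples; (subject, site) must be unique.",
                  dup$subject_id[1], dup$n[1], dup$site[1]))
  }
  ann
}

#' @rdname read_annotation
#' @export
write_annotation <- function(ann, path) {
  readr::write_tsv(validate_annotation(ann), path, progress = FALSE)
  invisible(path)
}

#' Subjects with one sample at each site
#'
#' @param ann Annotation tibble.
#' @return Character vector of subject ids having exactly one `upper` and one
#'   `lower` sample.
#' @export
paired_subjects <- function(ann) {
  ann <- validate_annotation(ann)
  tab <- ann |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(ok = length(.data$site) == 2 && all(sort(.data$site) == c("lower", "upper")),
                     .groups = "drop")
  tab$subject_id[tab$ok]
}

#' Read and write probe lists
#'
#' A probe list is a plain-text file with one probe id per line; blank lines
#' are skipped.  The returned vector carries the list name (by default the
#' file name) as a `"name"` attribute.
#'
#' @param path File path.
#' @param name Optional list name.
#' @return Character vector of unique probe ids, in file order.
#' @export
read_probe_list <- function(path, name = NULL) {
  ids <- readLines(path, warn = FALSE)
  ids <- trimws(ids)
  ids <- ids[nzchar(ids)]
  if (length(ids) == 0) abort(paste0("Probe list is empty: ", path))
  if (anyDuplicated(ids)) {
    abort(paste0("Duplicated probe id(s) in list: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  attr(ids, "name") <- name %||% sub("\\.[^.]*$", "", basename(path))
  ids
}

#' @rdname read_probe_list
#' @param ids Character vector of probe ids.
#' @export
write_probe_list <- function(ids, path) {
  if (anyDuplicated(ids)) abort("Probe list has duplicates.")
  writeLines(as.character(ids), path)
  invisible(path)
}

#' Read a detection-call (present/absent) matrix
#'
#' Accepts logical `TRUE`/`FALSE`, `1`/`0`, or MAS5-style `P`/`M`/`A` tokens
#' (`P` maps to present, everything else to absent).
#'
#' @param path TSV with the same layout as an expression file.
#' @return A tibble: `probe_id` column plus one logical column per sample.
#' @export
read_detection <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  names(raw)[1] <- "probe_id"
  for (j in seq(2, ncol(raw))) {
    v <- toupper(trimws(raw[[j]]))
    raw[[j]] <- v %in% c("TRUE", "T", "1", "P")
  }
  raw
}

#' @rdname read_detection
#' @param det Detection tibble.
#' @export
write_detection <- function(det, path) {
  readr::write_tsv(det, path, progress = FALSE)
  invisible(path)
}

#' Serialize analysis results
#'
#' Per-probe tables go to TSV; scalar statistics and null distributions
#' (e.g. [pairing_permutation_test()] or [vector_length_null()] results) go
#' to JSON with full double precision.
#'
#' @param x A data frame, or a result object with a [tidy()]/[glance()] pair.
#' @param path Output path (`.tsv` or `.json` decides the format for data
#'   frames; result objects are always JSON).
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path) {
  if (is.data.frame(x)) {
    if (grepl("\\.json$", path)) {
      jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
    } else {
      readr::write_tsv(x, path, progress = FALSE)
    }
  } else if (is.list(x)) {
    jsonlite::write_json(unclass(x), path, digits = NA, auto_unbox = TRUE,
                         pretty = TRUE, force = TRUE)
  } else {
    abort("Don't know how to serialize this result.")
  }
  invisible(path)
}
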