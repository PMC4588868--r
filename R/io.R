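# Flat-file layouts: beta / detection-p matrices as TSV (probe_id column +
# one column per sample), sample sheet as CSV, annotation as TSV, truth as
# JSON. Missing values are written as empty fields; round-trips are lossless
# for finite values.

matrix_to_tbl <- function(mat) {
  # %.17g keeps full double precision so write/read round-trips bit-identically
  fmt <- matrix(sprintf("%.17g", mat), nrow = nrow(mat),
                dimnames = dimnames(mat))
  dplyr::bind_cols(tibble(probe_id = rownames(mat)), as_tibble(fmt))
}

tbl_to_matrix <- function(tbl, path) {
  if (names(tbl)[1] != "probe_id") {
    stop_invalid("%s: first column must be `probe_id`", path)
  }
  m <- as.matrix(tbl[, -1, drop = FALSE])
  rownames(m) <- tbl$probe_id
  storage.mode(m) <- "double"
  m
}

check_problems <- function(tbl, path) {
  pr <- readr::problems(tbl)
  if (nrow(pr) > 0) {
    stop_invalid("%s: malformed input at line(s) %s",
                 path, paste(unique(pr$row), collapse = ", "))
  }
  tbl
}

#' Read and write probes-by-samples matrices as TSV
#'
#' @param mat Numeric matrix with probe row names and sample column names.
#' @param path File path.
#' @return `read_beta_matrix()` returns the matrix; the writer returns `path`
#'   invisibly. The same layout serves beta values and detection p-values.
#' @export
write_beta_matrix <- function(mat, path) {
  readr::write_tsv(matrix_to_tbl(mat), path)
  invisible(path)
}

#' @rdname write_beta_matrix
#' @export
read_beta_matrix <- function(path) {
  # base parser: correctly rounded doubles, so %.17g output round-trips exactly
  nf <- utils::count.fields(path, sep = "\t", quote = "\"")
  if (length(unique(nf)) > 1) {
    bad <- which(nf != nf[1])
    stop_invalid("%s: malformed row length at line(s) %s",
                 path, paste(utils::head(bad, 5), collapse = ", "))
  }
  tbl <- utils::read.delim(path, check.names = FALSE)
  tbl_to_matrix(as_tibble(tbl), path)
}

sample_sheet_required <- c("sample_id", "exposure", "birthweight")

#' Read and write the sample sheet as CSV
#'
#' The sheet must carry `sample_id`, `exposure` and `birthweight`; unknown
#' extra columns are preserved with a warning on read.
#'
#' @param samples Sample sheet data frame.
#' @param path File path.
#' @param expected_columns Columns beyond the required three that are part of
#'   the documented schema (no warning for these).
#' @return `read_sample_sheet()` returns a tibble.
#' @export
write_sample_sheet <- function(samples, path) {
  missing_col <- setdiff(sample_sheet_required, names(samples))
  if (length(missing_col) > 0) {
    stop_invalid("sample sheet lacks columns: %s", paste(missing_col, collapse = ", "))
  }
  readr::write_csv(as_tibble(samples), path, na = "")
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path,
                              expected_columns = c("sex", "gestational_age",
                                                   "maternal_age", "maternal_bmi",
                                                   "education", "plate",
                                                   "cigarettes_per_day",
                                                   "paternal_smoking")) {
  tbl <- check_problems(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE), path)
  missing_col <- setdiff(sample_sheet_required, names(tbl))
  if (length(missing_col) > 0) {
    stop_invalid("%s: sample sheet lacks columns: %s",
                 path, paste(missing_col, collapse = ", "))
  }
  unknown <- setdiff(names(tbl), c(sample_sheet_required, expected_columns))
  unknown <- unknown[!startsWith(unknown, "imputed_") &
                       !endsWith(unknown, "_imputed")]
  if (length(unknown) > 0) {
    rlang::warn(sprintf("unknown sample sheet column(s) preserved: %s",
                        paste(unknown, collapse = ", ")))
  }
  # binary indicator columns come back as integers, matching the generator
  for (cv in c("exposure", "sex", "education", "paternal_smoking")) {
    x <- tbl[[cv]]
    if (!is.null(x) && is.numeric(x) && all(x == as.integer(x), na.rm = TRUE)) {
      tbl[[cv]] <- as.integer(x)
    }
  }
  tbl
}

#' Read and write the probe annotation table as TSV
#'
#' @param annotation Annotation data frame (`probe_id`, `chromosome`, `gene`,
#'   `probe_class`, optional `island_relation`).
#' @param path File path.
#' @export
write_annotation <- function(annotation, path) {
  need <- c("probe_id", "chromosome", "probe_class")
  missing_col <- setdiff(need, names(annotation))
  if (length(missing_col) > 0) {
    stop_invalid("annotation lacks columns: %s", paste(missing_col, collapse = ", "))
  }
  readr::write_tsv(as_tibble(annotation), path, na = "")
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  tbl <- check_problems(
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                    col_types = readr::cols(chromosome = readr::col_character(),
                                            .default = readr::col_guess())),
    path)
  need <- c("probe_id", "chromosome", "probe_class")
  missing_col <- setdiff(need, names(tbl))
  if (length(missing_col) > 0) {
    stop_invalid("%s: annotation lacks columns: %s",
                 path, paste(missing_col, collapse = ", "))
  }
  tbl
}

#' Write or read a whole cohort as flat files
#'
#' Writes `beta.tsv`, `detection_p.tsv`, `samples.csv` and (when present)
#' `truth.json` into `dir`.
#'
#' @param cohort A `meth_cohort`.
#' @param dir Directory (created if needed).
#' @return `read_cohort()` returns a `meth_cohort` (the truth record, being
#'   JSON, comes back as plain lists).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_beta_matrix(cohort$beta, file.path(dir, "beta.tsv"))
  write_beta_matrix(cohort$detection_p, file.path(dir, "detection_p.tsv"))
  write_sample_sheet(cohort$samples, file.path(dir, "samples.csv"))
  if (!is.null(cohort$truth)) {
    truth <- cohort$truth
    truth$config <- unclass(truth$config)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  truth_path <- file.path(dir, "truth.json")
  structure(
    list(beta = read_beta_matrix(file.path(dir, "beta.tsv")),
         detection_p = read_beta_matrix(file.path(dir, "detection_p.tsv")),
         samples = read_sample_sheet(file.path(dir, "samples.csv")),
         truth = if (file.exists(truth_path)) jsonlite::read_json(truth_path)),
    class = "meth_cohort")
}

#' Write a results table as TSV
#'
#' @param results Any results tibble (EWAS, mediation, meta).
#' @param path File path.
#' @export
write_results <- function(results, path) {
  readr::write_tsv(as_tibble(results), path, na = "")
  invisible(path)
}
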