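#' Read and write cohort tables, connectivity matrices and parcellations
#'
#' Cohort tables are CSV with header
#' `subject_id,age,sex,education,cortical_thickness,psmd,tmta,tmtb`;
#' connectivity matrices are one delimited-text square matrix per subject
#' (whitespace- or comma-separated), named `<subject_id>_matrix.txt`;
#' parcellations are TSV with columns `roi_index`, `roi_name`, `network`;
#' generator ground truth is an edge-list TSV
#' `node_i<TAB>node_j<TAB>true_slope`.
#'
#' @param cohort A cohort tibble.
#' @param path File path.
#' @return `read_cohort()` returns the validated cohort tibble; writers
#'   return the path invisibly.
#' @name cohort_io
NULL

cohort_columns <- c("subject_id", "age", "sex", "education",
                    "cortical_thickness", "psmd", "tmta", "tmtb")

#' @rdname cohort_io
#' @export
write_cohort <- function(cohort, path) {
  missing <- setdiff(cohort_columns, names(cohort))
  if (length(missing)) {
    stop("cohort is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  readr::write_csv(cohort[cohort_columns], path)
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(cohort_columns, names(df))
  if (length(missing)) {
    stop(sprintf("cohort file %s is missing columns: %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  numeric_cols <- setdiff(cohort_columns, "subject_id")
  for (cl in numeric_cols) {
    if (!is.numeric(df[[cl]])) {
      stop(sprintf("cohort column `%s` is not numeric in %s", cl, path),
           call. = FALSE)
    }
  }
  if (anyDuplicated(df$subject_id)) {
    stop("duplicated subject_id values in ", path, call. = FALSE)
  }
  tibble::as_tibble(df[cohort_columns])
}

#' Write a stack of connectivity matrices to a directory
#'
#' @param matrices Named list of matrices (names are subject ids), or an
#'   unnamed list with `subject_ids` supplied.
#' @param dir Output directory (created if absent).
#' @param subject_ids Optional character vector of subject ids.
#' @return The directory path, invisibly.
#' @export
write_connectome_matrices <- function(matrices, dir, subject_ids = names(matrices)) {
  if (is.null(subject_ids) || length(subject_ids) != length(matrices)) {
    stop("one subject id per matrix is required", call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in seq_along(matrices)) {
    utils::write.table(matrices[[s]],
                       file.path(dir, paste0(subject_ids[s], "_matrix.txt")),
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}

read_matrix_file <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  m <- as.matrix(utils::read.table(path, sep = sep, header = FALSE))
  dimnames(m) <- NULL
  if (nrow(m) != ncol(m)) {
    stop(sprintf("matrix file %s is not square (%d x %d)", path, nrow(m), ncol(m)),
         call. = FALSE)
  }
  if (!is.numeric(m) || any(!is.finite(m))) {
    stop(sprintf("matrix file %s contains non-numeric or non-finite entries", path),
         call. = FALSE)
  }
  m
}

#' Read per-subject connectivity matrices for a cohort
#'
#' Looks for `<subject_id>_matrix.txt` in `dir` for every cohort subject.
#' Subjects without a readable matrix are excluded (with a message);
#' matrix files in `dir` without a cohort row are an error.
#'
#' @param dir Directory of matrix files.
#' @param subject_ids Character vector of expected subject ids.
#' @return A named list of matrices aligned to the subjects that were
#'   found, with attribute `excluded` listing the dropped ids.
#' @export
read_connectome_matrices <- function(dir, subject_ids) {
  if (!dir.exists(dir)) stop("matrix directory not found: ", dir, call. = FALSE)
  files <- list.files(dir, pattern = "_matrix\\.txt$")
  file_ids <- sub("_matrix\\.txt$", "", files)
  orphans <- setdiff(file_ids, subject_ids)
  if (length(orphans)) {
    stop("matrix files without a cohort row: ", paste(orphans, collapse = ", "),
         call. = FALSE)
  }
  present <- subject_ids %in% file_ids
  if (!all(present)) {
    message(sprintf("excluded %d subject(s) without a matrix file: %s",
                    sum(!present),
                    paste(subject_ids[!present], collapse = ", ")))
  }
  ids <- subject_ids[present]
  mats <- lapply(ids, function(id) read_matrix_file(file.path(dir, paste0(id, "_matrix.txt"))))
  names(mats) <- ids
  n <- unique(vapply(mats, nrow, integer(1)))
  if (length(n) > 1) {
    stop("matrix files disagree on the number of ROIs: ",
         paste(n, collapse = ", "), call. = FALSE)
  }
  attr(mats, "excluded") <- subject_ids[!present]
  mats
}

#' @rdname cohort_io
#' @param parcellation A parcellation tibble (`roi_index`, `roi_name`,
#'   `network`).
#' @export
write_parcellation <- function(parcellation, path) {
  readr::write_tsv(parcellation[c("roi_index", "roi_name", "network")], path)
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_parcellation <- function(path) {
  if (!file.exists(path)) stop("parcellation file not found: ", path, call. = FALSE)
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("roi_index", "roi_name", "network")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop(sprintf("parcellation file %s is missing columns: %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df$roi_index <- as.integer(df$roi_index)
  if (!setequal(df$roi_index, seq_len(nrow(df)))) {
    stop("parcellation roi_index values must be unique and contiguous from 1",
         call. = FALSE)
  }
  tibble::as_tibble(df[need])
}

#' @rdname cohort_io
#' @param ground_truth The generator's ground-truth edge list.
#' @export
write_ground_truth <- function(ground_truth, path) {
  readr::write_tsv(ground_truth[c("node_i", "node_j", "true_slope")], path)
  invisible(path)
}
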