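#' Read a feature-by-sample matrix from delimited text
#'
#' Reads a TSV (or GCT 1.2) matrix whose first column holds feature ids and
#' whose header row holds sample ids, validates it, and optionally joins a
#' feature annotation table carrying genomic locus and the 14q32 flag.
#'
#' @param path Path to a tab-delimited matrix. GCT 1.2 files (`.gct`, two
#'   header lines, `Name`/`Description` columns) are detected by extension.
#' @param omics_kind One of `"mrna"`, `"mirna"`, `"methylation"`.
#' @param annotation_path Optional path to a TSV with columns `feature_id`,
#'   `chromosome`, `start`, `is_14q32` (0/1).
#' @return An [omics_matrix()].
#' @export
read_matrix <- function(path, omics_kind, annotation_path = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  gct <- grepl("\\.gct$", path, ignore.case = TRUE)
  df <- readr::read_tsv(path, skip = if (gct) 2 else 0, show_col_types = FALSE,
                        progress = FALSE)
  if (gct && tolower(names(df)[2]) == "description") df <- df[, -2]
  ids <- as.character(df[[1]])
  body <- df[, -1, drop = FALSE]
  bad <- which(!vapply(body, is.numeric, logical(1)))
  if (length(bad)) {
    # report the first offending cell for diagnosis
    col <- bad[1]
    row <- which(is.na(suppressWarnings(as.numeric(body[[col]]))))[1]
    stop(sprintf("non-numeric value in column '%s' (sample %d), row %s",
                 names(body)[col], col, if (is.na(row)) "?" else ids[row]),
         call. = FALSE)
  }
  values <- as.matrix(body)
  rownames(values) <- ids
  ann <- NULL
  if (!is.null(annotation_path)) {
    ann <- readr::read_tsv(annotation_path, show_col_types = FALSE, progress = FALSE)
  }
  omics_matrix(values, omics_kind, feature_annotation = ann)
}

#' Write pipeline objects to an output directory
#'
#' Matrices and label vectors are written as TSV, run reports (plain lists)
#' as JSON. Numeric precision is kept at 15 significant digits so a TSV
#' round trip reproduces values to within 1e-12.
#'
#' @param objects Named list of objects: `omics_matrix`, `label_vector`,
#'   plain numeric matrices (e.g. co-classification matrices) or lists
#'   (written as JSON reports).
#' @param out_dir Output directory, created if absent.
#' @return Invisibly, a character vector of written paths (the file manifest).
#' @export
write_outputs <- function(objects, out_dir) {
  if (!is.list(objects) || is.null(names(objects)) || any(names(objects) == "")) {
    stop("`objects` must be a fully named list", call. = FALSE)
  }
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(out_dir, 2) != 0) {
    stop("output directory is not writable: ", out_dir, call. = FALSE)
  }
  paths <- character(0)
  for (nm in names(objects)) {
    obj <- objects[[nm]]
    if (inherits(obj, "omics_matrix")) obj <- obj$values
    if (inherits(obj, "label_vector")) {
      p <- file.path(out_dir, paste0(nm, ".tsv"))
      readr::write_tsv(tidy(obj), p, progress = FALSE)
    } else if (is.matrix(obj)) {
      p <- file.path(out_dir, paste0(nm, ".tsv"))
      df <- tibble::as_tibble(obj, rownames = "feature_id", .name_repair = "minimal")
      # full double precision so read_matrix round-trips within 1e-12
      readr::write_tsv(dplyr::mutate(df, dplyr::across(
        dplyr::where(is.numeric), ~ formatC(.x, digits = 15, format = "g"))),
        p, progress = FALSE)
    } else if (is.list(obj)) {
      p <- file.path(out_dir, paste0(nm, ".json"))
      jsonlite::write_json(obj, p, auto_unbox = TRUE, digits = NA, null = "null")
    } else {
      stop("cannot serialize object '", nm, "' of class ", class(obj)[1], call. = FALSE)
    }
    paths <- c(paths, p)
  }
  invisible(paths)
}
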