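# Delimited-text I/O. Subject files are frames x ROI with a header row of
# region labels; matrices round-trip through %.17g formatting. Indices in
# files are 0-based.

fmt17 <- function(x) formatC(x, format = "g", digits = 17)

#' Read a parcellated series file
#'
#' Expects delimited text (comma for `.csv`, otherwise tab) with a header
#' row of ROI labels and one row per frame; transposed internally to
#' ROI x T.
#'
#' @param path File path.
#' @param subject_id Subject id; defaults to the file name without
#'   extension.
#' @param tr_seconds Repetition time to attach.
#' @return A [roi_time_series()].
#' @export
read_roi_series <- function(path, subject_id = NULL, tr_seconds = 3.0) {
  if (!file.exists(path)) stop_edgedyn("file not found: %s", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                      colClasses = "numeric"),
    error = function(e) stop_edgedyn("parse error in %s: %s", path,
                                     conditionMessage(e)))
  m <- as.matrix(df)
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop_edgedyn("missing/non-numeric cell in %s at frame %d, column '%s'",
                 path, bad[1L], colnames(m)[bad[2L]])
  }
  if (anyDuplicated(colnames(m)))
    stop_edgedyn("duplicate ROI labels in %s", path)
  roi_time_series(t(m), subject_id = subject_id %||%
                    sub("\\.[^.]*$", "", basename(path)),
                  roi_labels = colnames(m), tr_seconds = tr_seconds)
}

#' Write a parcellated series file
#'
#' Inverse of [read_roi_series()]: frames x ROI, header of region labels,
#' values at 17 significant digits.
#'
#' @param series A [roi_time_series()].
#' @param path Output path (`.csv` for comma-separated, else tab).
#' @return `path`, invisibly.
#' @export
write_roi_series <- function(series, path) {
  stopifnot(inherits(series, "roi_time_series"))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  m <- t(series$data)
  out <- rbind(series$roi_labels, apply(m, 2L, fmt17))
  writeLines(apply(out, 1L, paste, collapse = sep), path)
  invisible(path)
}

#' Write an FC or adjacency matrix as delimited text
#' @param mat Square matrix with ROI dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(mat, path) {
  labels <- rownames(mat) %||% paste0("roi_", seq_len(nrow(mat)))
  out <- rbind(labels, apply(mat, 2L, fmt17))
  writeLines(apply(t(out), 1L, paste, collapse = ","), path)
  invisible(path)
}

#' Write a synthetic cohort to a directory
#'
#' One frames x ROI file per subject (`<subject_id>.csv`), a
#' `metadata.csv` with columns subject_id, group, site, apoe4_count, mmse,
#' moca, and a `truth.json` with per-subject event frames (0-based in the
#' file) and amplitudes.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$series)
    write_roi_series(s, file.path(dir, paste0(s$subject_id, ".csv")))
  utils::write.csv(cohort$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  truth <- lapply(cohort$truth, function(tr)
    list(event_frames_0based = tr$event_frames - 1L,
         event_amplitudes = tr$event_amplitudes,
         event_communities_0based = tr$event_communities - 1L,
         group = tr$group, site = tr$site))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory with per-subject `.csv` files and `metadata.csv`.
#' @param tr_seconds Repetition time to attach to every subject.
#' @return List with `series` (named list of [roi_time_series()]) and
#'   `metadata` (data.frame).
#' @export
read_cohort <- function(dir, tr_seconds = 3.0) {
  meta_path <- file.path(dir, "metadata.csv")
  if (!file.exists(meta_path)) stop_edgedyn("missing metadata.csv in %s", dir)
  metadata <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "site", "apoe4_count", "mmse", "moca")
  miss <- setdiff(need, names(metadata))
  if (length(miss))
    stop_edgedyn("metadata.csv missing column(s): %s", paste(miss, collapse = ", "))
  series <- lapply(metadata$subject_id, function(id) {
    p <- file.path(dir, paste0(id, ".csv"))
    if (!file.exists(p)) stop_edgedyn("missing series file for subject %s", id)
    read_roi_series(p, subject_id = id, tr_seconds = tr_seconds)
  })
  names(series) <- metadata$subject_id
  list(series = series, metadata = metadata)
}
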