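#' Read a recording from a delimited text file
#'
#' The file must have a header row of channel labels and one row per
#' frame.  Metadata (subject, condition, sampling rate) are taken from a
#' JSON sidecar `<path>.json` when present (fields `subject_id`,
#' `condition`, `rate`) and can be overridden by the arguments.
#'
#' @param path path to the delimited file (separator auto-detected).
#' @param subject_id,condition,rate metadata overrides.
#' @param require_canonical require exactly the seven canonical channel
#'   labels (default TRUE).
#' @param warn passed to [recording()].
#' @return A [recording()].
#' @export
read_recording <- function(path, subject_id = NULL, condition = NULL,
                           rate = NULL, require_canonical = TRUE,
                           warn = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- data.table::fread(path, header = TRUE)
  labels <- names(dt)
  if (require_canonical) {
    missing_ch <- setdiff(phistar_channels, labels)
    if (length(missing_ch) > 0)
      stop("missing channel column(s): ", paste(missing_ch, collapse = ", "))
    extra <- setdiff(labels, phistar_channels)
    if (length(extra) > 0)
      stop("unknown channel column(s): ", paste(extra, collapse = ", "))
    dt <- dt[, phistar_channels, with = FALSE]
    labels <- phistar_channels
  }
  if (!all(vapply(dt, is.numeric, TRUE))) {
    bad <- labels[!vapply(dt, is.numeric, TRUE)]
    stop("non-numeric values in channel(s): ", paste(bad, collapse = ", "))
  }
  meta <- list(subject_id = "S1", condition = "SYNC", rate = 250)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    got <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    meta[names(got)] <- got
  }
  if (!is.null(subject_id)) meta$subject_id <- subject_id
  if (!is.null(condition)) meta$condition <- condition
  if (!is.null(rate)) meta$rate <- rate
  recording(as.matrix(dt), subject_id = meta$subject_id,
            condition = meta$condition, rate = meta$rate, warn = warn)
}

#' Write a recording and its JSON sidecar
#'
#' @param rec a [recording()].
#' @param path output path; the sidecar goes to `<path>.json`.
#' @param sep field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, sep = "\t") {
  stopifnot(inherits(rec, "recording"))
  data.table::fwrite(data.table::as.data.table(rec$data), path, sep = sep)
  jsonlite::write_json(
    list(subject_id = rec$subject_id, condition = rec$condition,
         rate = rec$rate),
    paste0(path, ".json"), auto_unbox = TRUE
  )
  invisible(path)
}

#' Read a questionnaire ratings table
#'
#' Expects columns `subject_id`, `condition`, `Q1`..`Q9`.
#'
#' @param path path to a delimited file.
#' @return Data frame of ratings.
#' @export
read_ratings <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- as.data.frame(data.table::fread(path, header = TRUE))
  need <- c("subject_id", "condition", paste0("Q", 1:3))
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("ratings table is missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' Write tidy result tables plus run metadata
#'
#' Writes any named data frames in `results` as tab-separated tables
#' (`<name>.tsv`) and a `run_meta.json` holding the window configuration,
#' the seed and the package version, enough to re-run bit-identically.
#'
#' @param results named list of data frames (e.g. a cohort series, phase
#'   contrasts, frequency differences, subject scores).
#' @param dir output directory (created if needed).
#' @param config optional [window_config()] stored in the metadata.
#' @param seed optional seed stored in the metadata.
#' @return `dir`, invisibly.
#' @export
write_results <- function(results, dir, config = NULL, seed = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stopifnot(is.list(results), !is.null(names(results)))
  for (nm in names(results)) {
    df <- as.data.frame(results[[nm]])
    df <- df[, !vapply(df, is.list, TRUE), drop = FALSE]
    data.table::fwrite(df, file.path(dir, paste0(nm, ".tsv")), sep = "\t")
  }
  meta <- list(
    package = "phistar",
    version = as.character(packageVersion("phistar")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    tables = names(results)
  )
  if (!is.null(config)) meta$window_config <- unclass(config)
  if (!is.null(seed)) meta$seed <- seed
  jsonlite::write_json(meta, file.path(dir, "run_meta.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(dir)
}
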