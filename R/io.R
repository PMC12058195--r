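# Plain-text I/O conventions: ROI matrices as delimited files with a
# header row of ROI labels (rows = TRs), rating logs as CSV
# (rater_id, time_s, value), configs as YAML, results as CSV/JSON.

#' Write / read a per-subject ROI time-series matrix
#'
#' Tab-delimited text, rows = TRs, columns = ROIs, header row of ROI
#' labels.
#'
#' @param x TR x ROI matrix.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_roi_matrix <- function(x, path) {
  readr::write_tsv(as_tibble(as.data.frame(x)), path)
  invisible(path)
}

#' @rdname write_roi_matrix
#' @export
read_roi_matrix <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_double()))
  as.matrix(df)
}

#' Write / read a rating log
#'
#' CSV with columns `rater_id`, `time_s`, `value`.
#'
#' @param ratings Tibble of rating events.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_rating_log <- function(ratings, path) {
  stopifnot(all(c("rater_id", "time_s", "value") %in% names(ratings)))
  readr::write_csv(ratings, path)
  invisible(path)
}

#' @rdname write_rating_log
#' @export
read_rating_log <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    rater_id = readr::col_character(),
    time_s = readr::col_double(),
    value = readr::col_double()))
}

#' Write the ground truth of a synthetic dataset as JSON
#' @param truth A [synth_truth()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(
    list(
      latent = truth$latent,
      planted = truth$planted
    ),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write / read a run configuration as YAML
#' @param config Named list of run settings.
#' @param path Output file.
#' @return `path` (write) or the configuration list (read).
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}

#' Validate on-disk pipeline inputs
#'
#' Checks ROI matrices for consistent shapes, rating logs for values
#' within the slider scale and proper initial events, and the network
#' assignment for completeness. Problems are reported, not thrown.
#'
#' @param roi_paths Character vector of ROI matrix files (optional).
#' @param rating_path Rating-log CSV (optional).
#' @param assignment_path Network-assignment TSV (optional).
#' @param spec A [dataset_spec()] used for expected lengths (optional).
#' @return A tibble `severity` (`"error"`/`"warning"`), `item`,
#'   `message`; zero rows when everything checks out.
#' @export
validate_inputs <- function(roi_paths = character(), rating_path = NULL,
                            assignment_path = NULL, spec = NULL) {
  probs <- list()
  note <- function(severity, item, message) {
    probs[[length(probs) + 1L]] <<- tibble(severity = severity,
      item = item, message = message)
  }
  shapes <- NULL
  for (p in roi_paths) {
    if (!file.exists(p)) {
      note("error", p, "file not found")
      next
    }
    m <- tryCatch(read_roi_matrix(p), error = function(e) NULL)
    if (is.null(m)) {
      note("error", p, "could not parse as a delimited ROI matrix")
      next
    }
    shapes <- rbind(shapes, c(nrow(m), ncol(m)))
    if (!is.null(spec) && nrow(m) != spec$n_tr) {
      note("error", p, sprintf("expected %d TRs, found %d",
        spec$n_tr, nrow(m)))
    }
    if (anyNA(m)) note("error", p, "missing values in ROI matrix")
  }
  if (!is.null(shapes) && nrow(shapes) > 1L &&
    length(unique(shapes[, 2])) != 1L) {
    note("error", "roi matrices", "subjects disagree on ROI count")
  }
  if (!is.null(rating_path)) {
    if (!file.exists(rating_path)) {
      note("error", rating_path, "file not found")
    } else {
      rl <- tryCatch(read_rating_log(rating_path), error = function(e) NULL)
      if (is.null(rl)) {
        note("error", rating_path, "could not parse rating log")
      } else {
        if (any(rl$value < 1 | rl$value > 25)) {
          note("error", rating_path, "rating values outside [1, 25]")
        }
        first_t <- tapply(rl$time_s, rl$rater_id, min)
        if (any(first_t > 0)) {
          note("error", rating_path,
            "rater without initial slider position at t <= 0")
        }
      }
    }
  }
  if (!is.null(assignment_path)) {
    asn <- tryCatch(network_assignment(assignment_path),
      error = function(e) e)
    if (inherits(asn, "error")) {
      note("error", assignment_path, conditionMessage(asn))
    } else if (!is.null(shapes) && nrow(asn) != shapes[1, 2]) {
      note("error", assignment_path,
        "assignment ROI count does not match the ROI matrices")
    }
  }
  if (length(probs) == 0L) {
    return(tibble(severity = character(), item = character(),
      message = character()))
  }
  dplyr::bind_rows(probs)
}
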