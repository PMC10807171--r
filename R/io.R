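## Plain-CSV readers/writers for the tabular modalities.

#' Read / write tabular assay inputs
#'
#' Thin CSV adapters for the tabular modalities: calcein traces
#' (`time_s, F`), wound-healing series (`time_h, area_um2`), nucleus tracks
#' (`track_id, time_h, x_um, y_um`) and expression matrices (genes x
#' samples, first column = gene id).
#'
#' @param path CSV file path.
#' @param stimulus_onset,label see [calcein_trace()].
#' @param gap_length see [gap_series()].
#' @return The corresponding container (`calcein_trace`, `gap_series`,
#'   data.frame of tracks, or numeric matrix).
#' @name assay_io
NULL

#' @rdname assay_io
#' @export
read_calcein_csv <- function(path, stimulus_onset = 30,
                             label = "whole-cell") {
  d <- utils::read.csv(path)
  calcein_trace(d$time_s, d$F, stimulus_onset = stimulus_onset, label = label)
}

#' @rdname assay_io
#' @export
read_gap_csv <- function(path, gap_length) {
  d <- utils::read.csv(path)
  gap_series(d$time_h, d$area_um2, gap_length = gap_length)
}

#' @rdname assay_io
#' @export
read_tracks_csv <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("track_id", "time_h", "x_um", "y_um") %in% names(d)))
  d
}

#' @rdname assay_io
#' @export
read_expression_csv <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  storage.mode(m) <- "double"
  m
}
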