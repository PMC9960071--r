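#' Episodic voltage-clamp recording
#'
#' Container for episodic sweeps with a shared protocol. `data` holds one row
#' per sample (`sweep`, `time_s`, `current`); `protocol` maps every sample to
#' exactly one segment (`segment`, `start_s`, `end_s`, `voltage_mV`), where a
#' segment covers `start_s <= t < end_s` (the final segment includes its end
#' point). `solution` optionally records the external solution per sweep.
#'
#' @param data data.frame with columns `sweep`, `time_s`, `current`.
#' @param protocol data.frame with columns `segment`, `start_s`, `end_s`,
#'   `voltage_mV`; segments must be contiguous and non-overlapping.
#' @param solution optional data.frame with columns `sweep`, `ion`, `conc_mM`.
#' @param sample_rate sampling rate (Hz).
#' @param metadata named list of free-form key/values.
#' @return An object of class `ko_recording`.
#' @export
recording <- function(data, protocol, solution = NULL, sample_rate = NULL,
                      metadata = list()) {
  need <- c("sweep", "time_s", "current")
  if (!all(need %in% names(data))) {
    stop("recording data needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  pneed <- c("segment", "start_s", "end_s", "voltage_mV")
  if (!all(pneed %in% names(protocol))) {
    stop("protocol needs columns: ", paste(pneed, collapse = ", "),
         call. = FALSE)
  }
  for (sw in unique(data$sweep)) {
    tt <- data$time_s[data$sweep == sw]
    if (any(diff(tt) <= 0)) {
      stop("time must be strictly increasing within a sweep", call. = FALSE)
    }
  }
  if (any(protocol$end_s <= protocol$start_s)) {
    stop("protocol segments must have end_s > start_s", call. = FALSE)
  }
  if (is.null(sample_rate)) {
    tt <- data$time_s[data$sweep == data$sweep[1]]
    sample_rate <- if (length(tt) > 1) 1 / stats::median(diff(tt)) else NA_real_
  }
  structure(list(data = data, protocol = protocol, solution = solution,
                 sample_rate = sample_rate, metadata = metadata),
            class = "ko_recording")
}

#' @export
print.ko_recording <- function(x, ...) {
  cat(sprintf("<ko_recording> %d sweep(s), %d samples, %.4g Hz\n",
              length(unique(x$data$sweep)), nrow(x$data), x$sample_rate))
  cat("segments:", paste(sprintf("%s[%g-%gs @ %g mV]", x$protocol$segment,
                                 x$protocol$start_s, x$protocol$end_s,
                                 x$protocol$voltage_mV), collapse = " "), "\n")
  if (length(x$metadata)) {
    cat("metadata:", paste(names(x$metadata), unlist(x$metadata), sep = "=",
                           collapse = ", "), "\n")
  }
  invisible(x)
}

# rows of rec$data falling in a named protocol segment
.segment_rows <- function(rec, segment, sweep = NULL) {
  pr <- rec$protocol[rec$protocol$segment == segment, , drop = FALSE]
  if (nrow(pr) != 1) stop(sprintf("segment '%s' not found", segment),
                          call. = FALSE)
  last <- pr$end_s >= max(rec$protocol$end_s)
  sel <- rec$data$time_s >= pr$start_s &
    (if (last) rec$data$time_s <= pr$end_s else rec$data$time_s < pr$end_s)
  if (!is.null(sweep)) sel <- sel & rec$data$sweep %in% sweep
  which(sel)
}

#' Peak current of a protocol segment
#'
#' Extremum of the current over the entire segment, taken in the outward
#' direction for depolarizing segments (positive segment voltage) and in the
#' inward direction otherwise; `direction` overrides the convention.
#'
#' @param rec a [recording()].
#' @param segment segment label.
#' @param sweep optional sweep id(s) to restrict to.
#' @param direction `"auto"` (from segment voltage sign), `"max"` or `"min"`.
#' @return Named numeric vector, one peak per sweep present.
#' @export
peak_current <- function(rec, segment, sweep = NULL,
                         direction = c("auto", "max", "min")) {
  direction <- match.arg(direction)
  idx <- .segment_rows(rec, segment, sweep)
  if (!length(idx)) stop("empty segment", call. = FALSE)
  pr <- rec$protocol[rec$protocol$segment == segment, ]
  use_max <- switch(direction, auto = pr$voltage_mV >= 0,
                    max = TRUE, min = FALSE)
  dd <- rec$data[idx, ]
  vapply(split(dd$current, dd$sweep),
         if (use_max) max else min, numeric(1))
}

#' Subtract mean unspecific (blank) current
#'
#' Elementwise subtraction of the mean blank trace recorded from uninjected
#' cells under the identical protocol and cursor positions.
#'
#' @param series numeric vector of per-timepoint amplitudes.
#' @param blank_mean numeric vector of the same length.
#' @param n_blanks number of blank cells averaged (stored as an attribute).
#' @return Corrected series with attribute `n_blanks`.
#' @export
subtract_unspecific <- function(series, blank_mean, n_blanks = NA_integer_) {
  if (length(series) != length(blank_mean)) {
    stop("series and blank_mean lengths differ", call. = FALSE)
  }
  out <- series - blank_mean
  attr(out, "n_blanks") <- n_blanks
  out
}
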