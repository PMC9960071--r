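# File dialects shared by all modules: CSV/TSV with '#key=value' metadata
# header lines, site-map JSON, and results JSON with unit-suffixed keys.

.read_meta_table <- function(path, sep = ",") {
  lines <- readLines(path)
  meta_idx <- grep("^#", lines)
  meta <- list()
  for (l in lines[meta_idx]) {
    kv <- sub("^#", "", l)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) {
      key <- substr(kv, 1, eq - 1)
      val <- substr(kv, eq + 1, nchar(kv))
      num <- suppressWarnings(as.numeric(val))
      meta[[key]] <- if (!is.na(num)) num else val
    }
  }
  body <- if (length(meta_idx)) lines[-meta_idx] else lines
  df <- tryCatch(
    utils::read.table(text = body, header = TRUE, sep = sep,
                      stringsAsFactors = FALSE),
    error = function(e) {
      stop(sprintf("parse error in '%s': %s", path, conditionMessage(e)),
           call. = FALSE)
    })
  attr(df, "metadata") <- meta
  df
}

.write_meta_table <- function(df, path, metadata = list(), sep = ",") {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(metadata)) {
    writeLines(sprintf("#%s=%s", k, format(metadata[[k]], digits = 15)), con)
  }
  utils::write.table(df, con, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.require_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s: missing column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

#' Write an episodic recording to CSV
#'
#' Flat CSV with columns `sweep,time_s,current,segment,voltage_mV` and
#' `#key=value` metadata header lines (protocol segment boundaries are stored
#' in the metadata header).
#'
#' @param rec a [recording()].
#' @param path output file.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "ko_recording"))
  pr <- rec$protocol
  seg_idx <- findInterval(rec$data$time_s, pr$start_s)
  seg_idx[seg_idx < 1] <- 1
  df <- data.frame(sweep = rec$data$sweep, time_s = rec$data$time_s,
                   current = rec$data$current,
                   segment = pr$segment[seg_idx],
                   voltage_mV = pr$voltage_mV[seg_idx])
  meta <- c(rec$metadata,
            list(sample_rate_Hz = rec$sample_rate,
                 protocol = paste(sprintf("%s:%g:%g:%g", pr$segment,
                                          pr$start_s, pr$end_s,
                                          pr$voltage_mV), collapse = ";")))
  .write_meta_table(df, path, meta)
}

#' Read an episodic recording from CSV
#'
#' @param path CSV written by [write_recording()].
#' @return A [recording()].
#' @export
read_recording <- function(path) {
  df <- .read_meta_table(path)
  .require_columns(df, c("sweep", "time_s", "current", "segment",
                         "voltage_mV"), "recording CSV")
  meta <- attr(df, "metadata")
  if (!is.null(meta$protocol)) {
    parts <- strsplit(strsplit(meta$protocol, ";")[[1]], ":")
    protocol <- data.frame(
      segment = vapply(parts, `[`, character(1), 1),
      start_s = as.numeric(vapply(parts, `[`, character(1), 2)),
      end_s = as.numeric(vapply(parts, `[`, character(1), 3)),
      voltage_mV = as.numeric(vapply(parts, `[`, character(1), 4)))
  } else {
    agg <- stats::aggregate(time_s ~ segment + voltage_mV, df,
                            function(x) c(min(x), max(x)))
    protocol <- data.frame(segment = agg$segment,
                           start_s = agg$time_s[, 1],
                           end_s = agg$time_s[, 2],
                           voltage_mV = agg$voltage_mV)
    protocol <- protocol[order(protocol$start_s), ]
  }
  sr <- meta$sample_rate_Hz
  meta$protocol <- NULL
  meta$sample_rate_Hz <- NULL
  recording(df[, c("sweep", "time_s", "current")], protocol,
            sample_rate = sr, metadata = meta)
}

#' Write/read dose-response pulse tables
#'
#' CSV with columns `cell,concentration_mM,point_index,amplitude`.
#'
#' @param pulses data.frame of pulse amplitudes.
#' @param path file path.
#' @param metadata named list written as `#key=value` header lines.
#' @return `read_dose_table` returns the data.frame with a `metadata`
#'   attribute.
#' @export
write_dose_table <- function(pulses, path, metadata = list()) {
  .require_columns(pulses, c("cell", "concentration_mM", "point_index",
                             "amplitude"), "dose table")
  .write_meta_table(pulses, path, metadata)
}

#' @rdname write_dose_table
#' @export
read_dose_table <- function(path) {
  df <- .read_meta_table(path)
  .require_columns(df, c("cell", "concentration_mM", "point_index",
                         "amplitude"), "dose table")
  df
}

#' Write/read ion z-trajectory tables
#'
#' TSV with columns `time_ns,ion_id,z_A`.
#'
#' @param tracks long-format z-table.
#' @param path file path.
#' @param metadata named list written as `#key=value` header lines.
#' @export
write_ion_tracks <- function(tracks, path, metadata = list()) {
  .require_columns(tracks, c("time_ns", "ion_id", "z_A"), "ion tracks")
  .write_meta_table(tracks, path, metadata, sep = "\t")
}

#' @rdname write_ion_tracks
#' @export
read_ion_tracks <- function(path) {
  df <- .read_meta_table(path, sep = "\t")
  .require_columns(df, c("time_ns", "ion_id", "z_A"), "ion tracks")
  df
}

#' Write/read dihedral tracks
#'
#' TSV with columns `time_ns,subunit,chi_deg`.
#'
#' @param track dihedral data.frame.
#' @param path file path.
#' @param metadata named list written as `#key=value` header lines.
#' @export
write_dihedral_track <- function(track, path, metadata = list()) {
  .require_columns(track, c("time_ns", "subunit", "chi_deg"),
                   "dihedral track")
  .write_meta_table(track, path, metadata, sep = "\t")
}

#' @rdname write_dihedral_track
#' @export
read_dihedral_track <- function(path) {
  df <- .read_meta_table(path, sep = "\t")
  .require_columns(df, c("time_ns", "subunit", "chi_deg"), "dihedral track")
  df
}

#' Serialize fitted parameters to a JSON record
#'
#' Explicit unit-suffixed keys (`ic50_mM`, `p_cm_per_s`, ...) so results are
#' self-describing.
#'
#' @param x a [fit_result()].
#' @param path output JSON file.
#' @export
write_fit_json <- function(x, path) {
  stopifnot(inherits(x, "ko_fit"))
  unit_key <- function(nm) {
    switch(nm, ic50 = "ic50_mM", imax = "imax", nh = "nh",
           p = "p_cm_per_s", vhalf = "vhalf_mV", z = "z_e", gmin = "gmin",
           nm)
  }
  params <- as.list(x$params)
  names(params) <- vapply(names(params), unit_key, character(1))
  stderr <- as.list(x$stderr)
  names(stderr) <- paste0(vapply(names(x$stderr), unit_key, character(1)),
                          "_se")
  jsonlite::write_json(c(params, stderr,
                         list(model = x$model, converged = x$converged,
                              n_points = x$n_points,
                              residual_norm = x$residual_norm)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
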