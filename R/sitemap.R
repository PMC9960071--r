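#' Selectivity-filter site map
#'
#' Defines the bands along the pore axis used to classify K+ ion positions
#' into the filter sites Scav, S4, S3, S2, S1, S0 (ordered internal to
#' external), plus the internal/external bulk regions and the permeation
#' completion criterion. `z = 0` is the substate reference (center of mass of
#' the four G314 carbonyl carbons); the completion (exit) reference sits
#' `exit_ref_offset_A` above it, and a passage is complete once an ion rises
#' more than `exit_threshold_A` above the exit reference.
#'
#' Band boundaries are a configurable convention, not measured values:
#' defaults use a canonical K+-channel inter-site spacing (`band_width_A`,
#' 3.1 A) with S2 centered at `s2_center_A`.
#'
#' @param band_width_A width of each site band (A).
#' @param s2_center_A center of the S2 band (A).
#' @param exit_ref_offset_A offset of the exit reference above the substate
#'   reference (A).
#' @param exit_threshold_A completion threshold above the exit reference (A).
#' @return An object of class `ko_site_map`: list with `bands` (data.frame
#'   `site`, `lower_A`, `upper_A`, internal to external), `exit_z_A`
#'   (absolute completion coordinate), `internal_z_A` (lower bulk boundary),
#'   `anchors_A` (named band centers plus bulk anchor positions).
#' @export
site_map <- function(band_width_A = 3.1, s2_center_A = 0,
                     exit_ref_offset_A = 6, exit_threshold_A = 4) {
  stopifnot(band_width_A > 0, exit_threshold_A > 0)
  sites <- c("Scav", "S4", "S3", "S2", "S1", "S0")
  centers <- s2_center_A + band_width_A * c(-3, -2, -1, 0, 1, 2)
  names(centers) <- sites
  bands <- data.frame(site = sites,
                      lower_A = centers - band_width_A / 2,
                      upper_A = centers + band_width_A / 2)
  exit_z <- exit_ref_offset_A + exit_threshold_A
  if (exit_z <= max(bands$upper_A)) {
    stop("completion coordinate must lie above the S0 band", call. = FALSE)
  }
  anchors <- c(centers,
               internal = unname(min(bands$lower_A) - 3.5),
               external = unname(exit_z + 2))
  structure(list(bands = bands, exit_z_A = exit_z,
                 internal_z_A = min(bands$lower_A),
                 exit_ref_offset_A = exit_ref_offset_A,
                 exit_threshold_A = exit_threshold_A,
                 anchors_A = anchors),
            class = "ko_site_map")
}

#' @export
print.ko_site_map <- function(x, ...) {
  cat(sprintf("<ko_site_map> completion at z >= %.2f A (ref +%g A, threshold %g A)\n",
              x$exit_z_A, x$exit_ref_offset_A, x$exit_threshold_A))
  print(x$bands, digits = 4)
  invisible(x)
}

#' Write a site map to JSON
#' @param sites a [site_map()].
#' @param path output file.
#' @export
write_site_map <- function(sites, path) {
  stopifnot(inherits(sites, "ko_site_map"))
  jsonlite::write_json(
    list(bands = sites$bands,
         exit_ref_offset_A = sites$exit_ref_offset_A,
         exit_threshold_A = sites$exit_threshold_A),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a site map from JSON
#' @param path JSON file written by [write_site_map()] (band boundaries may
#'   be edited freely as long as bands stay ordered and non-overlapping).
#' @return A `ko_site_map`.
#' @export
read_site_map <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  bands <- as.data.frame(j$bands)
  if (any(bands$upper_A <= bands$lower_A) ||
      any(diff(bands$lower_A) <= 0) ||
      any(bands$lower_A[-1] < bands$upper_A[-nrow(bands)] - 1e-9)) {
    stop("site bands must be ordered and non-overlapping", call. = FALSE)
  }
  exit_z <- j$exit_ref_offset_A + j$exit_threshold_A
  if (exit_z <= max(bands$upper_A)) {
    stop("completion coordinate must lie above the S0 band", call. = FALSE)
  }
  centers <- (bands$lower_A + bands$upper_A) / 2
  names(centers) <- bands$site
  structure(list(bands = bands, exit_z_A = exit_z,
                 internal_z_A = min(bands$lower_A),
                 exit_ref_offset_A = j$exit_ref_offset_A,
                 exit_threshold_A = j$exit_threshold_A,
                 anchors_A = c(centers,
                               internal = unname(min(bands$lower_A) - 3.5),
                               external = unname(exit_z + 2))),
            class = "ko_site_map")
}

#' Translate a site map along the pore axis
#'
#' Shifts every band, the bulk boundaries and the completion coordinate by
#' `dz_A`, e.g. to re-reference from the G314 carbonyl to the G314 C-alpha
#' center of mass.
#'
#' @param sites a [site_map()].
#' @param dz_A shift (A) added to all coordinates.
#' @return The translated `ko_site_map`.
#' @export
translate_site_map <- function(sites, dz_A) {
  stopifnot(inherits(sites, "ko_site_map"))
  sites$bands$lower_A <- sites$bands$lower_A + dz_A
  sites$bands$upper_A <- sites$bands$upper_A + dz_A
  sites$exit_z_A <- sites$exit_z_A + dz_A
  sites$internal_z_A <- sites$internal_z_A + dz_A
  sites$exit_ref_offset_A <- sites$exit_ref_offset_A + dz_A
  sites$anchors_A <- sites$anchors_A + dz_A
  sites
}
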