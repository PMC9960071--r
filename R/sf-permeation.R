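# Trajectory-level ion-permeation analysis. The core input contract is the
# long-format z-table: one row per (frame, ion) with columns time_ns, ion_id,
# z_A, all ions sampled on one uniform frame grid.

.check_tracks <- function(tracks) {
  need <- c("time_ns", "ion_id", "z_A")
  if (!all(need %in% names(tracks))) {
    stop("tracks need columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(tracks$z_A))) stop("z must be finite", call. = FALSE)
  times <- sort(unique(tracks$time_ns))
  if (length(times) > 2) {
    dt <- diff(times)
    if (diff(range(dt)) > 1e-6 * stats::median(dt)) {
      stop("frame times must be uniform", call. = FALSE)
    }
  }
  per_ion <- table(tracks$ion_id)
  if (length(unique(per_ion)) != 1 ||
      per_ion[1] != length(times)) {
    stop("all ions must share a common time base", call. = FALSE)
  }
  times
}

# per-sample region label: a filter site, "internal" or "external"
# (positions between bands and below exit_z fall to the nearest bulk side
# of the filter: below the Scav band -> internal, above the S0 band ->
# external vestibule, counted as external only for occupancy purposes)
.site_of <- function(z, sites) {
  bands <- sites$bands
  edges <- c(bands$lower_A, bands$upper_A[nrow(bands)])
  idx <- findInterval(z, edges)
  lab <- rep("external", length(z))
  lab[idx == 0] <- "internal"
  inside <- idx >= 1 & idx <= nrow(bands)
  lab[inside] <- bands$site[idx[inside]]
  lab
}

# suppress boundary chatter: a new label must persist for >= debounce frames,
# otherwise the previous label is kept
.debounce <- function(labels, debounce = 2) {
  if (debounce <= 1 || length(labels) < 2) return(labels)
  r <- rle(labels)
  if (length(r$lengths) < 2) return(labels)
  for (i in 2:length(r$values)) {
    if (r$lengths[i] < debounce) r$values[i] <- r$values[i - 1]
  }
  # merge again so consecutive equal runs collapse
  inverse.rle(list(lengths = r$lengths, values = r$values))
}

#' Classify selectivity-filter occupancy substates frame by frame
#'
#' Assigns each ion a site per frame from the site-map bands (with a
#' debounce: a band change must persist at least `debounce` frames) and
#' renders each frame's occupied sites as a substate label such as
#' `"Scav-S3-S2"` (sites ordered internal to external; `"empty"` when no ion
#' is in the filter). Frames where two ions fall in one band are retained but
#' flagged.
#'
#' @param tracks long-format z-table (`time_ns`, `ion_id`, `z_A`).
#' @param sites a [site_map()].
#' @param debounce minimum persistence (frames) of a site change.
#' @return An object of class `ko_occupancy`: data.frame with `time_ns`,
#'   `state`, `flagged`; the per-(frame, ion) site assignments are in
#'   `attr(, "assignments")`.
#' @export
classify_substates <- function(tracks, sites, debounce = 2) {
  stopifnot(inherits(sites, "ko_site_map"))
  times <- .check_tracks(tracks)
  tracks <- tracks[order(tracks$ion_id, tracks$time_ns), ]
  lab <- unlist(lapply(split(.site_of(tracks$z_A, sites), tracks$ion_id),
                       .debounce, debounce = debounce), use.names = FALSE)
  asg <- data.frame(time_ns = tracks$time_ns, ion_id = tracks$ion_id,
                    site = lab)
  site_order <- sites$bands$site
  in_filter <- asg[asg$site %in% site_order, ]
  state <- rep("empty", length(times))
  flagged <- rep(FALSE, length(times))
  if (nrow(in_filter)) {
    fidx <- match(in_filter$time_ns, times)
    by_frame <- split(in_filter$site, fidx)
    lab_of <- vapply(by_frame, function(ss) {
      paste(site_order[site_order %in% ss], collapse = "-")
    }, character(1))
    dup <- vapply(by_frame, anyDuplicated, integer(1)) > 0
    ii <- as.integer(names(by_frame))
    state[ii] <- lab_of
    flagged[ii] <- dup
  }
  if (any(flagged)) {
    warning(sprintf("%d frame(s) with two ions in one band (flagged)",
                    sum(flagged)))
  }
  structure(data.frame(time_ns = times, state = state, flagged = flagged),
            assignments = asg, class = c("ko_occupancy", "data.frame"))
}

#' Substate distribution from an occupancy series
#'
#' @param occupancy a [classify_substates()] result.
#' @param drop_flagged exclude flagged frames.
#' @return data.frame with `state`, `probability`, sorted by probability.
#' @export
substate_distribution <- function(occupancy, drop_flagged = FALSE) {
  st <- occupancy$state
  if (drop_flagged) st <- st[!occupancy$flagged]
  tab <- table(st) / length(st)
  out <- data.frame(state = names(tab), probability = as.numeric(tab))
  out[order(-out$probability), ]
}

#' Detect complete permeation events
#'
#' One event per contiguous passage between the internal and external bulk. A
#' passage is complete when the ion rises above the completion coordinate
#' (exit reference + 4 A threshold by default); an ion that re-enters and
#' exits again yields multiple events. Events are detected symmetrically in
#' both directions (outward = internal to external).
#'
#' @param tracks long-format z-table.
#' @param sites a [site_map()].
#' @return data.frame with `ion_id`, `time_ns` (completion time),
#'   `direction` (`"outward"`/`"inward"`), `mode` (`NA`, see
#'   [classify_modes()]).
#' @export
detect_permeations <- function(tracks, sites) {
  stopifnot(inherits(sites, "ko_site_map"))
  .check_tracks(tracks)
  tracks <- tracks[order(tracks$ion_id, tracks$time_ns), ]
  events <- lapply(split(tracks, tracks$ion_id), function(tr) {
    side <- ifelse(tr$z_A >= sites$exit_z_A, "ext",
                   ifelse(tr$z_A < sites$internal_z_A, "int", NA))
    known <- which(!is.na(side))
    if (length(known) < 2) return(NULL)
    s <- side[known]
    chg <- which(s[-1] != s[-length(s)])
    if (!length(chg)) return(NULL)
    data.frame(ion_id = tr$ion_id[1],
               time_ns = tr$time_ns[known[chg + 1]],
               direction = ifelse(s[chg + 1] == "ext", "outward", "inward"))
  })
  out <- do.call(rbind, c(events, list(NULL)))
  if (is.null(out) || !nrow(out)) {
    out <- data.frame(ion_id = integer(0), time_ns = numeric(0),
                      direction = character(0))
  }
  out <- out[order(out$time_ns), , drop = FALSE]
  rownames(out) <- NULL
  out$mode <- rep(NA_character_, nrow(out))
  out
}

#' Classify permeation events into conduction modes
#'
#' An outward permeation is `canonical` when the cavity site Scav becomes
#' newly occupied within `window_w` ns before the release of the permeating
#' ion from S0 (the knock-on coupling: an intracellular K+ binding below the
#' filter triggers the release above); `spontaneous_S0` when Scav is
#' unoccupied throughout that window; and `other` otherwise (e.g. Scav
#' occupied continuously since before the window, or no identifiable S0
#' release). Inward events are labelled `other`.
#'
#' @param events a [detect_permeations()] result.
#' @param occupancy a [classify_substates()] result on the same time base.
#' @param window_w coupling window (ns), default 1.0.
#' @return `events` with `mode` filled in and attribute `mode_fractions`
#'   (fractions over all events, summing to 1).
#' @export
classify_modes <- function(events, occupancy, window_w = 1.0) {
  stopifnot(inherits(occupancy, "ko_occupancy"))
  asg <- attr(occupancy, "assignments")
  times <- occupancy$time_ns
  if (nrow(events) &&
      (min(events$time_ns) < min(times) || max(events$time_ns) > max(times))) {
    stop("events outside the occupancy time range", call. = FALSE)
  }
  step <- if (length(times) > 1) times[2] - times[1] else 1
  scav_occ <- times %in% asg$time_ns[asg$site == "Scav"]
  modes <- character(nrow(events))
  for (i in seq_len(nrow(events))) {
    if (events$direction[i] != "outward") { modes[i] <- "other"; next }
    at_s0 <- asg$time_ns[asg$ion_id == events$ion_id[i] &
                           asg$site == "S0" &
                           asg$time_ns < events$time_ns[i]]
    if (!length(at_s0)) { modes[i] <- "other"; next }
    t_rel <- max(at_s0) + step  # first frame after leaving S0
    win <- which(times >= t_rel - window_w & times < t_rel)
    if (!length(win)) { modes[i] <- "other"; next }
    occ <- scav_occ[win]
    prev <- c(if (win[1] > 1) scav_occ[win[1] - 1] else FALSE,
              occ[-length(occ)])
    if (any(occ & !prev)) {
      modes[i] <- "canonical"
    } else if (!any(occ)) {
      modes[i] <- "spontaneous_S0"
    } else {
      modes[i] <- "other"
    }
  }
  events$mode <- modes
  fr <- c(canonical = 0, spontaneous_S0 = 0, other = 0)
  if (length(modes)) {
    tab <- table(factor(modes, levels = names(fr))) / length(modes)
    fr <- stats::setNames(as.numeric(tab), names(fr))
  }
  attr(events, "mode_fractions") <- fr
  events
}

#' S0 occupancy probability split by ion origin
#'
#' Finds all S0 dwell episodes, attributes each to the site occupied just
#' before entry (`from_SF` when the ion came up from S1, `from_external`
#' when it bound from the external side), discards episodes shorter than
#' `min_dwell`, and reports the fraction of total trajectory time S0 is
#' occupied by each class.
#'
#' @param tracks long-format z-table.
#' @param sites a [site_map()].
#' @param min_dwell minimum counted dwell (ns), default 0.4.
#' @param debounce passed to the site assignment.
#' @return List with `from_SF`, `from_external` (time fractions) and
#'   `episodes` (data.frame ion_id, start_ns, end_ns, dwell_ns, origin).
#' @export
s0_occupancy_by_origin <- function(tracks, sites, min_dwell = 0.4,
                                   debounce = 2) {
  occ <- classify_substates(tracks, sites, debounce = debounce)
  asg <- attr(occ, "assignments")
  times <- occ$time_ns
  step <- if (length(times) > 1) times[2] - times[1] else 1
  total <- length(times) * step
  eps <- lapply(split(asg, asg$ion_id), function(a) {
    a <- a[order(a$time_ns), ]
    r <- rle(a$site)
    ends <- cumsum(r$lengths)
    starts <- c(1, utils::head(ends, -1) + 1)
    is_s0 <- which(r$values == "S0")
    if (!length(is_s0)) return(NULL)
    data.frame(ion_id = a$ion_id[1],
               start_ns = a$time_ns[starts[is_s0]],
               end_ns = a$time_ns[ends[is_s0]],
               dwell_ns = r$lengths[is_s0] * step,
               origin = vapply(is_s0, function(j) {
                 if (j == 1) return("unknown")
                 before <- r$values[j - 1]
                 if (before %in% c("S1", "S2", "S3", "S4", "Scav")) "from_SF"
                 else "from_external"
               }, character(1)))
  })
  eps <- do.call(rbind, c(eps, list(NULL)))
  if (is.null(eps) || !nrow(eps)) {
    return(list(from_SF = 0, from_external = 0,
                episodes = data.frame(ion_id = integer(0),
                                      start_ns = numeric(0),
                                      end_ns = numeric(0),
                                      dwell_ns = numeric(0),
                                      origin = character(0))))
  }
  keep <- eps[eps$dwell_ns >= min_dwell, , drop = FALSE]
  list(from_SF = sum(keep$dwell_ns[keep$origin == "from_SF"]) / total,
       from_external = sum(keep$dwell_ns[keep$origin == "from_external"]) /
         total,
       episodes = eps)
}

#' Mean ion density along the pore axis
#'
#' Histogram of all (frame, ion) z positions inside the bin range, normalized
#' to a per-frame linear density so that the integral over z equals the mean
#' number of ions in the range.
#'
#' @param tracks long-format z-table.
#' @param z_bins bin edges (A), increasing.
#' @param reference_offset_A subtracted from z before binning (e.g. to
#'   re-reference from the G314 carbonyl to the G314 C-alpha convention).
#' @return data.frame with `z_mid_A`, `density_per_A`; the integral is in
#'   `attr(, "integral")` (mean ion count in range).
#' @export
density_profile <- function(tracks, z_bins, reference_offset_A = 0) {
  .check_tracks(tracks)
  if (any(diff(z_bins) <= 0)) stop("z_bins must increase", call. = FALSE)
  z <- tracks$z_A - reference_offset_A
  n_frames <- length(unique(tracks$time_ns))
  h <- graphics::hist(z[z >= z_bins[1] & z <= z_bins[length(z_bins)]],
                      breaks = z_bins, plot = FALSE)
  dens <- h$counts / n_frames / diff(z_bins)
  out <- data.frame(z_mid_A = h$mids, density_per_A = dens)
  attr(out, "integral") <- sum(dens * diff(z_bins))
  out
}

#' Current from a permeation-event count
#'
#' Net single-channel current `I = n e / t`: `n_events` net outward
#' elementary charges over `duration_ns` nanoseconds, in pA.
#'
#' @param n_events net outward event count (outward minus inward).
#' @param duration_ns trajectory duration (ns), `> 0`.
#' @return Current (pA).
#' @examples
#' current_from_flux(10, 100)  # 16.02 pA
#' @export
current_from_flux <- function(n_events, duration_ns) {
  if (duration_ns <= 0) stop("'duration_ns' must be > 0", call. = FALSE)
  n_events * ko_constants$e / (duration_ns * 1e-9) * 1e12
}

#' Two-state statistics of an aromatic side-chain dihedral
#'
#' Assigns each frame of a chi (C-Calpha-Cbeta-Cgamma) dihedral time series to
#' the low (~55 deg) or high (~160 deg) rotamer using a boundary with a
#' hysteresis band (a crossing only counts once the angle passes
#' `boundary +/- hysteresis`), and reports per-subunit state probabilities,
#' flip counts and an amplitude histogram.
#'
#' @param track data.frame with `time_ns`, `subunit`, `chi_deg` (degrees in
#'   `[-180, 180)`).
#' @param boundary state boundary (degrees), default 110.
#' @param hysteresis half-width of the hysteresis band (degrees).
#' @param hist_breaks histogram bin edges (degrees).
#' @return List with `per_subunit` (subunit, p_low, p_high, flips) and
#'   `histogram` (chi_mid_deg, count).
#' @export
dihedral_flip_stats <- function(track, boundary = 110, hysteresis = 10,
                                hist_breaks = seq(-180, 180, by = 5)) {
  need <- c("time_ns", "subunit", "chi_deg")
  if (!all(need %in% names(track))) {
    stop("track needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(track$chi_deg < -180 | track$chi_deg >= 180)) {
    stop("chi must be in [-180, 180)", call. = FALSE)
  }
  per <- lapply(split(track, track$subunit), function(tr) {
    tr <- tr[order(tr$time_ns), ]
    chi <- tr$chi_deg
    state <- integer(length(chi))  # 1 = low rotamer, 2 = high rotamer
    cur <- if (chi[1] >= boundary) 2L else 1L
    for (i in seq_along(chi)) {
      if (cur == 1L && chi[i] > boundary + hysteresis) cur <- 2L
      if (cur == 2L && chi[i] < boundary - hysteresis) cur <- 1L
      state[i] <- cur
    }
    data.frame(subunit = tr$subunit[1],
               p_low = mean(state == 1L), p_high = mean(state == 2L),
               flips = sum(diff(state) != 0))
  })
  h <- graphics::hist(track$chi_deg, breaks = hist_breaks, plot = FALSE)
  list(per_subunit = do.call(rbind, c(per, list(make.row.names = FALSE))),
       histogram = data.frame(chi_mid_deg = h$mids, count = h$counts))
}
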