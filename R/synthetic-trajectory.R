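#' Configuration for the ion-hopping trajectory generator
#'
#' Parameters of the scripted continuous-time hopping process that emulates
#' outward K+ conduction through the selectivity filter for analyzer
#' validation (it is a validation instrument with known ground truth, not a
#' physical model). A resident ion waits at S1, moves to S0 and is released
#' to the external side at scheduled event times; each event is constructed
#' as one of the three conduction modes:
#' \itemize{
#'   \item canonical: an incoming ion reaches Scav `coupling_delay_ns` before
#'     the S0 release (knock-on coupling);
#'   \item spontaneous_S0: the release happens with Scav vacant throughout
#'     the preceding window, the replacement entering only afterwards;
#'   \item other: Scav is already occupied from before the window (no new
#'     binding precedes the release).
#' }
#' After its Scav dwell the incoming ion ascends S4-S3-S2 with independent
#' exponential dwells (rate `rate_up_per_ns`) and becomes the next resident.
#' External K+ additionally binds the vacant S0 site from the outside as a
#' Poisson process with rate `k_on_per_mM_ns * ko_mM` and an exponential
#' dwell; binding episodes never overlap resident S0 occupancy.
#'
#' @param n_events number of programmed outward permeations.
#' @param mode_fractions named fractions (canonical, spontaneous_S0, other),
#'   realized exactly up to largest-remainder rounding of `n_events`.
#' @param rate_up_per_ns per-edge ascent hopping rate (1/ns).
#' @param coupling_delay_ns Scav-arrival-to-release delay of canonical
#'   events (ns); keep well inside the analysis window.
#' @param s0_lead_ns time the resident occupies S0 before a triggered
#'   release (ns).
#' @param spont_dwell_ns mean S0 dwell before a spontaneous release (ns;
#'   0.3 ns floor so the dwell spans several frames).
#' @param scav_dwell_ns handoff dwell at Scav (ns, fixed).
#' @param min_gap_ns,mean_extra_gap_ns inter-event gap = `min_gap_ns` plus an
#'   exponential of mean `mean_extra_gap_ns`.
#' @param ko_mM external K+ concentration (mM).
#' @param k_on_per_mM_ns external S0 binding rate per mM (1/ns).
#' @param ext_dwell_ns mean S0 dwell of external binders (ns; 0.3 ns floor).
#' @param jitter_A Gaussian positional jitter around site anchors (A).
#' @param step_ns frame step (ns); must be smaller than a fifth of the
#'   shortest mean dwell (`1/rate_up_per_ns`).
#' @return A list of class `ko_hop_config`.
#' @export
hop_config <- function(n_events = 25,
                       mode_fractions = c(canonical = 0.5,
                                          spontaneous_S0 = 0.4,
                                          other = 0.1),
                       rate_up_per_ns = 2, coupling_delay_ns = 0.3,
                       s0_lead_ns = 0.8, spont_dwell_ns = 0.5,
                       scav_dwell_ns = 0.4, min_gap_ns = 3,
                       mean_extra_gap_ns = 5, ko_mM = 5,
                       k_on_per_mM_ns = 2e-3, ext_dwell_ns = 0.8,
                       jitter_A = 0.35, step_ns = 0.05) {
  stopifnot(n_events >= 1, rate_up_per_ns > 0, step_ns > 0,
            all(mode_fractions >= 0), abs(sum(mode_fractions) - 1) < 1e-9,
            all(c("canonical", "spontaneous_S0", "other") %in%
                  names(mode_fractions)))
  if (step_ns >= (1 / rate_up_per_ns) / 5) {
    stop("frame step too coarse: must be < (1/rate_up_per_ns)/5",
         call. = FALSE)
  }
  structure(as.list(environment()), class = "ko_hop_config")
}

# exact integer mode counts by largest remainder
.mode_counts <- function(fractions, n) {
  raw <- fractions * n
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  base
}

#' Generate a synthetic ion-permeation trajectory with ground truth
#'
#' Renders the hopping process of [hop_config()] onto a uniform frame grid as
#' a long-format z-table (every ion present on every frame; ions park at bulk
#' anchor positions before entry and after exit). The truth log records every
#' permeation with its programmed mode, every S0 occupancy episode with its
#' origin, and every exponential ascent dwell.
#'
#' @param cfg a [hop_config()].
#' @param sites a [site_map()]; its band centers are the hop anchors, so
#'   analyzer and generator share one site definition.
#' @param seed integer seed.
#' @param render if `FALSE`, skip rendering the frame table (schedule and
#'   truth log only; used for dwell-statistics checks at large `n_events`).
#' @return List with `tracks` (`time_ns`, `ion_id`, `z_A`; `NULL` when
#'   `render = FALSE`), `sites`, and `truth` (see Details).
#' @export
gen_ion_trajectory <- function(cfg = hop_config(), sites = site_map(),
                               seed = 1, render = TRUE) {
  stopifnot(inherits(cfg, "ko_hop_config"), inherits(sites, "ko_site_map"))
  anchors <- sites$anchors_A
  .with_seed(seed, {
    counts <- .mode_counts(cfg$mode_fractions, cfg$n_events)
    modes <- sample(rep(names(counts), counts))
    dwell_log <- list()
    # each ion: vectors of segment start times and locations
    seg <- list()
    new_ion <- function() length(seg) + 1L
    add_seg <- function(id, starts, locs) {
      cur <- if (id <= length(seg)) seg[[id]] else {
        list(starts = numeric(0), locs = character(0))
      }
      seg[[id]] <<- list(starts = c(cur$starts, starts),
                         locs = c(cur$locs, locs))
    }
    ascend <- function(id, from_ns) {
      d <- stats::rexp(3, cfg$rate_up_per_ns)
      dwell_log[[length(dwell_log) + 1L]] <<-
        data.frame(site = c("S4", "S3", "S2"), dwell_ns = d)
      tt <- from_ns + cumsum(c(0, d))
      add_seg(id, tt, c("S4", "S3", "S2", "S1"))
      tt[4]  # arrival at S1
    }
    # first resident enters from the internal bulk at t ~ 0
    res <- new_ion()
    add_seg(res, c(0, 0.2), c("internal", "Scav"))
    ready <- ascend(res, 0.2 + cfg$scav_dwell_ns)
    events <- data.frame(ion_id = integer(0), release_ns = numeric(0),
                         mode = character(0))
    s0_int <- data.frame(ion_id = integer(0), start_ns = numeric(0),
                         end_ns = numeric(0), origin = character(0))
    t_prev <- 0
    for (k in seq_len(cfg$n_events)) {
      m <- modes[k]
      pre <- if (m == "spontaneous_S0") {
        0.3 + stats::rexp(1, 1 / max(cfg$spont_dwell_ns - 0.3, 0.05))
      } else cfg$s0_lead_ns
      t_rel <- max(t_prev + cfg$min_gap_ns +
                     stats::rexp(1, 1 / cfg$mean_extra_gap_ns),
                   ready + pre + 0.3)
      # resident: S1 -> S0 -> external
      add_seg(res, c(t_rel - pre, t_rel), c("S0", "external"))
      events <- rbind(events, data.frame(ion_id = res, release_ns = t_rel,
                                         mode = m))
      s0_int <- rbind(s0_int, data.frame(ion_id = res,
                                         start_ns = t_rel - pre,
                                         end_ns = t_rel,
                                         origin = "from_SF"))
      # incoming replacement
      inc <- new_ion()
      arr <- switch(m,
                    canonical = t_rel - cfg$coupling_delay_ns,
                    spontaneous_S0 = t_rel + 0.5,
                    other = t_rel - 1.6)
      dep <- switch(m,
                    canonical = t_rel + cfg$scav_dwell_ns,
                    spontaneous_S0 = arr + cfg$scav_dwell_ns,
                    other = t_rel + 0.3)
      add_seg(inc, c(0, arr), c("internal", "Scav"))
      ready <- ascend(inc, dep)
      res <- inc
      t_prev <- t_rel
    }
    duration <- ceiling((t_prev + 4) / cfg$step_ns) * cfg$step_ns
    # external S0 binders (Poisson, non-overlapping with resident occupancy)
    rate <- cfg$k_on_per_mM_ns * cfg$ko_mM
    n_cand <- stats::rpois(1, rate * max(duration - 2, 0))
    cand <- sort(stats::runif(n_cand, 1, duration - 1))
    occupied <- s0_int[, c("start_ns", "end_ns")]
    n_binders <- 0L
    for (a in cand) {
      d <- 0.3 + stats::rexp(1, 1 / max(cfg$ext_dwell_ns - 0.3, 0.05))
      b <- a + d
      if (b > duration - 0.5) next
      clash <- any(a < occupied$end_ns + 0.15 &
                     b > occupied$start_ns - 0.15)
      if (clash) next
      id <- new_ion()
      add_seg(id, c(0, a, b), c("external", "S0", "external"))
      occupied <- rbind(occupied, data.frame(start_ns = a, end_ns = b))
      s0_int <- rbind(s0_int, data.frame(ion_id = id, start_ns = a,
                                         end_ns = b,
                                         origin = "from_external"))
      n_binders <- n_binders + 1L
    }
    truth <- list(events = events,
                  mode_counts = counts,
                  mode_fractions = counts / sum(counts),
                  s0_intervals = s0_int[order(s0_int$start_ns), ],
                  n_binders = n_binders,
                  ascent_dwells = do.call(rbind, dwell_log),
                  duration_ns = duration, n_ions = length(seg),
                  config = cfg, seed = seed)
    tracks <- NULL
    if (render) {
      t_grid <- seq(0, duration, by = cfg$step_ns)
      nf <- length(t_grid)
      tracks <- do.call(rbind, lapply(seq_along(seg), function(id) {
        s <- seg[[id]]
        loc <- s$locs[findInterval(t_grid, s$starts)]
        data.frame(time_ns = t_grid, ion_id = id,
                   z_A = anchors[loc] +
                     stats::rnorm(nf, 0, cfg$jitter_A))
      }))
      rownames(tracks) <- NULL
    }
    list(tracks = tracks, sites = sites, truth = truth)
  })
}

#' Generate synthetic side-chain dihedral tracks
#'
#' Per-subunit two-state telegraph between the low (~55 deg) and high
#' (~160 deg) rotamer with stationary high-state probability `p_high` and
#' total switching intensity `flip_rate_per_ns`, plus Gaussian angular noise.
#'
#' @param p_high named or plain vector of per-subunit high-state
#'   probabilities.
#' @param flip_rate_per_ns total switching intensity (1/ns).
#' @param angles the two rotamer angles (degrees), low then high.
#' @param noise_sd_deg angular noise SD (degrees).
#' @param duration_ns,step_ns trajectory length and frame step.
#' @param seed integer seed.
#' @return List with `track` (`time_ns`, `subunit`, `chi_deg`) and `truth`
#'   (`p_high`, per-subunit true flip counts and state fractions).
#' @export
gen_dihedral_track <- function(p_high = c(A = 0.8, B = 0.2, C = 0.5,
                                          D = 0.9),
                               flip_rate_per_ns = 0.05, angles = c(55, 160),
                               noise_sd_deg = 6, duration_ns = 500,
                               step_ns = 0.1, seed = 1) {
  stopifnot(all(p_high > 0 & p_high < 1), flip_rate_per_ns > 0)
  subs <- if (!is.null(names(p_high))) names(p_high) else {
    LETTERS[seq_along(p_high)]
  }
  t_grid <- seq(0, duration_ns, by = step_ns)
  .with_seed(seed, {
    pieces <- lapply(seq_along(p_high), function(i) {
      p <- p_high[i]
      k_lh <- flip_rate_per_ns * p        # low -> high
      k_hl <- flip_rate_per_ns * (1 - p)  # high -> low
      state <- integer(length(t_grid))
      cur <- if (stats::runif(1) < p) 2L else 1L
      t_next <- stats::rexp(1, if (cur == 1L) k_lh else k_hl)
      flips <- 0L
      for (j in seq_along(t_grid)) {
        while (t_grid[j] >= t_next) {
          cur <- 3L - cur
          flips <- flips + 1L
          t_next <- t_next + stats::rexp(1, if (cur == 1L) k_lh else k_hl)
        }
        state[j] <- cur
      }
      chi <- angles[state] + stats::rnorm(length(state), 0, noise_sd_deg)
      chi <- pmin(pmax(chi, -179.9), 179.9)
      list(track = data.frame(time_ns = t_grid, subunit = subs[i],
                              chi_deg = chi),
           truth = data.frame(subunit = subs[i], p_high = unname(p),
                              frac_high = mean(state == 2L),
                              flips = flips))
    })
    list(track = do.call(rbind, lapply(pieces, `[[`, "track")),
         truth = list(per_subunit = do.call(rbind,
                                            lapply(pieces, `[[`, "truth")),
                      angles = angles, noise_sd_deg = noise_sd_deg,
                      flip_rate_per_ns = flip_rate_per_ns, seed = seed))
  })
}
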