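# Selectivity-filter trajectory analysis: substates, permeation events,
# conduction modes, S0 occupancy, density profiles, dihedral flips.

grid_tracks <- function(..., step = 0.05, n = 100) {
  # build a common-time-base z-table from per-ion z vectors (scalars are
  # held constant; the grid length follows the longest vector)
  ions <- list(...)
  n <- max(n, vapply(ions, length, integer(1)))
  t <- seq(0, by = step, length.out = n)
  do.call(rbind, lapply(seq_along(ions), function(i) {
    z <- ions[[i]]
    stopifnot(length(z) %in% c(1, n))
    data.frame(time_ns = t, ion_id = i, z_A = rep_len(z, n))
  }))
}

test_that("classify_substates labels hand-built configurations", {
  sm <- site_map()
  ctr <- sm$anchors_A
  # a single ion fixed at the S2 band center
  occ <- classify_substates(grid_tracks(ctr[["S2"]]), sm)
  expect_true(all(occ$state == "S2"))
  # two ions at S3 and S1 -> "S3-S1" (internal-to-external site order)
  occ2 <- classify_substates(grid_tracks(ctr[["S3"]], ctr[["S1"]]), sm)
  expect_true(all(occ2$state == "S3-S1"))
  # three ions: Scav, S3, S2
  occ3 <- classify_substates(
    grid_tracks(ctr[["Scav"]], ctr[["S3"]], ctr[["S2"]]), sm)
  expect_true(all(occ3$state == "Scav-S3-S2"))
  # two ions in one band: frames flagged but retained
  expect_warning(occ4 <- classify_substates(
    grid_tracks(ctr[["S2"]], ctr[["S2"]] + 0.2), sm), "flagged")
  expect_true(all(occ4$flagged))
  expect_equal(nrow(occ4), 100)
})

test_that("classify_substates agrees with the generator program frame by
          frame", {
  g <- gen_ion_trajectory(hop_config(n_events = 10), seed = 2)
  occ <- classify_substates(g$tracks, g$sites)
  # the resident parks at S1: the most frequent substate contains S1
  dist <- substate_distribution(occ)
  expect_match(dist$state[1], "S1")
  # generator S0 intervals are visible as S0-containing labels
  iv <- g$truth$s0_intervals[1, ]
  mid <- (iv$start_ns + iv$end_ns) / 2
  frame <- which.min(abs(occ$time_ns - mid))
  expect_match(occ$state[frame], "S0")
})

test_that("detect_permeations: bulk residents, hand-built passage,
          generator counts", {
  sm <- site_map()
  # ion resident in the external bulk throughout -> no events
  ev0 <- detect_permeations(grid_tracks(12), sm)
  expect_equal(nrow(ev0), 0)
  # hand-built outward passage internal -> ladder -> beyond threshold
  z <- c(rep(-14, 20), rep(sm$anchors_A[["Scav"]], 10),
         rep(sm$anchors_A[["S4"]], 10), rep(sm$anchors_A[["S2"]], 10),
         rep(sm$anchors_A[["S0"]], 10), rep(12, 40))
  ev1 <- detect_permeations(grid_tracks(z), sm)
  expect_equal(nrow(ev1), 1)
  expect_equal(ev1$direction, "outward")
  expect_equal(ev1$time_ns, 0.05 * 60)  # first frame past the threshold
  # re-entry and second exit -> two events (plus the inward crossing)
  z2 <- c(z, rep(-14, 20), rep(12, 20))
  ev2 <- detect_permeations(grid_tracks(z2), sm)
  expect_equal(sum(ev2$direction == "outward"), 2)
  expect_equal(sum(ev2$direction == "inward"), 1)
  # programmed event count is matched exactly
  g <- gen_ion_trajectory(hop_config(n_events = 25), seed = 5)
  ev <- detect_permeations(g$tracks, g$sites)
  expect_equal(nrow(ev), 25)
  expect_true(all(ev$direction == "outward"))
})

test_that("detect_permeations is invariant to time offset and uniform
          translation", {
  g <- gen_ion_trajectory(hop_config(n_events = 8), seed = 3)
  ev <- detect_permeations(g$tracks, g$sites)
  shifted <- g$tracks
  shifted$time_ns <- shifted$time_ns + 1000
  ev_t <- detect_permeations(shifted, g$sites)
  expect_equal(ev_t$time_ns, ev$time_ns + 1000)
  expect_equal(ev_t$ion_id, ev$ion_id)
  dz <- 25
  zshift <- g$tracks
  zshift$z_A <- zshift$z_A + dz
  ev_z <- detect_permeations(zshift, translate_site_map(g$sites, dz))
  expect_equal(ev_z$time_ns, ev$time_ns)
  expect_equal(ev_z$direction, ev$direction)
})

test_that("per-ion flux conservation holds on generator fixtures", {
  for (seed in c(4, 9)) {
    g <- gen_ion_trajectory(hop_config(n_events = 12), seed = seed)
    ev <- detect_permeations(g$tracks, g$sites)
    sm <- g$sites
    for (ion in unique(g$tracks$ion_id)) {
      tr <- g$tracks[g$tracks$ion_id == ion, ]
      side <- function(z) {
        if (z >= sm$exit_z_A) 1 else if (z < sm$internal_z_A) -1 else NA
      }
      s <- c(side(tr$z_A[1]), side(tr$z_A[nrow(tr)]))
      net <- sum(ev$direction == "outward" & ev$ion_id == ion) -
        sum(ev$direction == "inward" & ev$ion_id == ion)
      if (!any(is.na(s))) {
        expect_equal(net, (s[2] - s[1]) / 2)
      } else {
        expect_lte(abs(net), 1)  # partial transit at a trajectory edge
      }
    }
  }
})

test_that("classify_modes recovers the programmed conduction modes", {
  g <- gen_ion_trajectory(hop_config(n_events = 30), seed = 6)
  occ <- classify_substates(g$tracks, g$sites)
  ev <- classify_modes(detect_permeations(g$tracks, g$sites), occ,
                       window_w = 1.0)
  truth <- g$truth$events
  m <- match(ev$ion_id, truth$ion_id)
  expect_gt(mean(ev$mode == truth$mode[m]), 0.9)
  # fractions sum to 1
  expect_equal(sum(attr(ev, "mode_fractions")), 1)
  # events outside the occupancy range are rejected
  bad <- ev
  bad$time_ns[1] <- max(occ$time_ns) + 10
  expect_error(classify_modes(bad, occ), "outside")
})

test_that("s0_occupancy_by_origin separates filter and external origins and
          applies the dwell threshold", {
  sm <- site_map()
  s0 <- sm$anchors_A[["S0"]]
  # external ion dwelling 1 ns (20 frames) in S0 over a 10 ns track
  z_ext <- c(rep(12, 100), rep(s0, 20), rep(12, 80))
  # resident coming up from S1 for 30 frames (1.5 ns)
  z_res <- c(rep(sm$anchors_A[["S1"]], 120), rep(s0, 30),
             rep(sm$anchors_A[["S1"]], 50))
  tracks <- grid_tracks(z_ext, z_res, n = 200)
  out <- s0_occupancy_by_origin(tracks, sm, min_dwell = 0.4)
  expect_equal(out$from_external, 1.0 / 10, tolerance = 0.01)
  expect_equal(out$from_SF, 1.5 / 10, tolerance = 0.01)
  # dwell of 0.3 ns with a 0.4 ns threshold is not counted
  z_short <- c(rep(12, 100), rep(s0, 6), rep(12, 94))
  out2 <- s0_occupancy_by_origin(grid_tracks(z_short, n = 200), sm,
                                 min_dwell = 0.4)
  expect_equal(out2$from_external, 0)
  # no ion ever in S0 -> both zero
  out3 <- s0_occupancy_by_origin(grid_tracks(12, -14, n = 50), sm)
  expect_equal(out3$from_SF, 0)
  expect_equal(out3$from_external, 0)
})

test_that("density_profile conserves the mean ion count and localizes
          density", {
  sm <- site_map()
  # single stationary ion: delta-like peak integrating to 1
  tr <- grid_tracks(sm$anchors_A[["S2"]], n = 400)
  tr$z_A <- tr$z_A + rnorm(400, 0, 0.3)
  dp <- density_profile(tr, seq(-15, 13, 0.25))
  expect_equal(attr(dp, "integral"), 1, tolerance = 1e-9)
  expect_lt(abs(dp$z_mid_A[which.max(dp$density_per_A)] -
                  sm$anchors_A[["S2"]]), 0.5)
  # uniform positions -> flat profile within sampling error
  set.seed(13)
  n <- 20000
  tru <- data.frame(time_ns = rep(seq(0, 0.05 * (n / 4 - 1), 0.05), 4),
                    ion_id = rep(1:4, each = n / 4),
                    z_A = runif(n, -10, 10))
  dpu <- density_profile(tru, seq(-10, 10, 2))
  expect_equal(attr(dpu, "integral"), 4, tolerance = 1e-9)
  expect_lt(diff(range(dpu$density_per_A)) / mean(dpu$density_per_A), 0.25)
  # sticky-site generator: peak in the dominant band (S1 parking)
  g <- gen_ion_trajectory(hop_config(n_events = 8), seed = 3)
  dpg <- density_profile(g$tracks,
                         seq(sm$bands$lower_A[1], sm$bands$upper_A[6], 0.5))
  expect_lt(abs(dpg$z_mid_A[which.max(dpg$density_per_A)] -
                  sm$anchors_A[["S1"]]), 1)
})

test_that("current_from_flux converts event counts to pA", {
  expect_equal(current_from_flux(0, 100), 0)
  expect_equal(current_from_flux(10, 100), 16.02)
  expect_equal(current_from_flux(5 - 5, 100), 0)
  expect_error(current_from_flux(1, 0), "> 0")
})

test_that("dihedral_flip_stats: constant, square-wave, generator
          recovery", {
  t <- seq(0, 9.95, 0.05)
  const <- data.frame(time_ns = t, subunit = "A", chi_deg = 160)
  s <- dihedral_flip_stats(const)
  expect_equal(s$per_subunit$p_high, 1)
  expect_equal(s$per_subunit$flips, 0)
  sq <- data.frame(time_ns = t, subunit = "A",
                   chi_deg = rep(c(55, 160, 55, 160, 55), each = 40))
  expect_equal(dihedral_flip_stats(sq)$per_subunit$flips, 4)
  # generator with asymmetric per-subunit probabilities
  g <- gen_dihedral_track(p_high = c(A = 0.8, B = 0.3),
                          flip_rate_per_ns = 0.4, duration_ns = 400,
                          seed = 17)
  st <- dihedral_flip_stats(g$track)
  m <- match(st$per_subunit$subunit, g$truth$per_subunit$subunit)
  expect_equal(st$per_subunit$p_high, g$truth$per_subunit$frac_high[m],
               tolerance = 0.02)
  # transitions faster than one frame cannot be seen; allow a small deficit
  expect_lte(max(abs(st$per_subunit$flips - g$truth$per_subunit$flips[m])),
             4)
  # programmed probabilities recovered within a binomial-style tolerance
  expect_lt(abs(st$per_subunit$p_high[1] - 0.8), 0.1)
  expect_lt(abs(st$per_subunit$p_high[2] - 0.3), 0.1)
  expect_error(dihedral_flip_stats(data.frame(time_ns = 1, subunit = "A",
                                              chi_deg = 200)),
               "-180")
})
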