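#' Detect amplitude stabilization in a pulse train
#'
#' Returns the (1-based) index of the first pulse at which the amplitude has
#' stabilized: the first position where, over a sliding window of `window`
#' consecutive pulses, the peak-to-peak spread relative to the window mean is
#' below `tol`. Typical recordings stabilize after four to six pulses at the
#' first perfusion step.
#'
#' @param amplitudes pulse-by-pulse peak amplitudes (at least 4).
#' @param tol relative tolerance (default 0.05).
#' @param window sliding-window length in pulses (default 3).
#' @return Integer index of the first stabilized pulse, or `NA_integer_`
#'   (with a warning) if the series never stabilizes.
#' @examples
#' detect_stabilization(c(0.5, 0.8, 0.95, 1.0, 1.01, 1.0))  # 4
#' @export
detect_stabilization <- function(amplitudes, tol = 0.05, window = 3) {
  n <- length(amplitudes)
  if (n < 4) stop("need at least 4 pulses", call. = FALSE)
  for (i in seq_len(n - window + 1)) {
    w <- amplitudes[i:(i + window - 1)]
    m <- mean(abs(w))
    if (m == 0 || diff(range(w)) / m < tol) return(i)
  }
  warning("amplitudes never stabilized; series should be excluded")
  NA_integer_
}

#' Build a per-cell concentration series from pulse tables
#'
#' Implements the recording protocol of the concentration-series experiments:
#' per concentration, the unspecific (blank) mean is subtracted at identical
#' cursor positions, stabilization is detected at the first (reference)
#' concentration, and exactly three stabilized points are retained per
#' concentration. A series that does not reach the highest requested
#' concentration is excluded (returned as `NULL` with a reason attribute).
#'
#' @param pulses data.frame with columns `cell`, `concentration_mM`,
#'   `point_index`, `amplitude` — peak currents pulse by pulse (one cell).
#' @param blanks optional data.frame with the same columns from water-injected
#'   cells; the per-(concentration, point) mean is subtracted.
#' @param concs required concentration ladder; defaults to the concentrations
#'   present, and the series is excluded if `max(concs)` is missing.
#' @param n_keep points retained per concentration (default 3).
#' @param tol,window stabilization parameters, see [detect_stabilization()].
#' @return An object of class `ko_conc_series`: list with `cell`, `points`
#'   (concentration_mM, point_index, amplitude), `norm_ref` (mean of the
#'   retained reference triplet) and `normalized` (per-concentration means
#'   divided by `norm_ref`). An excluded series returns `NULL` with a
#'   warning stating the reason.
#' @export
build_series <- function(pulses, blanks = NULL, concs = NULL, n_keep = 3,
                         tol = 0.05, window = 3) {
  need <- c("cell", "concentration_mM", "point_index", "amplitude")
  if (!all(need %in% names(pulses))) {
    stop("pulses needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (length(unique(pulses$cell)) != 1) {
    stop("build_series takes one cell at a time", call. = FALSE)
  }
  if (is.null(concs)) concs <- sort(unique(pulses$concentration_mM))
  have <- sort(unique(pulses$concentration_mM))
  if (!max(concs) %in% have) {
    warning(sprintf("series excluded: did not reach the %g mM perfusion step",
                    max(concs)))
    return(NULL)
  }
  n_blanks <- NA_integer_
  if (!is.null(blanks)) {
    n_blanks <- length(unique(blanks$cell))
    bl <- stats::aggregate(amplitude ~ concentration_mM + point_index,
                           blanks, mean)
    key_p <- paste(pulses$concentration_mM, pulses$point_index)
    key_b <- paste(bl$concentration_mM, bl$point_index)
    m <- match(key_p, key_b)
    if (any(is.na(m))) stop("blank cursors do not match series cursors",
                            call. = FALSE)
    pulses$amplitude <- subtract_unspecific(pulses$amplitude,
                                            bl$amplitude[m], n_blanks)
  }
  ref_conc <- min(concs)
  ref <- pulses[pulses$concentration_mM == ref_conc, ]
  ref <- ref[order(ref$point_index), ]
  i0 <- if (nrow(ref) >= 4) {
    detect_stabilization(ref$amplitude, tol = tol, window = window)
  } else 1L
  if (is.na(i0)) {
    warning("series excluded: amplitudes never stabilized")
    return(NULL)
  }
  keep <- function(df, from) {
    df <- df[order(df$point_index), ]
    df[seq(from, length.out = min(n_keep, nrow(df) - from + 1)), ]
  }
  pieces <- lapply(sort(unique(pulses$concentration_mM)), function(cc) {
    keep(pulses[pulses$concentration_mM == cc, ], if (cc == ref_conc) i0 else 1L)
  })
  pts <- do.call(rbind, pieces)
  means <- stats::aggregate(amplitude ~ concentration_mM, pts, mean)
  norm_ref <- means$amplitude[means$concentration_mM == ref_conc]
  structure(list(cell = pulses$cell[1],
                 points = pts[, c("concentration_mM", "point_index",
                                  "amplitude")],
                 norm_ref = norm_ref, n_blanks = n_blanks,
                 normalized = data.frame(
                   concentration_mM = means$concentration_mM,
                   value = means$amplitude / norm_ref)),
            class = "ko_conc_series")
}

#' @export
print.ko_conc_series <- function(x, ...) {
  cat(sprintf("<ko_conc_series> cell %s, %d concentrations\n",
              as.character(x$cell), nrow(x$normalized)))
  print(x$normalized, digits = 4)
  invisible(x)
}

#' GHK driving-force correction of a normalized dose-response curve
#'
#' The theoretical normalized current `Ith(C)` expected from the loss of
#' outward driving force alone (no channel modulation) is the GHK current
#' ratio between `C` and the reference concentration. The default additive
#' mode adds back the theoretical reduction,
#' `corrected = observed + (1 - Ith)`; the multiplicative mode divides,
#' `corrected = observed / Ith`. The two agree to first order when
#' `|1 - Ith| << 1`.
#'
#' @param series data.frame with columns `concentration_mM`, `value`
#'   (normalized observed means), or a `ko_conc_series`.
#' @param vm membrane potential of the test pulse (mV), default +60.
#' @param kin internal K+ (mM), default 108 (oocyte).
#' @param mode `"additive"` (default) or `"multiplicative"`.
#' @param temp_K temperature (K).
#' @return data.frame with `concentration_mM`, `observed`, `ith`, `corrected`.
#' @export
ghk_correct <- function(series, vm = 60, kin = 108,
                        mode = c("additive", "multiplicative"),
                        temp_K = ko_constants$T_default) {
  mode <- match.arg(mode)
  if (inherits(series, "ko_conc_series")) series <- series$normalized
  cc <- series$concentration_mM
  ref <- min(cc)
  ith <- ghk_current_ratio(kin, cc, kin, ref, vm, temp_K)
  corrected <- if (mode == "additive") {
    series$value + (1 - ith)
  } else {
    series$value / ith
  }
  data.frame(concentration_mM = cc, observed = series$value, ith = ith,
             corrected = corrected)
}

#' Fit Hill parameters over a set of cells
#'
#' Fits the Hill inhibition equation per cell and reports the parameter means
#' with their SEM over cells (the per-cell reporting shape of dose-response
#' tables), or a single pooled fit over all points.
#'
#' @param cells either a list of data.frames with columns `concentration_mM`
#'   and `corrected` (or `value`), one per cell, or a single data.frame with
#'   an additional `cell` column.
#' @param aggregate `"per_cell"` (default) or `"pooled"`.
#' @return For `"per_cell"`: list with `mean` (imax, ic50, nh), `sem`, `n`,
#'   `per_cell` (data.frame of per-cell estimates with convergence flags) and
#'   `fits`. For `"pooled"`: a single [fit_result()].
#' @export
fit_series <- function(cells, aggregate = c("per_cell", "pooled")) {
  aggregate <- match.arg(aggregate)
  val_col <- function(df) {
    if ("corrected" %in% names(df)) df$corrected
    else if ("value" %in% names(df)) df$value
    else stop("need a 'corrected' or 'value' column", call. = FALSE)
  }
  if (is.data.frame(cells)) {
    if (!"cell" %in% names(cells)) {
      cells <- list(cells)
    } else {
      cells <- split(cells, cells$cell)
    }
  }
  if (aggregate == "pooled") {
    cc <- unlist(lapply(cells, function(d) d$concentration_mM))
    vv <- unlist(lapply(cells, val_col))
    return(fit_hill(cc, vv))
  }
  fits <- lapply(cells, function(d) fit_hill(d$concentration_mM, val_col(d)))
  per <- data.frame(
    cell = if (!is.null(names(cells))) names(cells) else seq_along(cells),
    imax = vapply(fits, function(f) f$params["imax"], numeric(1)),
    ic50 = vapply(fits, function(f) f$params["ic50"], numeric(1)),
    nh = vapply(fits, function(f) f$params["nh"], numeric(1)),
    converged = vapply(fits, function(f) f$converged, logical(1)))
  ok <- per$converged
  if (!any(ok)) warning("no cell fit converged")
  est <- per[ok, c("imax", "ic50", "nh"), drop = FALSE]
  n <- nrow(est)
  list(mean = colMeans(est),
       sem = vapply(est, function(v) {
         if (n > 1) stats::sd(v) / sqrt(n) else NA_real_
       }, numeric(1)),
       n = n, per_cell = per, fits = fits)
}

#' Two-point inhibition statistic
#'
#' Simplified external-K+ sensitivity measure comparing currents at the two
#' endpoint concentrations: `1 - I_high / I_low`. Negative values indicate
#' potentiation by high external K+.
#'
#' @param i_low current (or normalized value) at the low reference
#'   concentration; must be nonzero.
#' @param i_high current at the high test concentration.
#' @return Signed inhibition fraction.
#' @export
two_point_inhibition <- function(i_low, i_high) {
  if (any(i_low == 0)) stop("zero low-condition current", call. = FALSE)
  1 - i_high / i_low
}

#' Two-sample t test on parameter estimates
#'
#' Thin wrapper around [stats::t.test()] (Welch by default) returning the
#' statistic and p value, provided as plumbing for comparing per-cell
#' parameter estimates between channel variants.
#'
#' @param x,y numeric vectors of per-cell estimates.
#' @param var.equal passed to [stats::t.test()].
#' @return List with `t`, `df`, `p_value`, `mean_x`, `mean_y`.
#' @export
two_sample_t <- function(x, y, var.equal = FALSE) {
  tt <- stats::t.test(x, y, var.equal = var.equal)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_x = mean(x), mean_y = mean(y))
}
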