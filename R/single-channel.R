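#' All-point amplitude histogram of single-channel sweeps
#'
#' Bins every sample of the supplied (baseline-subtracted) sweeps exactly
#' once. Bin edges are aligned so that 0 pA falls on an edge.
#'
#' @param sweeps a list of numeric current vectors (pA), or one vector.
#' @param bin_width bin width (pA), default 0.01.
#' @param voltage_mV optional voltage tag stored on the result.
#' @return An object of class `ko_aph`: list with `bin_edges`, `mids`,
#'   `counts`, `n_sweeps`, `n_samples`, `bin_width`, `voltage_mV`,
#'   `degenerate` (TRUE when all samples fall in a single bin).
#' @export
all_point_histogram <- function(sweeps, bin_width = 0.01,
                                voltage_mV = NA_real_) {
  if (is.numeric(sweeps)) sweeps <- list(sweeps)
  x <- unlist(sweeps, use.names = FALSE)
  if (!length(x)) stop("empty input", call. = FALSE)
  lo <- floor(min(x) / bin_width) * bin_width
  hi <- ceiling(max(x) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  edges <- seq(lo, hi, by = bin_width)
  if (edges[length(edges)] < hi) edges <- c(edges, hi)
  counts <- tabulate(findInterval(x, edges, rightmost.closed = TRUE,
                                  all.inside = TRUE),
                     nbins = length(edges) - 1)
  degenerate <- sum(counts > 0) == 1
  if (degenerate && diff(range(x)) > 0) {
    warning("bin width exceeds the signal range; single occupied bin")
  }
  structure(list(bin_edges = edges,
                 mids = (edges[-1] + edges[-length(edges)]) / 2,
                 counts = counts, n_sweeps = length(sweeps),
                 n_samples = length(x), bin_width = bin_width,
                 voltage_mV = voltage_mV, degenerate = degenerate),
            class = "ko_aph")
}

#' @export
print.ko_aph <- function(x, ...) {
  cat(sprintf(
    "<ko_aph> %d samples from %d sweep(s), %d bins of %g pA [%g, %g]\n",
    x$n_samples, x$n_sweeps, length(x$counts), x$bin_width,
    min(x$bin_edges), max(x$bin_edges)))
  invisible(x)
}

#' Subtract the closed-state baseline from single-channel sweeps
#'
#' Default baseline is the mode of the per-sweep amplitude density (the
#' closed state dominates slow single-channel records); a user constant
#' overrides it.
#'
#' @param sweeps list of numeric vectors.
#' @param baseline optional numeric constant used for every sweep.
#' @return List of baseline-subtracted sweeps.
#' @export
subtract_baseline <- function(sweeps, baseline = NULL) {
  if (is.numeric(sweeps)) sweeps <- list(sweeps)
  lapply(sweeps, function(s) {
    b <- if (is.null(baseline)) {
      d <- stats::density(s)
      d$x[which.max(d$y)]
    } else baseline
    s - b
  })
}

# sum of k Gaussian components evaluated on bin mids (counts scale)
.gauss_mix_counts <- function(mids, w, mu, sd, total, bin_width) {
  out <- numeric(length(mids))
  for (j in seq_along(w)) {
    out <- out + w[j] * total * bin_width * stats::dnorm(mids, mu[j], sd[j])
  }
  out
}

#' Fit Gaussian peaks to an all-point histogram
#'
#' Least-squares fit of a sum of `k` Gaussian components to the histogram
#' counts (the usual treatment of all-point histograms), with the number of
#' components selected by a BIC-type criterion up to `k_max`. The component nearest 0 pA is
#' the baseline (closed) level; the "largest peak" is the non-baseline
#' component with the largest mixture weight (area), used for conductance
#' curves. Peaks are reported sorted by weight.
#'
#' @param h a [all_point_histogram()] result.
#' @param k_max maximum number of components.
#' @return An object of class `ko_gauss_peaks`: list with `peaks`
#'   (data.frame mean_pA, sd_pA, weight, sorted by weight), `k`, `baseline`
#'   (index into `peaks`), `largest_peak` (mean of the dominant non-baseline
#'   component, `NA` if `k = 1`), `converged`, `ic` (BIC-type criterion).
#' @export
fit_gaussian_peaks <- function(h, k_max = 3) {
  stopifnot(inherits(h, "ko_aph"))
  occ <- sum(h$counts > 0)
  if (occ < 2 * k_max) k_max <- max(1, occ %/% 2)
  mids <- h$mids; counts <- h$counts; n <- h$n_samples; bw <- h$bin_width
  sd0 <- max(stats::sd(rep(mids, counts)), bw)
  fit_k <- function(k) {
    qs <- stats::quantile(rep(mids, counts), probs = (seq_len(k) - 0.5) / k)
    start <- as.list(c(stats::setNames(qs, paste0("mu", 1:k)),
                       stats::setNames(rep(log(sd0 / k), k),
                                       paste0("lsd", 1:k)),
                       stats::setNames(rep(log(1 / k), k),
                                       paste0("lw", 1:k))))
    fn <- function(p) {
      mu <- unlist(p[paste0("mu", 1:k)])
      sd <- exp(unlist(p[paste0("lsd", 1:k)]))
      w <- exp(unlist(p[paste0("lw", 1:k)]))
      .gauss_mix_counts(mids, w, mu, sd, n, bw)
    }
    r <- .nls_fit(fn, start, counts, maxiter = 300)
    if (is.null(r)) return(NULL)
    npts <- length(counts)
    r$ic <- npts * log(max(r$rss, 1e-300) / npts) + 3 * k * log(npts)
    r$k <- k
    r
  }
  best <- NULL
  for (k in seq_len(k_max)) {
    r <- fit_k(k)
    if (!is.null(r) && (is.null(best) || r$ic < best$ic)) best <- r
  }
  if (is.null(best)) {
    return(structure(list(peaks = data.frame(mean_pA = numeric(0),
                                             sd_pA = numeric(0),
                                             weight = numeric(0)),
                          k = 0, baseline = NA_integer_,
                          largest_peak = NA_real_, converged = FALSE,
                          ic = NA_real_),
                     class = "ko_gauss_peaks"))
  }
  k <- best$k
  mu <- unname(best$params[paste0("mu", 1:k)])
  sd <- exp(unname(best$params[paste0("lsd", 1:k)]))
  w <- exp(unname(best$params[paste0("lw", 1:k)]))
  w <- w / sum(w)
  ord <- order(w, decreasing = TRUE)
  peaks <- data.frame(mean_pA = mu[ord], sd_pA = sd[ord], weight = w[ord])
  baseline <- which.min(abs(peaks$mean_pA))
  open_idx <- setdiff(seq_len(k), baseline)
  largest <- if (length(open_idx)) peaks$mean_pA[open_idx[1]] else NA_real_
  structure(list(peaks = peaks, k = k, baseline = baseline,
                 largest_peak = largest, converged = best$converged,
                 ic = best$ic),
            class = "ko_gauss_peaks")
}

#' @export
print.ko_gauss_peaks <- function(x, ...) {
  cat(sprintf("<ko_gauss_peaks> k = %d, largest open peak = %.4g pA\n",
              x$k, x$largest_peak))
  print(x$peaks, digits = 4)
  invisible(x)
}

#' Single-channel conductance from an amplitude-voltage relation
#'
#' Linear regression of single-channel amplitude (pA) on voltage (mV); the
#' slope times 1000 is the chord conductance in pS, and the x-intercept
#' estimates the reversal potential.
#'
#' @param voltage_mV voltages (mV), at least 3.
#' @param amplitude_pA single-channel amplitudes (pA).
#' @return List with `conductance_pS`, `slope_se_pS`, `intercept_pA`,
#'   `reversal_mV`, `flagged` (zero slope) and the `lm` fit.
#' @export
conductance_from_iv <- function(voltage_mV, amplitude_pA) {
  if (length(voltage_mV) < 3) stop("need at least 3 voltages", call. = FALSE)
  fit <- stats::lm(amplitude_pA ~ voltage_mV)
  co <- suppressWarnings(summary(fit))$coefficients
  slope <- unname(co["voltage_mV", "Estimate"])
  flagged <- slope == 0 ||
    (is.finite(co["voltage_mV", "Std. Error"]) &&
       abs(slope) < .Machine$double.eps * 100)
  list(conductance_pS = slope * 1000,
       slope_se_pS = unname(co["voltage_mV", "Std. Error"]) * 1000,
       intercept_pA = unname(co["(Intercept)", "Estimate"]),
       reversal_mV = if (slope != 0) {
         -unname(co["(Intercept)", "Estimate"]) / slope
       } else NA_real_,
       flagged = flagged, fit = fit)
}

#' Test for equality of two regression slopes
#'
#' Standard two-line analysis-of-covariance slope test: an F test of the
#' voltage-by-group interaction against the common-slope model.
#'
#' @param line1,line2 data.frames with columns `x` and `y` (the points each
#'   line was fitted to).
#' @return List with `F`, `df1`, `df2`, `p_value`, and the two slopes.
#' @export
compare_slopes <- function(line1, line2) {
  for (d in list(line1, line2)) {
    if (!all(c("x", "y") %in% names(d))) {
      stop("line data need columns 'x' and 'y'", call. = FALSE)
    }
    if (nrow(d) < 3) stop("each line needs residual df >= 1", call. = FALSE)
    if (stats::var(d$x) == 0) stop("degenerate x variance", call. = FALSE)
  }
  dat <- rbind(data.frame(line1, g = "a"), data.frame(line2, g = "b"))
  dat$g <- factor(dat$g)
  m0 <- stats::lm(y ~ x + g, data = dat)
  m1 <- stats::lm(y ~ x * g, data = dat)
  if (summary(m1)$sigma == 0 && summary(m0)$sigma == 0) {
    # both models interpolate (e.g. identical exact lines): no evidence of
    # different slopes
    return(list(F = 0, df1 = 1, df2 = nrow(dat) - 4, p_value = 1,
                slope1 = stats::coef(stats::lm(y ~ x, line1))[["x"]],
                slope2 = stats::coef(stats::lm(y ~ x, line2))[["x"]]))
  }
  an <- stats::anova(m0, m1)
  f_stat <- an$F[2]
  p_val <- an$`Pr(>F)`[2]
  if (is.na(f_stat)) {  # no interaction information (e.g. duplicated data)
    f_stat <- 0
    p_val <- 1
  }
  list(F = f_stat, df1 = an$Df[2], df2 = an$Res.Df[2],
       p_value = p_val,
       slope1 = stats::coef(stats::lm(y ~ x, line1))[["x"]],
       slope2 = stats::coef(stats::lm(y ~ x, line2))[["x"]])
}

#' Percent reduction in absolute permeability
#'
#' `100 * (1 - p_high / p_low)`: the percent loss of GHK absolute
#' permeability between a low and a high external K+ condition.
#'
#' @param p_low permeability at the low-K+ condition (cm/s), `> 0`.
#' @param p_high permeability at the high-K+ condition (cm/s).
#' @return Percent reduction (negative = increase).
#' @examples
#' permeability_reduction(5.82e-4, 2.47e-4)  # ~57.6%
#' @export
permeability_reduction <- function(p_low, p_high) {
  if (p_low <= 0) stop("'p_low' must be > 0", call. = FALSE)
  100 * (1 - p_high / p_low)
}
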