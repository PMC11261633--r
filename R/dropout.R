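# AIS interval location and the chord-enclosed "signal dropout" area.

#' AIS interval on the profile axis
#'
#' @param distal_edge,proximal_edge signed profile positions in um with
#'   `distal_edge < proximal_edge` (distal is negative by convention)
#' @param method how the edges were obtained: `"manual"` (the default
#'   pipeline practice, mirroring marker/morphology-based manual calls) or
#'   `"marker-trough"` (automated, from [detect_ais_interval()])
#' @return An object of class `ais_interval`.
#' @export
ais_interval <- function(distal_edge, proximal_edge,
                         method = c("manual", "marker-trough")) {
  if (!is.finite(distal_edge) || !is.finite(proximal_edge) ||
      distal_edge >= proximal_edge)
    stop("need finite edges with distal_edge < proximal_edge")
  structure(list(distal_edge = as.numeric(distal_edge),
                 proximal_edge = as.numeric(proximal_edge),
                 method = match.arg(method)),
            class = "ais_interval")
}

#' Detect the AIS interval from a structural-marker trough
#'
#' Automates the manual marker-based boundary calls for synthetic
#' self-tests: markers such as actin are relatively depleted inside the
#' AIS, so the AIS shows up as a trough in the normalized marker profile.
#' The reference level is the mean of the medians of the flanking 25% of
#' bins on each side; the detected interval is the longest contiguous run
#' of bins below `trough_fraction` times that reference, provided the run
#' is at least `min_run` um long.
#'
#' @param marker_profile a normalized `intensity_profile` of the
#'   structural-marker channel
#' @param trough_fraction fraction of the flanking level below which a bin
#'   counts as inside the trough (default 0.6)
#' @param min_run minimum trough length in um (default 2)
#' @return An [ais_interval()] with method `"marker-trough"`.
#' @export
detect_ais_interval <- function(marker_profile, trough_fraction = 0.6,
                                min_run = 2) {
  stopifnot(inherits(marker_profile, "intensity_profile"))
  if (!isTRUE(marker_profile$normalized))
    stop("marker profile must be normalized")
  v <- marker_profile$values
  pos <- marker_profile$positions
  nb <- length(v)
  nf <- max(1L, floor(nb * 0.25))
  ref <- mean(c(stats::median(v[seq_len(nf)], na.rm = TRUE),
                stats::median(v[seq.int(nb - nf + 1L, nb)], na.rm = TRUE)))
  below <- !is.na(v) & v < trough_fraction * ref
  runs <- rle(below)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand <- which(runs$values)
  if (length(cand) > 0L) {
    lens <- runs$lengths[cand] * marker_profile$bin_width
    cand <- cand[lens >= min_run]
  }
  if (length(cand) == 0L)
    stop("no trough detected in marker profile")
  best <- cand[which.max(runs$lengths[cand])]
  hw <- marker_profile$bin_width / 2
  ais_interval(pos[starts[best]] - hw, pos[ends[best]] + hw,
               method = "marker-trough")
}

# piecewise-linear interpolation of a profile over its non-missing bins
profile_fun <- function(profile, x) {
  ok <- !is.na(profile$values)
  if (sum(ok) < 2L) stop("profile has fewer than two non-missing bins")
  stats::approx(profile$positions[ok], profile$values[ok], xout = x,
                rule = 1)$y
}

check_interval <- function(profile, interval) {
  stopifnot(inherits(profile, "intensity_profile"),
            inherits(interval, "ais_interval"))
  rng <- range(profile$positions)
  if (interval$distal_edge < rng[1L] || interval$proximal_edge > rng[2L])
    stop("interval edges lie outside the profile range")
}

# evaluation grid over the interval: both edges plus every interior bin centre
interval_grid <- function(profile, interval) {
  inner <- profile$positions[profile$positions > interval$distal_edge &
                               profile$positions < interval$proximal_edge]
  xs <- c(interval$distal_edge, inner, interval$proximal_edge)
  list(x = xs, y = profile_fun(profile, xs))
}

#' Chord-enclosed signal dropout area
#'
#' Draws the straight chord joining the normalized profile's values at the
#' distal and proximal AIS edges and integrates the area where the profile
#' lies below the chord: `integral of max(chord(x) - y(x), 0) dx` over the
#' interval. Both the profile (linearly interpolated between bin centres)
#' and the chord are piecewise linear, so the integral is evaluated
#' exactly by the trapezoid rule on the bin grid refined with the
#' chord-profile crossing points. Only the below-chord (dip) part counts,
#' because the statistic quantifies a signal depression. Units: um (area
#' under a unit-normalized intensity times position in um).
#'
#' @param profile a normalized `intensity_profile`
#' @param interval an [ais_interval()] inside the profile range
#' @return Nonnegative dropout area in um.
#' @export
chord_dropout_area <- function(profile, interval) {
  check_interval(profile, interval)
  g <- interval_grid(profile, interval)
  n <- length(g$x)
  ya <- g$y[1L]; yb <- g$y[n]
  diff_at <- function(x, y)
    ya + (yb - ya) * (x - g$x[1L]) / (g$x[n] - g$x[1L]) - y
  d <- diff_at(g$x, g$y)
  # refine the grid at chord/profile crossings so the positive part is
  # integrated exactly (both curves are piecewise linear)
  xs <- g$x; ds <- d
  cross <- which(d[-1L] * d[-n] < 0)
  if (length(cross) > 0L) {
    xc <- g$x[cross] + (g$x[cross + 1L] - g$x[cross]) *
      d[cross] / (d[cross] - d[cross + 1L])
    xs <- c(g$x, xc)
    ds <- c(d, rep(0, length(xc)))
    ord <- order(xs)
    xs <- xs[ord]; ds <- ds[ord]
  }
  trapz_sum(xs, pmax(ds, 0))
}

#' Integrated AIS intensity
#'
#' Trapezoid integral of the normalized profile over the AIS interval --
#' the "normalized, integrated mitochondrial intensity within the AIS
#' region". For a profile bounded by 1, the result is at most the
#' interval length.
#'
#' @inheritParams chord_dropout_area
#' @return Integral in um.
#' @export
integrated_ais_intensity <- function(profile, interval) {
  check_interval(profile, interval)
  g <- interval_grid(profile, interval)
  trapz_sum(g$x, g$y)
}

trapz_sum <- function(x, y) {
  n <- length(x)
  sum((x[-1L] - x[-n]) * (y[-1L] + y[-n])) / 2
}
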