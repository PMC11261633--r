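# Binned, max-normalized intensity profiles across the AIS.

#' Maximum-intensity projection of one channel
#'
#' Each output pixel is the maximum over z of the non-missing values at
#' that position; a pixel is missing only if it is missing in every slice.
#'
#' @param stack an [image_stack()]
#' @param channel channel to project (0-based index or name)
#' @return A `[y, x]` matrix with attribute `pixel_size` (`(y, x)` um).
#' @export
max_project <- function(stack, channel = 0L) {
  ch <- stack_channel(stack, channel)
  d <- dim(ch)
  if (d[3L] < 1L) stop("stack has no slices")
  proj <- ch[, , 1L]
  if (d[3L] > 1L)
    for (zi in 2L:d[3L]) {
      slice <- ch[, , zi]
      proj <- ifelse(is.na(proj), slice,
                     ifelse(is.na(slice), proj, pmax(proj, slice)))
    }
  attr(proj, "pixel_size") <- stack$voxel_size[c("y", "x")]
  proj
}

#' Extract a binned intensity profile along a rectangular ROI
#'
#' The projected image is resampled into the ROI's rotated frame by
#' bilinear interpolation (4x oversampling along both axes), averaged
#' across the ROI width, and then averaged into length bins. The bin count
#' is `round(length / bin_width)`, so the effective bin width is
#' `length / n_bins` (~0.41 um for the 37 um / 90-bin larval ROI).
#' Positions are bin centres in signed um spanning `[-L/2, +L/2]` with 0
#' at the ROI centre; by the orientation convention, negative positions
#' are distal (towards the axonal lobes) and positive positions proximal
#' (towards the calyx). Missing pixels are excluded from averages; a bin
#' with no valid samples is missing.
#'
#' @param image2d projected image from [max_project()] (or any matrix with
#'   a `pixel_size` attribute)
#' @param roi a [rect_roi()]
#' @param bin_width requested bin width in um (> 0)
#' @param oversample sampling factor relative to the pixel grid
#' @param source_id identifier carried into the profile
#' @return An object of class `intensity_profile`: a list with `positions`,
#'   `values`, `bin_width`, `normalized`, `source_id`.
#' @export
extract_profile <- function(image2d, roi, bin_width, oversample = 4L,
                            source_id = NA_character_) {
  stopifnot(inherits(roi, "rect_roi"))
  if (!is.finite(bin_width) || bin_width <= 0) stop("bin_width must be > 0")
  px <- attr(image2d, "pixel_size")
  if (is.null(px)) stop("image2d must carry a pixel_size attribute (y, x)")
  ny <- nrow(image2d); nx <- ncol(image2d)

  n_bins <- max(1L, round(roi$length / bin_width))
  eff_bw <- roi$length / n_bins
  step <- min(px) / oversample
  m_len <- max(1L, ceiling(eff_bw / step))          # samples per bin
  n_wid <- max(1L, ceiling(roi$width / step))       # samples across width

  # sample offsets, symmetric within each bin and across the width
  s_in_bin <- (seq_len(m_len) - 0.5) / m_len * eff_bw - eff_bw / 2
  centers <- -roi$length / 2 + (seq_len(n_bins) - 0.5) * eff_bw
  s <- rep(centers, each = m_len) + rep(s_in_bin, times = n_bins)
  t_off <- (seq_len(n_wid) - 0.5) / n_wid * roi$width - roi$width / 2

  a <- roi$angle * pi / 180
  u <- c(cos(a), sin(a)); v <- c(-sin(a), cos(a))
  X <- roi$center["x"] + outer(s, t_off, function(si, ti) si * u[1L] + ti * v[1L])
  Y <- roi$center["y"] + outer(s, t_off, function(si, ti) si * u[2L] + ti * v[2L])

  # fractional pixel coordinates (pixel centre iy at y = (iy - 0.5) * dy)
  fx <- X / px["x"] + 0.5
  fy <- Y / px["y"] + 0.5
  if (any(fx < 1 | fx > nx | fy < 1 | fy > ny))
    stop("ROI extends outside the image")
  vals <- bilinear_sample(image2d, fy, fx)

  vals <- matrix(vals, nrow = length(s))
  bin_of <- rep(seq_len(n_bins), each = m_len)
  bin_vals <- vapply(seq_len(n_bins), function(b) {
    vv <- vals[bin_of == b, ]
    vv <- vv[!is.na(vv)]
    if (length(vv) == 0L) NA_real_ else mean(vv)
  }, numeric(1L))

  structure(list(positions = centers, values = bin_vals,
                 bin_width = eff_bw, normalized = FALSE,
                 source_id = source_id),
            class = "intensity_profile")
}

# bilinear interpolation at fractional pixel coordinates; NA if any of the
# four neighbours is missing (so thresholded pixels propagate as missing)
bilinear_sample <- function(img, fy, fx) {
  ny <- nrow(img); nx <- ncol(img)
  y0 <- pmin(pmax(floor(fy), 1), ny - 1); x0 <- pmin(pmax(floor(fx), 1), nx - 1)
  wy <- fy - y0; wx <- fx - x0
  i00 <- cbind(as.vector(y0), as.vector(x0))
  v00 <- img[i00]; v01 <- img[cbind(i00[, 1L], i00[, 2L] + 1L)]
  v10 <- img[cbind(i00[, 1L] + 1L, i00[, 2L])]
  v11 <- img[cbind(i00[, 1L] + 1L, i00[, 2L] + 1L)]
  wy <- as.vector(wy); wx <- as.vector(wx)
  (1 - wy) * (1 - wx) * v00 + (1 - wy) * wx * v01 +
    wy * (1 - wx) * v10 + wy * wx * v11
}

#' Normalize a profile to its maximum
#'
#' Divides all bin values by the profile maximum (per image), so the
#' largest bin becomes 1.
#'
#' @param profile an `intensity_profile`
#' @return The normalized `intensity_profile`.
#' @export
normalize_profile <- function(profile) {
  stopifnot(inherits(profile, "intensity_profile"))
  m <- suppressWarnings(max(profile$values, na.rm = TRUE))
  if (!is.finite(m) || m <= 0)
    stop("cannot normalize: profile maximum is not positive")
  profile$values <- profile$values / m
  profile$normalized <- TRUE
  profile
}

#' Aggregate normalized profiles into a group mean with SEM
#'
#' All profiles must share the same position grid. Per bin, the mean and
#' standard error (sample SD / sqrt(n)) are computed over the non-missing
#' values; with a single profile the SEM is reported as 0 (with a
#' warning).
#'
#' @param profiles list of normalized `intensity_profile`s
#' @return A data frame with columns `position`, `mean`, `sem`, `n`.
#' @export
aggregate_group <- function(profiles) {
  if (length(profiles) < 1L) stop("no profiles to aggregate")
  pos <- profiles[[1L]]$positions
  for (p in profiles) {
    stopifnot(inherits(p, "intensity_profile"))
    if (length(p$positions) != length(pos) ||
        max(abs(p$positions - pos)) > 1e-9)
      stop("profiles have mismatched position grids")
  }
  if (length(profiles) == 1L)
    warning("single profile: SEM reported as 0")
  vals <- vapply(profiles, function(p) p$values,
                 numeric(length(pos)))
  vals <- matrix(vals, nrow = length(pos))
  agg <- t(apply(vals, 1L, function(row) {
    row <- row[!is.na(row)]
    n <- length(row)
    if (n == 0L) return(c(NA_real_, NA_real_, 0))
    sem <- if (n > 1L) stats::sd(row) / sqrt(n) else 0
    c(mean(row), sem, n)
  }))
  data.frame(position = pos, mean = agg[, 1L], sem = agg[, 2L],
             n = as.integer(agg[, 3L]))
}
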