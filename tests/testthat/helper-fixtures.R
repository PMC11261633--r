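# Shared in-code fixtures for the test suite. Everything is generated at
# test time; nothing binary is stored.

# tiny anatomy used where a full cohort-sized stack is unnecessary
tiny_geometry <- function(voxel_size = c(z = 1, y = 0.5, x = 0.5)) {
  compartment_geometry(
    field_of_view = c(z = 10, y = 16, x = 44),
    voxel_size = voxel_size,
    calyx_center = c(z = 5, y = 8, x = 35), calyx_radius = 4.5,
    peduncle_p0 = c(z = 5, y = 8, x = 7),
    peduncle_p1 = c(z = 5, y = 8, x = 31), peduncle_radius = 2,
    ais_interval = c(9, 17),
    lobe_p0 = c(z = 5, y = 8, x = 1.5),
    lobe_p1 = c(z = 5, y = 8, x = 7), lobe_radius = 3)
}

# a random multi-channel stack with optional missing values
random_stack <- function(ny = 6, nx = 8, nz = 3, nc = 1, seed = 1,
                         na_frac = 0, voxel_size = c(1, 0.5, 0.5)) {
  set.seed(seed)
  a <- array(runif(ny * nx * nz * nc, 1, 100), c(ny, nx, nz, nc))
  if (na_frac > 0) {
    idx <- sample(length(a), round(na_frac * length(a)))
    a[idx] <- NA_real_
  }
  image_stack(a, voxel_size)
}

# a 2D image with pixel_size attribute, for profile tests
flat_image <- function(ny, nx, value = 1, pixel_size = c(y = 0.25, x = 0.25)) {
  img <- matrix(value, ny, nx)
  attr(img, "pixel_size") <- pixel_size
  img
}

# build an intensity_profile directly from positions/values
manual_profile <- function(positions, values, normalized = FALSE) {
  structure(list(positions = positions, values = values,
                 bin_width = positions[2] - positions[1],
                 normalized = normalized, source_id = "manual"),
            class = "intensity_profile")
}

# fine-grid numeric integration oracle (independent of the implementation):
# linear interpolation of the profile onto n points, pracma::trapz
oracle_dropout <- function(profile, interval, n = 1000, positive = TRUE) {
  ok <- !is.na(profile$values)
  xs <- seq(interval$distal_edge, interval$proximal_edge, length.out = n)
  ys <- approx(profile$positions[ok], profile$values[ok], xout = xs)$y
  ya <- ys[1]; yb <- ys[n]
  chord <- ya + (yb - ya) * (xs - xs[1]) / (xs[n] - xs[1])
  f <- if (positive) pmax(chord - ys, 0) else ys
  pracma::trapz(xs, f)
}
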