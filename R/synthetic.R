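# Synthetic two-channel confocal stacks of an MB-like neuron with known
# ground truth: compartment labels, puncta positions, and AIS interval.

#' Voxelise the compartment geometry into a label volume
#'
#' Every voxel (by its centre) receives exactly one label from
#' `background, calyx, ais, axon_proximal, axon_lobe`. Where idealized
#' shapes overlap, the calyx takes precedence over the peduncle, and the
#' peduncle over the lobe; the AIS is the half-open arc interval
#' `[distal, proximal)` of the peduncle.
#'
#' @param geometry a [compartment_geometry()]
#' @return An integer 3D array `[y, x, z]` of label codes (see
#'   `COMPARTMENT_LABELS`), with attributes `voxel_size`, `geometry`, and
#'   `labels`.
#' @export
build_label_volume <- function(geometry) {
  stopifnot(inherits(geometry, "compartment_geometry"))
  vs <- geometry$voxel_size
  fov <- geometry$field_of_view
  nz <- max(1L, round(fov["z"] / vs["z"]))
  ny <- max(1L, round(fov["y"] / vs["y"]))
  nx <- max(1L, round(fov["x"] / vs["x"]))
  cz <- (seq_len(nz) - 0.5) * vs["z"]
  cy <- (seq_len(ny) - 0.5) * vs["y"]
  cx <- (seq_len(nx) - 0.5) * vs["x"]
  # voxel order [y, x, z]
  Y <- rep(cy, times = nx * nz)
  X <- rep(rep(cx, each = ny), times = nz)
  Z <- rep(cz, each = ny * nx)

  lab <- integer(ny * nx * nz)

  in_cylinder <- function(p0, p1, r) {
    L <- sqrt(sum((p1 - p0)^2))
    if (L == 0 || r <= 0) return(list(inside = logical(length(Z)), t = NULL))
    u <- (p1 - p0) / L
    dz <- Z - p0["z"]; dy <- Y - p0["y"]; dx <- X - p0["x"]
    t <- dz * u["z"] + dy * u["y"] + dx * u["x"]
    d2 <- dz * dz + dy * dy + dx * dx - t * t
    list(inside = t >= 0 & t <= L & d2 <= r * r, t = t)
  }

  lob <- in_cylinder(geometry$lobe_p0, geometry$lobe_p1, geometry$lobe_radius)
  lab[lob$inside] <- COMPARTMENT_LABELS[["axon_lobe"]]

  ped <- in_cylinder(geometry$peduncle_p0, geometry$peduncle_p1,
                     geometry$peduncle_radius)
  if (any(ped$inside)) {
    ai <- geometry$ais_interval
    is_ais <- ped$inside & ped$t >= ai[1L] & ped$t < ai[2L]
    lab[ped$inside] <- COMPARTMENT_LABELS[["axon_proximal"]]
    lab[is_ais] <- COMPARTMENT_LABELS[["ais"]]
  }

  if (geometry$calyx_radius > 0) {
    cc <- geometry$calyx_center
    r2 <- (Z - cc["z"])^2 + (Y - cc["y"])^2 + (X - cc["x"])^2
    lab[r2 <= geometry$calyx_radius^2] <- COMPARTMENT_LABELS[["calyx"]]
  }

  lab <- array(lab, c(ny, nx, nz))
  attr(lab, "voxel_size") <- vs
  attr(lab, "geometry") <- geometry
  attr(lab, "labels") <- COMPARTMENT_LABELS
  lab
}

#' Sample mitochondrial puncta inside a label volume
#'
#' Per-compartment counts are Poisson with mean `density x volume`
#' (volume = voxel count x voxel volume). Inside the AIS, puncta are first
#' drawn at the baseline axonal density and then thinned with survival
#' probability `1 - d * w(s)`, realizing an inhomogeneous Poisson process
#' with effective density `density * (1 - d * w(s))` along the normalized
#' AIS position `s`. Positions are uniform within the voxelised
#' compartment; a punctum's compartment is the label of the voxel it falls
#' in.
#'
#' @param label_volume result of [build_label_volume()]
#' @param model a [puncta_model()]
#' @param seed integer seed; sampling is deterministic given the seed
#' @return A data frame with columns `z, y, x` (um), `amplitude`,
#'   `compartment`, carrying the `puncta_model` as attribute `model`.
#' @export
sample_puncta <- function(label_volume, model, seed) {
  stopifnot(inherits(model, "puncta_model"))
  geometry <- attr(label_volume, "geometry")
  vs <- attr(label_volume, "voxel_size")
  voxvol <- prod(vs)
  dens <- model$density_per_compartment

  with_seed(seed, {
    out <- list()
    draw_in <- function(code, n) {
      idx <- which(label_volume == code)
      if (length(idx) == 0L || n == 0L)
        return(matrix(numeric(0), 0L, 3L, dimnames = list(NULL, c("z", "y", "x"))))
      pick <- idx[sample.int(length(idx), n, replace = TRUE)]
      d <- dim(label_volume)
      iy <- (pick - 1L) %% d[1L] + 1L
      ix <- ((pick - 1L) %/% d[1L]) %% d[2L] + 1L
      iz <- (pick - 1L) %/% (d[1L] * d[2L]) + 1L
      cbind(z = (iz - 1L + stats::runif(n)) * vs["z"],
            y = (iy - 1L + stats::runif(n)) * vs["y"],
            x = (ix - 1L + stats::runif(n)) * vs["x"])
    }
    for (comp in c("calyx", "axon_proximal", "axon_lobe")) {
      code <- COMPARTMENT_LABELS[[comp]]
      vol <- sum(label_volume == code) * voxvol
      n <- stats::rpois(1L, dens[[comp]] * vol)
      pos <- draw_in(code, n)
      out[[comp]] <- data.frame(pos, amplitude = draw_amplitude(model, nrow(pos)),
                                compartment = rep(comp, nrow(pos)))
    }
    # AIS: baseline axonal density, thinned by the exclusion profile
    code <- COMPARTMENT_LABELS[["ais"]]
    vol <- sum(label_volume == code) * voxvol
    n <- stats::rpois(1L, dens[["axon_proximal"]] * vol)
    pos <- draw_in(code, n)
    if (nrow(pos) > 0L) {
      s <- ais_normalized_position(pos, geometry)
      w <- switch(model$ais_exclusion_weight,
                  "uniform" = rep(1, nrow(pos)),
                  "proximal-weighted" = s)
      keep <- stats::runif(nrow(pos)) >= model$ais_exclusion_depth * w
      pos <- pos[keep, , drop = FALSE]
    }
    out[["ais"]] <- data.frame(pos, amplitude = draw_amplitude(model, nrow(pos)),
                               compartment = rep("ais", nrow(pos)))
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    attr(res, "model") <- model
    res
  })
}

draw_amplitude <- function(model, n) {
  if (n == 0L) return(numeric(0))
  a <- stats::rnorm(n, model$punctum_amplitude["mean"],
                    model$punctum_amplitude["sd"])
  # truncate at zero by redrawing (amplitudes are intensities, not signed)
  bad <- which(a <= 0)
  while (length(bad) > 0L) {
    a[bad] <- stats::rnorm(length(bad), model$punctum_amplitude["mean"],
                           model$punctum_amplitude["sd"])
    bad <- bad[a[bad] <= 0]
  }
  a
}

# normalized arc position within the AIS: 0 at the distal edge, 1 proximal
ais_normalized_position <- function(pos, geometry) {
  p0 <- geometry$peduncle_p0; p1 <- geometry$peduncle_p1
  L <- sqrt(sum((p1 - p0)^2))
  u <- (p1 - p0) / L
  t <- (pos[, "z"] - p0["z"]) * u["z"] + (pos[, "y"] - p0["y"]) * u["y"] +
    (pos[, "x"] - p0["x"]) * u["x"]
  ai <- geometry$ais_interval
  pmin(1, pmax(0, (t - ai[1L]) / (ai[2L] - ai[1L])))
}

#' Render a two-channel stack from labels and puncta
#'
#' Channel 0 (mitochondrial marker) is the constant background plus every
#' punctum rendered as an anisotropic Gaussian whose per-axis sigma
#' combines the punctum size with the PSF
#' (`sigma_eff^2 = punctum_sigma^2 + psf_sigma^2`), evaluated in closed
#' form at voxel centres. Channel 1 (structural/AIS marker) fills all
#' neuronal labels at `marker_amplitude`, attenuated by
#' `ais_attenuation` inside the AIS -- emulating markers such as actin
#' whose relative depletion demarcates the AIS. Shot and read noise are
#' then applied to both channels.
#'
#' @param label_volume result of [build_label_volume()]
#' @param puncta result of [sample_puncta()]
#' @param acquisition an [acquisition_model()]
#' @param marker_amplitude marker intensity inside the neuron
#' @param ais_attenuation multiplicative marker attenuation inside the AIS
#'   (default 0.3, a clearly detectable trough)
#' @param seed integer seed for the noise draw
#' @return A list with elements `stack` (an [image_stack()], channels
#'   `mito`, `marker`) and `ground_truth` (label volume, puncta, the true
#'   AIS interval in signed profile coordinates, and the true calyx:lobe
#'   density ratio).
#' @export
render_stack <- function(label_volume, puncta, acquisition,
                         marker_amplitude = 100, ais_attenuation = 0.3,
                         seed = 1L) {
  stopifnot(inherits(acquisition, "acquisition_model"))
  geometry <- attr(label_volume, "geometry")
  vs <- attr(label_volume, "voxel_size")
  d <- dim(label_volume)
  model <- attr(puncta, "model")
  psig <- if (!is.null(model)) model$punctum_sigma else 0.4
  sig <- sqrt(psig^2 + acquisition$psf_sigma^2)  # (z, y, x)

  mito <- array(acquisition$background_level, d)
  if (nrow(puncta) > 0L)
    mito <- mito + render_puncta_field(puncta, d, vs, sig)

  lab <- label_volume
  marker <- array(acquisition$background_level, d)
  neuron <- lab != COMPARTMENT_LABELS[["background"]]
  marker[neuron] <- marker[neuron] + marker_amplitude
  in_ais <- lab == COMPARTMENT_LABELS[["ais"]]
  marker[in_ais] <- acquisition$background_level +
    marker_amplitude * ais_attenuation

  vox <- array(NA_real_, c(d, 2L))
  with_seed(seed, {
    vox[, , , 1L] <- apply_noise(mito, acquisition)
    vox[, , , 2L] <- apply_noise(marker, acquisition)
  })
  stack <- image_stack(vox, vs, c("mito", "marker"))

  ai <- geometry$ais_interval
  gt <- list(
    label_volume = label_volume,
    puncta = puncta,
    # signed profile coordinates for a profile ROI centred on the AIS
    # midpoint (distal negative)
    true_ais_interval = c(distal = -(ai[2L] - ai[1L]) / 2,
                          proximal = (ai[2L] - ai[1L]) / 2),
    ais_length = ai[2L] - ai[1L],
    ais_center_world = ais_center_world(geometry),
    true_density_ratio =
      unname(if (!is.null(model))
        model$density_per_compartment["calyx"] /
          model$density_per_compartment["axon_lobe"] else NA_real_))
  list(stack = stack, ground_truth = gt)
}

# (x, y) world position of the AIS arc midpoint, plus the unit axis (x, y)
ais_center_world <- function(geometry) {
  p0 <- geometry$peduncle_p0; p1 <- geometry$peduncle_p1
  L <- sqrt(sum((p1 - p0)^2))
  u <- (p1 - p0) / L
  mid <- p0 + u * mean(geometry$ais_interval)
  c(x = unname(mid["x"]), y = unname(mid["y"]),
    ux = unname(u["x"]), uy = unname(u["y"]))
}

# closed-form accumulation of Gaussian puncta onto the voxel grid,
# windowed at 4 sigma per axis
render_puncta_field <- function(puncta, d, vs, sig) {
  out <- array(0, d)
  cz <- (seq_len(d[3L]) - 0.5) * vs["z"]
  cy <- (seq_len(d[1L]) - 0.5) * vs["y"]
  cx <- (seq_len(d[2L]) - 0.5) * vs["x"]
  wz <- 4 * sig["z"]; wy <- 4 * sig["y"]; wx <- 4 * sig["x"]
  for (i in seq_len(nrow(puncta))) {
    pz <- puncta$z[i]; py <- puncta$y[i]; px <- puncta$x[i]
    iz <- which(cz >= pz - wz & cz <= pz + wz)
    iy <- which(cy >= py - wy & cy <= py + wy)
    ix <- which(cx >= px - wx & cx <= px + wx)
    if (!length(iz) || !length(iy) || !length(ix)) next
    gz <- exp(-0.5 * ((cz[iz] - pz) / sig["z"])^2)
    gy <- exp(-0.5 * ((cy[iy] - py) / sig["y"])^2)
    gx <- exp(-0.5 * ((cx[ix] - px) / sig["x"])^2)
    blk <- puncta$amplitude[i] * (gy %o% gx %o% gz)
    out[iy, ix, iz] <- out[iy, ix, iz] + blk
  }
  out
}

apply_noise <- function(clean, acquisition) {
  v <- clean
  if (acquisition$poisson_scale > 0) {
    lam <- pmax(0, clean) * acquisition$poisson_scale
    v <- stats::rpois(length(lam), lam) / acquisition$poisson_scale
  }
  if (acquisition$read_noise_sd > 0)
    v <- v + stats::rnorm(length(v), 0, acquisition$read_noise_sd)
  if (!is.null(acquisition$bit_depth_clip))
    v <- pmin(v, acquisition$bit_depth_clip)
  array(v, dim(clean))
}

# run expr with a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
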