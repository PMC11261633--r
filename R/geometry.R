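#' Compartment geometry of a synthetic mushroom-body-like neuron
#'
#' Describes the idealized anatomy that the generator voxelises: a spherical
#' calyx (somatodendritic compartment, by convention on the right / high-x
#' side), a cylindrical peduncle (proximal axon bundle) containing the AIS
#' interval, and a cylindrical axonal lobe on the distal (low-x) side. All
#' coordinates are physical micrometres; positions are `(z, y, x)` vectors.
#'
#' @param field_of_view `(z, y, x)` extent of the simulated volume, um
#' @param voxel_size `(z, y, x)` voxel size, um. The default mimics confocal
#'   acquisition with a 1 um z-step and finer xy sampling.
#' @param calyx_center `(z, y, x)` centre of the calyx sphere, um
#' @param calyx_radius calyx radius, um (0 for no calyx)
#' @param peduncle_p0,peduncle_p1 endpoints of the peduncle axis, um;
#'   `peduncle_p0` is the distal end, `peduncle_p1` the proximal (calyx) end
#' @param peduncle_radius peduncle radius, um
#' @param ais_interval `(distal, proximal)` arc positions of the AIS along
#'   the peduncle axis, in um from `peduncle_p0`; must lie strictly inside
#'   the axis segment
#' @param lobe_p0,lobe_p1 endpoints of the axonal-lobe axis, um
#' @param lobe_radius lobe radius, um
#' @return An object of class `compartment_geometry`.
#' @export
compartment_geometry <- function(
    field_of_view = c(z = 18, y = 32, x = 80),
    voxel_size = c(z = 1, y = 0.25, x = 0.25),
    calyx_center = c(z = 9, y = 16, x = 62),
    calyx_radius = 8,
    peduncle_p0 = c(z = 9, y = 16, x = 12),
    peduncle_p1 = c(z = 9, y = 16, x = 54),
    peduncle_radius = 3,
    ais_interval = c(21, 35),
    lobe_p0 = c(z = 9, y = 16, x = 2),
    lobe_p1 = c(z = 9, y = 16, x = 12),
    lobe_radius = 5) {
  g <- list(field_of_view = vec3(field_of_view, "field_of_view"),
            voxel_size = vec3(voxel_size, "voxel_size"),
            calyx_center = vec3(calyx_center, "calyx_center"),
            calyx_radius = num1(calyx_radius, "calyx_radius"),
            peduncle_p0 = vec3(peduncle_p0, "peduncle_p0"),
            peduncle_p1 = vec3(peduncle_p1, "peduncle_p1"),
            peduncle_radius = num1(peduncle_radius, "peduncle_radius"),
            ais_interval = as.numeric(ais_interval),
            lobe_p0 = vec3(lobe_p0, "lobe_p0"),
            lobe_p1 = vec3(lobe_p1, "lobe_p1"),
            lobe_radius = num1(lobe_radius, "lobe_radius"))
  if (any(g$voxel_size <= 0)) stop("voxel_size components must be > 0")
  if (any(g$field_of_view <= 0)) stop("field_of_view components must be > 0")
  if (g$calyx_radius < 0 || g$peduncle_radius < 0 || g$lobe_radius < 0)
    stop("radii must be >= 0")
  ped_len <- sqrt(sum((g$peduncle_p1 - g$peduncle_p0)^2))
  ai <- g$ais_interval
  if (length(ai) != 2L || ai[1L] >= ai[2L])
    stop("ais_interval must be (distal, proximal) with distal < proximal")
  if (ai[1L] <= 0 || ai[2L] >= ped_len)
    stop("configuration error: ais_interval must lie strictly within the ",
         "peduncle axis (length ", format(ped_len), " um)")
  check_inside <- function(lo, hi, what) {
    if (any(lo < 0) || any(hi > g$field_of_view))
      stop("configuration error: ", what, " exceeds field_of_view")
  }
  if (g$calyx_radius > 0)
    check_inside(g$calyx_center - g$calyx_radius,
                 g$calyx_center + g$calyx_radius, "calyx")
  cyl_extent <- function(p0, p1, r) {
    # exact bounding box of a finite cylinder: radial reach along axis i
    # is r * sqrt(1 - u_i^2)
    u <- (p1 - p0) / sqrt(sum((p1 - p0)^2))
    r * sqrt(pmax(0, 1 - u^2))
  }
  if (g$peduncle_radius > 0 && ped_len > 0) {
    e <- cyl_extent(g$peduncle_p0, g$peduncle_p1, g$peduncle_radius)
    check_inside(pmin(g$peduncle_p0, g$peduncle_p1) - e,
                 pmax(g$peduncle_p0, g$peduncle_p1) + e, "peduncle")
  }
  if (g$lobe_radius > 0 && any(g$lobe_p0 != g$lobe_p1)) {
    e <- cyl_extent(g$lobe_p0, g$lobe_p1, g$lobe_radius)
    check_inside(pmin(g$lobe_p0, g$lobe_p1) - e,
                 pmax(g$lobe_p0, g$lobe_p1) + e, "lobe")
  }
  structure(g, class = "compartment_geometry")
}

vec3 <- function(v, what) {
  v <- as.numeric(v)
  if (length(v) != 3L || any(!is.finite(v)))
    stop(what, " must be three finite numbers (z, y, x)")
  names(v) <- c("z", "y", "x")
  v
}

num1 <- function(v, what) {
  v <- as.numeric(v)
  if (length(v) != 1L || !is.finite(v)) stop(what, " must be a finite number")
  v
}

#' Model of punctate mitochondrial signal
#'
#' Mitochondria are modelled as Gaussian puncta placed by a Poisson point
#' process with a per-compartment density. Inside the AIS the axonal
#' density is thinned to `density * (1 - d * w(s))`, where `d` is the
#' exclusion depth and `w(s)` a weight over the normalized AIS position
#' `s` (0 at the distal edge, 1 at the proximal edge): `"uniform"` (w = 1,
#' the larval pattern of depletion throughout the AIS) or
#' `"proximal-weighted"` (w = s, strongest depletion at the proximal edge,
#' the adult pattern).
#'
#' @param density_per_compartment named numeric vector of puncta densities
#'   per um^3 for `calyx`, `axon_proximal` (peduncle outside the AIS; also
#'   the baseline AIS density before thinning) and `axon_lobe`. The default
#'   1.5/um^3 reflects that the peduncle carries a whole bundle of axons,
#'   so the summed mitochondrial signal is dense and quasi-continuous.
#' @param ais_exclusion_depth `d` in `[0, 1]`; 0 = no exclusion (KO-like),
#'   values near 1 = near-complete exclusion (WT-like).
#' @param ais_exclusion_weight `"uniform"` or `"proximal-weighted"`
#' @param punctum_amplitude `(mean, sd)` of the punctum peak intensity
#'   (normal, truncated at 0)
#' @param punctum_sigma Gaussian radius of one punctum, um (> 0)
#' @return An object of class `puncta_model`.
#' @export
puncta_model <- function(
    density_per_compartment = c(calyx = 1.5, axon_proximal = 1.5,
                                axon_lobe = 1.5),
    ais_exclusion_depth = 0.8,
    ais_exclusion_weight = c("uniform", "proximal-weighted"),
    punctum_amplitude = c(mean = 10, sd = 2),
    punctum_sigma = 0.4) {
  dens <- density_per_compartment
  need <- c("calyx", "axon_proximal", "axon_lobe")
  if (!all(need %in% names(dens)))
    stop("density_per_compartment must name ", paste(need, collapse = ", "))
  dens <- dens[need]
  if (any(!is.finite(dens)) || any(dens < 0))
    stop("validation error: densities must be finite and >= 0")
  d <- num1(ais_exclusion_depth, "ais_exclusion_depth")
  if (d < 0 || d > 1) stop("ais_exclusion_depth must be in [0, 1]")
  amp <- as.numeric(punctum_amplitude)
  if (length(amp) != 2L || amp[1L] <= 0 || amp[2L] < 0)
    stop("punctum_amplitude must be (mean > 0, sd >= 0)")
  sig <- num1(punctum_sigma, "punctum_sigma")
  if (sig <= 0) stop("punctum_sigma must be > 0")
  structure(list(density_per_compartment = dens,
                 ais_exclusion_depth = d,
                 ais_exclusion_weight = match.arg(ais_exclusion_weight),
                 punctum_amplitude = c(mean = amp[1L], sd = amp[2L]),
                 punctum_sigma = sig),
            class = "puncta_model")
}

#' Confocal acquisition model
#'
#' Emulates the imaging chain: anisotropic Gaussian PSF blur (applied to
#' the puncta channel in closed form), a constant background, shot noise
#' (Poisson with `poisson_scale` photons per intensity unit; 0 disables),
#' additive Gaussian read noise, and an optional clip at the detector
#' maximum.
#'
#' @param psf_sigma `(z, y, x)` PSF standard deviation, um. The z component
#'   dominates, as in a confocal stack with ~1 um z-steps.
#' @param background_level constant background intensity
#' @param poisson_scale photons per intensity unit (>= 0; 0 disables shot
#'   noise). Sample variance of a rendered voxel is ~ mean / poisson_scale.
#' @param read_noise_sd additive Gaussian noise SD (>= 0)
#' @param bit_depth_clip optional maximum intensity
#' @return An object of class `acquisition_model`.
#' @export
acquisition_model <- function(psf_sigma = c(z = 0.6, y = 0.25, x = 0.25),
                              background_level = 5,
                              poisson_scale = 20,
                              read_noise_sd = 1,
                              bit_depth_clip = NULL) {
  ps <- vec3(psf_sigma, "psf_sigma")
  if (any(ps <= 0)) stop("psf_sigma components must be > 0")
  if (background_level < 0 || poisson_scale < 0 || read_noise_sd < 0)
    stop("acquisition parameters must be nonnegative")
  if (!is.null(bit_depth_clip) && bit_depth_clip <= 0)
    stop("bit_depth_clip must be > 0 when given")
  structure(list(psf_sigma = ps, background_level = background_level,
                 poisson_scale = poisson_scale, read_noise_sd = read_noise_sd,
                 bit_depth_clip = bit_depth_clip),
            class = "acquisition_model")
}

# compartment label codes used throughout the generator
COMPARTMENT_LABELS <- c(background = 0L, calyx = 1L, ais = 2L,
                        axon_proximal = 3L, axon_lobe = 4L)
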