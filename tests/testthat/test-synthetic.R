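# Generator: label volume geometry, Poisson puncta statistics, closed-form
# rendering, and cohort determinism.

test_that("labels partition the volume and zero-radius geometry is empty", {
  lab <- build_label_volume(tiny_geometry())
  counts <- table(factor(lab, levels = 0:4))
  expect_identical(sum(counts), length(lab))
  expect_true(all(counts[c("1", "2", "3", "4")] > 0))

  empty <- compartment_geometry(
    field_of_view = c(z = 10, y = 16, x = 44),
    voxel_size = c(1, 0.5, 0.5),
    calyx_center = c(z = 5, y = 8, x = 35), calyx_radius = 0,
    peduncle_p0 = c(z = 5, y = 8, x = 7),
    peduncle_p1 = c(z = 5, y = 8, x = 31), peduncle_radius = 0,
    ais_interval = c(9, 17),
    lobe_p0 = c(z = 5, y = 8, x = 2),
    lobe_p1 = c(z = 5, y = 8, x = 7), lobe_radius = 0)
  expect_true(all(build_label_volume(empty) == 0L))
})

test_that("AIS voxel count matches the analytic cylinder volume within 5%", {
  # AIS arc: radius 2 um, length 10 um, isotropic 0.5 um voxels
  g <- compartment_geometry(
    field_of_view = c(z = 12, y = 12, x = 40),
    voxel_size = c(0.5, 0.5, 0.5),
    calyx_center = c(z = 6, y = 6, x = 35), calyx_radius = 3,
    peduncle_p0 = c(z = 6, y = 6, x = 4),
    peduncle_p1 = c(z = 6, y = 6, x = 32), peduncle_radius = 2,
    ais_interval = c(8, 18),
    lobe_p0 = c(z = 6, y = 6, x = 1),
    lobe_p1 = c(z = 6, y = 6, x = 4), lobe_radius = 2)
  lab <- build_label_volume(g)
  n_ais <- sum(lab == 2L)
  expected <- pi * 2^2 * 10 / 0.5^3
  expect_lt(abs(n_ais - expected) / expected, 0.05)
})

test_that("geometry validation rejects out-of-bounds and bad AIS intervals", {
  expect_error(compartment_geometry(calyx_center = c(z = 9, y = 16, x = 79)),
               "exceeds field_of_view")
  expect_error(compartment_geometry(ais_interval = c(0, 50)),
               "strictly within")
  expect_error(compartment_geometry(ais_interval = c(20, 10)),
               "distal < proximal")
  expect_error(compartment_geometry(voxel_size = c(1, 0, 0.5)), "> 0")
})

test_that("puncta counts are Poisson with mean density x volume", {
  lab <- build_label_volume(tiny_geometry())
  voxvol <- prod(attr(lab, "voxel_size"))

  # zero density -> empty
  pm0 <- puncta_model(density_per_compartment =
                        c(calyx = 0, axon_proximal = 0, axon_lobe = 0))
  expect_identical(nrow(sample_puncta(lab, pm0, seed = 1)), 0L)

  # Poisson moments for the calyx over 120 seeds
  pm <- puncta_model(density_per_compartment =
                       c(calyx = 0.5, axon_proximal = 0, axon_lobe = 0),
                     ais_exclusion_depth = 0)
  mu <- 0.5 * sum(lab == 1L) * voxvol
  counts <- vapply(seq_len(120L), function(s)
    nrow(sample_puncta(lab, pm, seed = s)), integer(1))
  expect_lt(abs(mean(counts) - mu), 3 * sqrt(mu / 120))
  expect_gt(var(counts) / mu, 0.6)
  expect_lt(var(counts) / mu, 1.5)
})

test_that("full exclusion removes all AIS puncta; expected count is monotone in d", {
  lab <- build_label_volume(tiny_geometry())
  count_ais <- function(d, seeds = 1:40) {
    vapply(seeds, function(s) {
      pm <- puncta_model(ais_exclusion_depth = d)
      sum(sample_puncta(lab, pm, seed = s)$compartment == "ais")
    }, integer(1))
  }
  expect_true(all(count_ais(1, 1:10) == 0L))
  means <- vapply(c(0, 0.3, 0.6, 0.9), function(d) mean(count_ais(d)),
                  numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("proximal-weighted exclusion depletes the proximal AIS more", {
  lab <- build_label_volume(tiny_geometry())
  geom <- attr(lab, "geometry")
  pm <- puncta_model(ais_exclusion_depth = 1,
                     ais_exclusion_weight = "proximal-weighted")
  s <- unlist(lapply(1:30, function(sd) {
    pts <- sample_puncta(lab, pm, seed = sd)
    pts <- pts[pts$compartment == "ais", ]
    aismito:::ais_normalized_position(
      cbind(z = pts$z, y = pts$y, x = pts$x), geom)
  }))
  # with w(s) = s the surviving density is proportional to 1 - s:
  # E[s] = 1/3; distal half keeps 3x the proximal half
  expect_lt(mean(s), 0.42)
  expect_gt(sum(s < 0.5) / sum(s >= 0.5), 1.5)
})

test_that("puncta lie in the compartment their label claims", {
  lab <- build_label_volume(tiny_geometry())
  vs <- attr(lab, "voxel_size")
  pts <- sample_puncta(lab, puncta_model(), seed = 5)
  codes <- c(calyx = 1L, ais = 2L, axon_proximal = 3L, axon_lobe = 4L)
  vox_label <- lab[cbind(ceiling(pts$y / vs["y"]),
                         ceiling(pts$x / vs["x"]),
                         ceiling(pts$z / vs["z"]))]
  expect_identical(unname(vox_label), unname(codes[pts$compartment]))
})

test_that("noise-free rendering gives background plus closed-form puncta", {
  lab <- build_label_volume(tiny_geometry())
  quiet <- acquisition_model(background_level = 7, poisson_scale = 0,
                             read_noise_sd = 0)

  # no puncta: every voxel of the mito channel equals the background
  none <- sample_puncta(lab, puncta_model(density_per_compartment = c(
    calyx = 0, axon_proximal = 0, axon_lobe = 0)), seed = 1)
  r0 <- render_stack(lab, none, quiet, seed = 1)
  expect_true(all(stack_channel(r0$stack, "mito") == 7))

  # marker channel: filled at amplitude, attenuated in the AIS
  marker <- stack_channel(r0$stack, "marker")
  expect_true(all(marker[lab == 3L] == 107))
  expect_true(all(marker[lab == 2L] == 7 + 100 * 0.3))
  expect_true(all(marker[lab == 0L] == 7))

  # single punctum: direct evaluation of the blurred kernel at voxel
  # centres is the oracle
  pm <- puncta_model(punctum_sigma = 0.5)
  p1 <- data.frame(z = 5.2, y = 8.1, x = 20.3, amplitude = 11,
                   compartment = "ais")
  attr(p1, "model") <- pm
  r1 <- render_stack(lab, p1, quiet, seed = 1)
  got <- stack_channel(r1$stack, "mito")
  vs <- attr(lab, "voxel_size")
  sig <- sqrt(0.5^2 + quiet$psf_sigma^2)
  d <- dim(lab)
  oracle <- array(7, d)
  for (iy in seq_len(d[1])) for (ix in seq_len(d[2])) for (iz in seq_len(d[3])) {
    dz <- (iz - 0.5) * vs["z"] - 5.2
    dy <- (iy - 0.5) * vs["y"] - 8.1
    dx <- (ix - 0.5) * vs["x"] - 20.3
    g <- exp(-0.5 * ((dz / sig["z"])^2 + (dy / sig["y"])^2 +
                       (dx / sig["x"])^2))
    if (abs(dz) <= 4 * sig["z"] && abs(dy) <= 4 * sig["y"] &&
        abs(dx) <= 4 * sig["x"])
      oracle[iy, ix, iz] <- oracle[iy, ix, iz] + 11 * g
  }
  expect_lt(max(abs(got - oracle)), 1e-6)
})

test_that("shot-noise variance scales as mean over poisson_scale", {
  lab <- build_label_volume(compartment_geometry(
    field_of_view = c(z = 3, y = 4, x = 8), voxel_size = c(1, 1, 1),
    calyx_center = c(z = 1.5, y = 2, x = 6), calyx_radius = 1,
    peduncle_p0 = c(z = 1.5, y = 2, x = 2),
    peduncle_p1 = c(z = 1.5, y = 2, x = 5), peduncle_radius = 0.6,
    ais_interval = c(1, 2),
    lobe_p0 = c(z = 1.5, y = 2, x = 0.5),
    lobe_p1 = c(z = 1.5, y = 2, x = 2), lobe_radius = 0))
  acq <- acquisition_model(background_level = 50, poisson_scale = 4,
                           read_noise_sd = 0)
  none <- sample_puncta(lab, puncta_model(density_per_compartment = c(
    calyx = 0, axon_proximal = 0, axon_lobe = 0)), seed = 1)
  sims <- vapply(seq_len(200L), function(s)
    stack_channel(render_stack(lab, none, acq, seed = s)$stack, "mito")[1, 1, 1],
    numeric(1))
  expect_lt(abs(mean(sims) - 50) / 50, 0.05)
  expect_lt(abs(var(sims) - 50 / 4) / (50 / 4), 0.35)
})

test_that("rendering and cohorts are deterministic for a fixed seed", {
  lab <- build_label_volume(tiny_geometry())
  pm <- puncta_model()
  p1 <- sample_puncta(lab, pm, seed = 9)
  p2 <- sample_puncta(lab, pm, seed = 9)
  expect_identical(p1, p2)
  r1 <- render_stack(lab, p1, acquisition_model(), seed = 10)
  r2 <- render_stack(lab, p1, acquisition_model(), seed = 10)
  expect_identical(r1$stack$voxels, r2$stack$voxels)

  grp <- list(cohort_group("WT", "larva", pm))
  c1 <- generate_cohort(grp, 1, master_seed = 3, geometry = tiny_geometry())
  c2 <- generate_cohort(grp, 1, master_seed = 3, geometry = tiny_geometry())
  expect_length(c1, 1L)
  expect_identical(c1[[1]]$stack$voxels, c2[[1]]$stack$voxels)
  # different seeds give different noise
  c3 <- generate_cohort(grp, 1, master_seed = 4, geometry = tiny_geometry())
  expect_false(identical(c1[[1]]$stack$voxels, c3[[1]]$stack$voxels))
})

test_that("ground truth records the AIS interval and density ratio", {
  lab <- build_label_volume(tiny_geometry())
  pm <- puncta_model(density_per_compartment =
                       c(calyx = 1, axon_proximal = 1, axon_lobe = 0.5))
  pts <- sample_puncta(lab, pm, seed = 2)
  gt <- render_stack(lab, pts, acquisition_model(), seed = 2)$ground_truth
  expect_equal(unname(gt$true_ais_interval), c(-4, 4))  # 8 um AIS
  expect_equal(gt$true_density_ratio, 2)
  expect_equal(gt$ais_center_world[["x"]], 7 + 13)      # p0 + mid-arc
})
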