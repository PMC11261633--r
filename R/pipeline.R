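# Orchestration: simulate -> quantify -> profile -> dropout -> stats, with
# a manifest recording every parameter, seed, and output hash.

#' Default compartment ROIs for the synthetic geometry
#'
#' The calyx ROI is a polygon approximating the calyx circle in the xy
#' plane; the lobe ROI is a rectangle around the axonal-lobe cylinder.
#' Both are applied as prisms across z; sub-threshold (background) voxels
#' inside them are removed by the masking step.
#'
#' @param geometry a [compartment_geometry()]
#' @return A list with elements `calyx` and `lobe` ([poly_roi()]s).
#' @export
default_rois <- function(geometry) {
  cc <- geometry$calyx_center
  r <- geometry$calyx_radius
  th <- seq(0, 2 * pi, length.out = 25L)[-25L]
  calyx <- poly_roi(cbind(cc["x"] + r * cos(th), cc["y"] + r * sin(th)))
  p0 <- geometry$lobe_p0; p1 <- geometry$lobe_p1; lr <- geometry$lobe_radius
  lobe <- poly_roi(rbind(c(p0["x"], p0["y"] - lr), c(p1["x"], p0["y"] - lr),
                         c(p1["x"], p0["y"] + lr), c(p0["x"], p0["y"] + lr)))
  list(calyx = calyx, lobe = lobe)
}

# profile ROI centred on the AIS midpoint, long axis along the peduncle,
# positive direction towards the calyx (so distal positions are negative)
profile_roi_for <- function(ground_truth, length, width) {
  ac <- ground_truth$ais_center_world
  rect_roi(center = c(ac[["x"]], ac[["y"]]), length = length, width = width,
           angle = atan2(ac[["uy"]], ac[["ux"]]) * 180 / pi)
}

# per-stack analysis: ratio, normalized profile, interval, dropout stats
analyse_record <- function(rec, cfg, rois) {
  stack <- rec$stack
  gt <- rec$ground_truth
  ratio_row <- somatodendritic_axonal_ratio(
    stack, rois$calyx, rois$lobe, t = cfg$threshold,
    fly_id = rec$fly_id, hemisphere = rec$hemisphere,
    genotype = rec$genotype, age = rec$age)

  pstack <- if (isTRUE(cfg$threshold_profiles))
    threshold_to_missing(stack, cfg$threshold) else stack
  roi <- profile_roi_for(gt, roi_length_for_age(cfg, rec$age), cfg$roi_width)
  prof <- normalize_profile(extract_profile(
    max_project(pstack, "mito"), roi, cfg$bin_width,
    source_id = sprintf("%s_h%d", rec$fly_id, rec$hemisphere)))

  interval <- switch(
    cfg$boundary_method,
    "ground-truth" = ais_interval(gt$true_ais_interval[["distal"]],
                                  gt$true_ais_interval[["proximal"]]),
    "manual" = ais_interval(cfg$ais_interval[1L], cfg$ais_interval[2L]),
    "marker-trough" = tryCatch({
      mprof <- normalize_profile(extract_profile(
        max_project(pstack, "marker"), roi, cfg$bin_width))
      detect_ais_interval(mprof)
    }, error = function(e) {
      warning("marker-trough detection failed (", conditionMessage(e),
              "); falling back to manual interval")
      ais_interval(cfg$ais_interval[1L], cfg$ais_interval[2L])
    }))

  list(ratio = ratio_row, profile = prof, interval = interval,
       dropout = data.frame(
         fly_id = rec$fly_id, hemisphere = rec$hemisphere,
         genotype = rec$genotype, age = rec$age,
         distal_edge = interval$distal_edge,
         proximal_edge = interval$proximal_edge,
         interval_method = interval$method,
         dropout_area = chord_dropout_area(prof, interval),
         integrated_intensity = integrated_ais_intensity(prof, interval)))
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Simulates the cohort described by the config, then runs every stage --
#' threshold-masked compartment ratio, max projection, binned normalized
#' AIS profile, dropout-area and integrated-intensity statistics, replicate
#' collapsing, and group comparisons -- and writes per-fly CSVs, group
#' profile CSVs, a comparison CSV, and a run manifest with the config
#' snapshot, master seed, and MD5 hash of every output file. Reruns with
#' the same config and seed are byte-identical.
#'
#' @param config a config list (see [default_config()]); validated first
#' @param out_dir output directory, created if needed
#' @param geometry shared [compartment_geometry()] for the cohort
#' @param acquisition shared [acquisition_model()]
#' @return The manifest, invisibly (also written to `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir,
                         geometry = cohort_geometry(),
                         acquisition = acquisition_model()) {
  cfg <- utils::modifyList(default_config(), config)
  # modifyList's recursive merge would silently keep the default groups
  # when the caller supplies an empty list, so take the caller's verbatim
  if (!is.null(config$cohort) && "groups" %in% names(config$cohort))
    cfg$cohort$groups <- config$cohort$groups
  cfg <- validate_config(cfg)
  if (is.null(cfg$cohort)) stop("config has no cohort section")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  groups <- lapply(cfg$cohort$groups, config_group)
  cohort <- generate_cohort(groups, cfg$cohort$n_per_group,
                            master_seed = cfg$seed, geometry = geometry,
                            acquisition = acquisition,
                            hemispheres = cfg$cohort$hemispheres)
  rois <- default_rois(geometry)

  results <- lapply(cohort, analyse_record, cfg = cfg, rois = rois)

  ratio_tab <- do.call(rbind, lapply(results, `[[`, "ratio"))
  drop_tab <- do.call(rbind, lapply(results, `[[`, "dropout"))

  prof_tab <- do.call(rbind, lapply(seq_along(results), function(i) {
    p <- results[[i]]$profile
    data.frame(source_id = p$source_id,
               genotype = cohort[[i]]$genotype, age = cohort[[i]]$age,
               position_um = p$positions, value = p$values)
  }))

  # group-average profiles (per genotype x age)
  grp_keys <- unique(prof_tab[, c("genotype", "age")])
  grp_tab <- do.call(rbind, lapply(seq_len(nrow(grp_keys)), function(i) {
    sel <- vapply(seq_along(results), function(j)
      cohort[[j]]$genotype == grp_keys$genotype[i] &&
        cohort[[j]]$age == grp_keys$age[i], logical(1L))
    gp <- suppressWarnings(
      aggregate_group(lapply(results[sel], `[[`, "profile")))
    cbind(genotype = grp_keys$genotype[i], age = grp_keys$age[i], gp)
  }))

  meas <- rbind(
    data.frame(fly_id = ratio_tab$fly_id, hemisphere = ratio_tab$hemisphere,
               genotype = ratio_tab$genotype, age = ratio_tab$age,
               metric = "ratio", value = ratio_tab$ratio),
    data.frame(fly_id = drop_tab$fly_id, hemisphere = drop_tab$hemisphere,
               genotype = drop_tab$genotype, age = drop_tab$age,
               metric = "dropout_area", value = drop_tab$dropout_area),
    data.frame(fly_id = drop_tab$fly_id, hemisphere = drop_tab$hemisphere,
               genotype = drop_tab$genotype, age = drop_tab$age,
               metric = "integrated_intensity",
               value = drop_tab$integrated_intensity))
  per_fly <- collapse_replicates(meas)
  comparisons <- run_comparisons(per_fly, alpha = cfg$alpha)

  files <- c(measurements = "measurements.csv", per_fly = "per_fly.csv",
             ratios = "ratios.csv", dropout = "dropout.csv",
             profiles = "profiles.csv", group_profiles = "group_profiles.csv",
             comparisons = "comparisons.csv")
  write_table(meas, file.path(out_dir, files["measurements"]))
  write_table(per_fly, file.path(out_dir, files["per_fly"]))
  write_table(ratio_tab, file.path(out_dir, files["ratios"]))
  write_table(drop_tab, file.path(out_dir, files["dropout"]))
  write_table(prof_tab, file.path(out_dir, files["profiles"]))
  write_table(grp_tab, file.path(out_dir, files["group_profiles"]))
  write_table(comparisons, file.path(out_dir, files["comparisons"]))

  paths <- file.path(out_dir, files)
  manifest <- list(
    package_version = as.character(utils::packageVersion("aismito")),
    master_seed = cfg$seed,
    config = cfg,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = as.list(stats::setNames(unname(tools::md5sum(paths)),
                                      basename(paths))))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(out_dir, "manifest.json"))
  invisible(manifest)
}

#' Group comparisons over a per-fly measurement table
#'
#' For each metric: with two or more levels of both factors, a two-way
#' ANOVA with Sidak-adjusted within-age genotype contrasts; with a single
#' age level, the normality-gated two-group comparison per age.
#'
#' @param per_fly per-fly table from [collapse_replicates()]
#' @param alpha significance level
#' @return A data frame of comparison results.
#' @export
run_comparisons <- function(per_fly, alpha = 0.05) {
  out <- list()
  for (met in unique(per_fly$metric)) {
    sub <- per_fly[per_fly$metric == met, , drop = FALSE]
    n_gen <- length(unique(sub$genotype))
    n_age <- length(unique(sub$age))
    if (n_gen >= 2L && n_age >= 2L) {
      out[[met]] <- compare_two_way(sub, metric = met, alpha = alpha)
    } else if (n_gen == 2L) {
      gen <- sort(unique(sub$genotype))
      for (ag in unique(sub$age)) {
        s2 <- sub[sub$age == ag, , drop = FALSE]
        cmp <- tryCatch(
          compare_two_groups(s2$value[s2$genotype == gen[1L]],
                             s2$value[s2$genotype == gen[2L]],
                             alpha = alpha, metric = met),
          error = function(e) {
            warning("comparison skipped for ", met, " @ ", ag, ": ",
                    conditionMessage(e))
            NULL
          })
        if (is.null(cmp)) next
        cmp$contrast <- sprintf("%s vs %s @ age %s", gen[1L], gen[2L], ag)
        out[[paste(met, ag)]] <- cmp
      }
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(metric = character(0), contrast = character(0),
                      test_name = character(0), statistic = numeric(0),
                      p_value = numeric(0), adjusted_p = numeric(0),
                      alpha = numeric(0), normality_p_a = numeric(0),
                      normality_p_b = numeric(0),
                      decision_path = character(0))
  rownames(res) <- NULL
  res
}

#' Write a small deterministic fixture cohort
#'
#' Generates a reduced cohort (tiny field of view, 2 groups) and writes the
#' stacks as float TIFFs with ground-truth JSON sidecars plus the config
#' and compartment ROIs, for I/O and CLI tests. Byte-identical for a fixed
#' seed.
#'
#' @param out_dir output directory
#' @param seed master seed
#' @param n_per_group flies per group
#' @return Character vector of written file paths, invisibly.
#' @export
make_fixtures <- function(out_dir, seed = 1L, n_per_group = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  geom <- fixture_geometry()
  groups <- list(
    cohort_group("WT", "larva",
                 puncta_model(ais_exclusion_depth = 0.8)),
    cohort_group("KO", "larva",
                 puncta_model(ais_exclusion_depth = 0)))
  cohort <- generate_cohort(groups, n_per_group, master_seed = seed,
                            geometry = geom)
  paths <- character(0)
  for (rec in cohort) {
    base <- file.path(out_dir, sprintf("%s_h%d", rec$fly_id, rec$hemisphere))
    write_stack(rec$stack, paste0(base, ".tif"))
    write_ground_truth(rec$ground_truth, paste0(base, ".truth.json"))
    paths <- c(paths, paste0(base, ".tif"), paste0(base, ".truth.json"))
  }
  rois <- default_rois(geom)
  write_roi(rois$calyx, file.path(out_dir, "calyx.roi.json"))
  write_roi(rois$lobe, file.path(out_dir, "lobe.roi.json"))
  cfg <- default_config()
  cfg$seed <- seed
  cfg$roi_length <- list(larva = 17)   # the fixture field of view is small
  cfg$roi_width <- 4
  write_config(cfg, file.path(out_dir, "config.yaml"))
  paths <- c(paths, file.path(out_dir, c("calyx.roi.json", "lobe.roi.json",
                                         "config.yaml")))
  invisible(paths)
}

# miniature geometry for fixtures: same anatomy, ~10x fewer voxels
fixture_geometry <- function() {
  compartment_geometry(
    field_of_view = c(z = 10, y = 16, x = 44),
    voxel_size = c(z = 1, y = 0.5, x = 0.5),
    calyx_center = c(z = 5, y = 8, x = 35), calyx_radius = 4.5,
    peduncle_p0 = c(z = 5, y = 8, x = 7),
    peduncle_p1 = c(z = 5, y = 8, x = 31), peduncle_radius = 2,
    ais_interval = c(9, 17),
    lobe_p0 = c(z = 5, y = 8, x = 1.5),
    lobe_p1 = c(z = 5, y = 8, x = 7), lobe_radius = 3)
}

write_ground_truth <- function(gt, path) {
  obj <- list(true_ais_interval = unname(gt$true_ais_interval),
              ais_length = gt$ais_length,
              ais_center_world = as.list(gt$ais_center_world),
              true_density_ratio = gt$true_density_ratio,
              n_puncta = nrow(gt$puncta),
              puncta = gt$puncta)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                              dataframe = "columns"),
             path)
  invisible(path)
}
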