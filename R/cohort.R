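#' Default reduced-field-of-view geometry for cohort simulations
#'
#' The cohort work uses the same anatomy as [compartment_geometry()] but a
#' coarser (1.0, 0.5, 0.5) um voxel grid so that whole-cohort experiments
#' run in minutes; the 1 um z-step matches confocal acquisition, and the
#' xy size still oversamples the ~0.41 um profile bins.
#'
#' @param voxel_size `(z, y, x)` voxel size in um
#' @param ... passed to [compartment_geometry()]
#' @return A [compartment_geometry()].
#' @export
cohort_geometry <- function(voxel_size = c(z = 1, y = 0.5, x = 0.5), ...) {
  compartment_geometry(voxel_size = voxel_size, ...)
}

#' Define a cohort group (genotype-like condition x age-like level)
#'
#' @param genotype group label for the genotype-like factor (e.g. `"WT"`,
#'   `"KO"`)
#' @param age group label for the age-like factor (e.g. `"larva"`,
#'   `"adult10"`)
#' @param model the group's [puncta_model()]; WT-like groups have
#'   `ais_exclusion_depth > 0`, KO-like groups ~0
#' @return A list describing the group.
#' @export
cohort_group <- function(genotype, age = "larva", model = puncta_model()) {
  stopifnot(inherits(model, "puncta_model"))
  list(genotype = as.character(genotype), age = as.character(age),
       model = model)
}

# deterministic per-stack seed derivation: extending a cohort with more
# groups or flies never reshuffles existing stacks
stack_seed <- function(master_seed, group_index, fly_index, hemisphere = 1L) {
  s <- as.double(master_seed) + 1e5 * group_index + 100 * fly_index +
    hemisphere
  as.integer(s %% 2147483647)
}

#' Generate a synthetic cohort
#'
#' Produces `n_per_group` flies per group with `hemispheres` stacks each
#' (per-hemisphere stacks are the technical replicates that
#' [collapse_replicates()] later averages). Each stack's puncta draw and
#' noise draw get seeds derived from the master seed by a fixed splitting
#' rule (`master + 1e5 * group + 100 * fly + hemisphere`), so cohorts are
#' reproducible and extensible without reshuffling.
#'
#' @param groups list of [cohort_group()]s
#' @param n_per_group flies per group (>= 1)
#' @param master_seed integer master seed
#' @param geometry shared [compartment_geometry()]; defaults to
#'   [cohort_geometry()]
#' @param acquisition shared [acquisition_model()]
#' @param hemispheres stacks (technical replicates) per fly
#' @return A list of records, each with `genotype`, `age`, `fly_id`,
#'   `hemisphere`, `stack`, `ground_truth`.
#' @export
generate_cohort <- function(groups, n_per_group, master_seed = 1L,
                            geometry = cohort_geometry(),
                            acquisition = acquisition_model(),
                            hemispheres = 1L) {
  if (n_per_group < 1L) stop("n_per_group must be >= 1")
  if (length(groups) < 1L) stop("at least one group is required")
  labels <- build_label_volume(geometry)
  out <- list()
  k <- 1L
  for (gi in seq_along(groups)) {
    grp <- groups[[gi]]
    for (fi in seq_len(n_per_group)) {
      for (hi in seq_len(hemispheres)) {
        s <- stack_seed(master_seed, gi, fi, hi)
        puncta <- sample_puncta(labels, grp$model, seed = s)
        rendered <- render_stack(labels, puncta, acquisition,
                                 seed = s + 500009L)
        out[[k]] <- list(
          genotype = grp$genotype, age = grp$age,
          fly_id = sprintf("%s_%s_fly%02d", grp$genotype, grp$age, fi),
          hemisphere = hi,
          stack = rendered$stack, ground_truth = rendered$ground_truth)
        k <- k + 1L
      }
    }
  }
  out
}
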