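# Analysis configuration: the fixed constants of a run (one threshold per
# experiment, ROI dimensions, bin width, interval policy, alpha, seed).

#' Default analysis configuration
#'
#' Returns the configuration used by [run_pipeline()], as a plain list that
#' round-trips through YAML. Fields:
#' \describe{
#'   \item{threshold}{intensity threshold applied before compartment
#'     quantification (one value for the whole experiment); default 8,
#'     about background + 3 SD of detector noise for the default
#'     acquisition model.}
#'   \item{threshold_profiles}{whether the same masking is also applied
#'     before profile projection (default `FALSE`).}
#'   \item{bin_width}{profile bin width in um (default 0.41).}
#'   \item{roi_length}{named list of profile ROI lengths in um per age
#'     class (`larva` 37, others 47).}
#'   \item{roi_width}{profile ROI width in um (~ the peduncle width).}
#'   \item{boundary_method}{`"ground-truth"` (synthetic runs), `"manual"`
#'     (use `ais_interval`), or `"marker-trough"` (automated detection
#'     with manual fallback).}
#'   \item{ais_interval}{manual `(distal, proximal)` interval in signed um,
#'     used when `boundary_method = "manual"` or as fallback.}
#'   \item{alpha}{significance level (default 0.05).}
#'   \item{seed}{master seed.}
#'   \item{cohort}{synthetic cohort description: `n_per_group`,
#'     `hemispheres`, and a list of `groups`, each with `genotype`, `age`,
#'     `ais_exclusion_depth`, `ais_exclusion_weight`, and optional
#'     `density` overrides (`calyx`, `axon_proximal`, `axon_lobe`).}
#' }
#'
#' @return A named list.
#' @export
default_config <- function() {
  list(
    threshold = 8,
    threshold_profiles = FALSE,
    bin_width = 0.41,
    roi_length = list(larva = 37, adult = 47),
    roi_width = 6,
    boundary_method = "ground-truth",
    ais_interval = c(-7, 7),
    alpha = 0.05,
    seed = 1L,
    cohort = list(
      n_per_group = 8L,
      hemispheres = 1L,
      groups = list(
        list(genotype = "WT", age = "larva", ais_exclusion_depth = 0.8,
             ais_exclusion_weight = "uniform"),
        list(genotype = "KO", age = "larva", ais_exclusion_depth = 0.0,
             ais_exclusion_weight = "uniform"))))
}

#' Demo configuration: WT-like versus KO-like larvae
#'
#' Two groups differing only in AIS exclusion depth (0.8 vs 0.0) with
#' matched compartment densities, two hemispheres per fly (exercising the
#' technical-replicate averaging), n = 8 flies per group.
#'
#' @param n_per_group flies per group
#' @param seed master seed
#' @return A config list.
#' @export
demo_config <- function(n_per_group = 8L, seed = 1L) {
  cfg <- default_config()
  cfg$seed <- seed
  cfg$cohort$n_per_group <- as.integer(n_per_group)
  cfg$cohort$hemispheres <- 2L
  cfg
}

#' Read / write an analysis configuration (YAML)
#'
#' @param path YAML file path
#' @return For `read_config`, the validated config list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cfg <- yaml::read_yaml(path)
  validate_config(utils::modifyList(default_config(), cfg))
}

#' @rdname read_config
#' @param config a config list
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

validate_config <- function(cfg) {
  cfg$seed <- as.integer(cfg$seed)
  if (!is.null(cfg$cohort)) {
    if (!is.null(cfg$cohort$n_per_group))
      cfg$cohort$n_per_group <- as.integer(cfg$cohort$n_per_group)
    if (!is.null(cfg$cohort$hemispheres))
      cfg$cohort$hemispheres <- as.integer(cfg$cohort$hemispheres)
  }
  if (!is.finite(cfg$threshold)) stop("threshold must be finite")
  if (!is.finite(cfg$bin_width) || cfg$bin_width <= 0)
    stop("bin_width must be > 0")
  if (!is.finite(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha >= 1)
    stop("alpha must be in (0, 1)")
  if (!cfg$boundary_method %in% c("ground-truth", "manual", "marker-trough"))
    stop("unknown boundary_method: ", cfg$boundary_method)
  if (!is.null(cfg$cohort)) {
    if (is.null(cfg$cohort$groups) || length(cfg$cohort$groups) == 0L)
      stop("cohort must define at least one group")
    if (is.null(cfg$cohort$n_per_group) || cfg$cohort$n_per_group < 1L)
      stop("cohort n_per_group must be >= 1")
  }
  cfg
}

# expand a config group entry into a cohort_group()
config_group <- function(g) {
  dens <- c(calyx = 1.5, axon_proximal = 1.5, axon_lobe = 1.5)
  if (!is.null(g$density)) {
    ov <- unlist(g$density)
    dens[names(ov)] <- ov
  }
  cohort_group(
    genotype = g$genotype,
    age = if (is.null(g$age)) "larva" else g$age,
    model = puncta_model(
      density_per_compartment = dens,
      ais_exclusion_depth =
        if (is.null(g$ais_exclusion_depth)) 0.8 else g$ais_exclusion_depth,
      ais_exclusion_weight =
        if (is.null(g$ais_exclusion_weight)) "uniform"
        else g$ais_exclusion_weight))
}

roi_length_for_age <- function(cfg, age) {
  rl <- cfg$roi_length
  if (!is.null(rl[[age]])) return(rl[[age]])
  if (grepl("larva", age) && !is.null(rl$larva)) return(rl$larva)
  if (!is.null(rl$adult)) return(rl$adult)
  37
}
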