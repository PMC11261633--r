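# Replicate collapsing and the group-comparison statistics: KS normality
# gate, t / Mann-Whitney two-group tests, two-way ANOVA with Sidak-adjusted
# contrasts.

#' Average technical replicates to one value per fly
#'
#' Measurements from the two MB hemispheres of one brain are technical
#' replicates; per (fly, metric) they are averaged to a single value
#' before any statistics. Flies measured in a single hemisphere pass
#' through unchanged.
#'
#' @param table data frame with columns `fly_id`, `hemisphere`,
#'   `genotype`, `age`, `metric`, `value`
#' @return A data frame with one row per (fly, metric), hemisphere column
#'   dropped.
#' @export
collapse_replicates <- function(table) {
  need <- c("fly_id", "hemisphere", "genotype", "age", "metric", "value")
  if (!all(need %in% names(table)))
    stop("table must have columns ", paste(need, collapse = ", "))
  key <- interaction(table$fly_id, table$hemisphere, table$metric, drop = TRUE)
  if (anyDuplicated(key))
    stop("duplicate (fly, hemisphere, metric) rows")
  agg <- stats::aggregate(value ~ fly_id + genotype + age + metric,
                          data = table, FUN = mean)
  agg[order(agg$metric, agg$genotype, agg$age, agg$fly_id), , drop = FALSE] ->
    agg
  rownames(agg) <- NULL
  agg
}

#' Kolmogorov-Smirnov normality check
#'
#' One-sample KS test of the data against a normal distribution with the
#' sample mean and SD. Parameters are estimated from the same sample (the
#' common packaged behaviour; no Lilliefors correction), so the p-value is
#' approximate and intentionally conservative as a gate. A constant
#' sample is degenerate and returns p = 0.
#'
#' @param x numeric sample, n >= 3
#' @return The KS p-value.
#' @export
normality_check <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3L) stop("normality check needs n >= 3")
  s <- stats::sd(x)
  if (s == 0) return(0)
  suppressWarnings(stats::ks.test(x, "pnorm", mean(x), s)$p.value)
}

#' Compare two groups with a normality-gated test
#'
#' If both groups pass the KS normality gate (p >= alpha), an unpaired
#' two-sided t-test is used: pooled-variance if the F-test of equality of
#' variances passes, Welch otherwise. If either group fails normality,
#' the two-sided Mann-Whitney U test is used (exact when the combined n
#' is <= 20 and there are no ties, normal approximation with continuity
#' and tie correction otherwise). `decision_path` records every gate
#' outcome.
#'
#' @param a,b numeric samples (n >= 3 each for the automatic gate)
#' @param alpha significance level for the gates (default 0.05)
#' @param metric label carried into the result
#' @param method `"auto"` applies the gates; `"t"` or `"mannwhitney"`
#'   force a test (forcing allows n >= 2)
#' @return A one-row data frame: `metric`, `contrast`, `test_name`,
#'   `statistic`, `p_value`, `adjusted_p`, `alpha`, `normality_p_a/b`,
#'   `decision_path`.
#' @export
compare_two_groups <- function(a, b, alpha = 0.05, metric = NA_character_,
                               method = c("auto", "t", "mannwhitney")) {
  method <- match.arg(method)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  min_n <- if (method == "auto") 3L else 2L
  if (length(a) < min_n || length(b) < min_n)
    stop("insufficient n: each group needs at least ", min_n, " values")
  path <- character(0)
  norm_a <- NA_real_; norm_b <- NA_real_
  if (method == "auto") {
    norm_a <- normality_check(a)
    norm_b <- normality_check(b)
    path <- c(path, sprintf("KS normality: p_a=%.4g, p_b=%.4g (gate %s)",
                            norm_a, norm_b,
                            if (norm_a >= alpha && norm_b >= alpha)
                              "passed" else "failed"))
    method <- if (norm_a >= alpha && norm_b >= alpha) "t" else "mannwhitney"
  } else path <- c(path, paste0("test forced: ", method))

  if (method == "t") {
    vp <- stats::var.test(a, b)$p.value
    pooled <- vp >= alpha
    path <- c(path, sprintf("F-test of variances: p=%.4g -> %s t-test", vp,
                            if (pooled) "pooled" else "Welch"))
    tt <- stats::t.test(a, b, var.equal = pooled)
    res <- list(test_name = if (pooled) "t (pooled)" else "t (Welch)",
                statistic = unname(tt$statistic), p_value = tt$p.value)
  } else {
    ties <- anyDuplicated(c(a, b)) > 0L
    exact <- (length(a) + length(b) <= 20L) && !ties
    path <- c(path, sprintf("Mann-Whitney: %s",
                            if (exact) "exact" else
                              "normal approximation with tie correction"))
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                              correct = TRUE))
    res <- list(test_name = "Mann-Whitney U", statistic = unname(wt$statistic),
                p_value = wt$p.value)
  }
  data.frame(metric = metric, contrast = "a vs b", test_name = res$test_name,
             statistic = res$statistic, p_value = res$p_value,
             adjusted_p = res$p_value, alpha = alpha,
             normality_p_a = norm_a, normality_p_b = norm_b,
             decision_path = paste(path, collapse = "; "))
}

#' Sidak multiple-comparison adjustment
#'
#' `p_adj = 1 - (1 - p)^m` for `m` contrasts in the family; equal to the
#' raw p when `m = 1` and non-decreasing in both `p` and `m`.
#'
#' @param p raw p-values
#' @param m family size (number of contrasts)
#' @return Adjusted p-values.
#' @export
sidak_adjust <- function(p, m) {
  if (any(m < 1L)) stop("m must be >= 1")
  pmin(1, 1 - (1 - p)^m)
}

#' Two-way ANOVA with Sidak-adjusted genotype contrasts within ages
#'
#' Fits `value ~ genotype * age` on per-fly values with sum-to-zero
#' contrasts and partial (Type-III) sums of squares, so unbalanced cell
#' sizes do not make the marginal tests depend on factor order. Pairwise
#' genotype contrasts within each age level are then tested and
#' Sidak-adjusted over the whole contrast family.
#'
#' @param table per-fly data frame with columns `genotype`, `age`, `value`
#'   (as produced by [collapse_replicates()] filtered to one metric)
#' @param metric label carried into the results
#' @param alpha significance level recorded in the results
#' @return A data frame of comparison results: one row per ANOVA effect
#'   (genotype, age, interaction) and one per within-age genotype contrast.
#' @export
compare_two_way <- function(table, metric = NA_character_, alpha = 0.05) {
  need <- c("genotype", "age", "value")
  if (!all(need %in% names(table)))
    stop("table must have columns ", paste(need, collapse = ", "))
  table$genotype <- factor(table$genotype)
  table$age <- factor(table$age)
  if (nlevels(table$genotype) < 2L || nlevels(table$age) < 2L)
    stop("need at least 2 levels per factor")
  cells <- table(table$genotype, table$age)
  if (any(cells == 0L)) {
    empty <- which(cells == 0L, arr.ind = TRUE)[1L, ]
    stop("empty cell: genotype=", rownames(cells)[empty[1L]],
         ", age=", colnames(cells)[empty[2L]])
  }
  fit <- stats::lm(value ~ genotype * age, data = table,
                   contrasts = list(genotype = "contr.sum", age = "contr.sum"))
  an <- car::Anova(fit, type = 3)
  effects <- c("genotype", "age", "genotype:age")
  rows <- lapply(effects, function(e) {
    data.frame(metric = metric, contrast = e,
               test_name = "two-way ANOVA (type III) F",
               statistic = an[e, "F value"], p_value = an[e, "Pr(>F)"],
               adjusted_p = an[e, "Pr(>F)"], alpha = alpha,
               normality_p_a = NA_real_, normality_p_b = NA_real_,
               decision_path = "two-way ANOVA, sum-to-zero contrasts, partial SS")
  })
  emm <- emmeans::emmeans(fit, ~ genotype | age)
  ctr <- summary(emmeans::contrast(emm, method = "pairwise", adjust = "none"))
  m <- nrow(ctr)
  crows <- lapply(seq_len(m), function(i) {
    data.frame(metric = metric,
               contrast = sprintf("%s @ age %s", ctr$contrast[i], ctr$age[i]),
               test_name = "pairwise contrast (Sidak)",
               statistic = ctr$t.ratio[i], p_value = ctr$p.value[i],
               adjusted_p = sidak_adjust(ctr$p.value[i], m), alpha = alpha,
               normality_p_a = NA_real_, normality_p_b = NA_real_,
               decision_path = sprintf(
                 "contrast from type-III model; Sidak over m=%d contrasts", m))
  })
  out <- do.call(rbind, c(rows, crows))
  rownames(out) <- NULL
  out
}
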