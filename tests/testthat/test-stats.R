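# Replicate collapsing, normality gate, two-group tests, Sidak, and the
# two-way ANOVA.

meas_row <- function(fly, hemi, geno, age, metric, value)
  data.frame(fly_id = fly, hemisphere = hemi, genotype = geno, age = age,
             metric = metric, value = value)

test_that("technical replicates are averaged to one value per fly", {
  tab <- rbind(meas_row("f1", 1, "WT", "larva", "ratio", 1),
               meas_row("f1", 2, "WT", "larva", "ratio", 3),
               meas_row("f2", 1, "WT", "larva", "ratio", 5),
               meas_row("f3", 1, "KO", "larva", "ratio", 2),
               meas_row("f3", 2, "KO", "larva", "ratio", 4),
               meas_row("f4", 1, "KO", "larva", "ratio", 7))
  out <- collapse_replicates(tab)
  expect_identical(nrow(out), 4L)
  expect_equal(out$value[out$fly_id == "f1"], 2)   # {1, 3} -> 2
  expect_equal(out$value[out$fly_id == "f2"], 5)   # single hemisphere
  expect_equal(out$value[out$fly_id == "f3"], 3)

  # duplicate (fly, hemisphere, metric) rows are an error
  expect_error(collapse_replicates(rbind(tab, tab[1, ])), "duplicate")

  # idempotence: collapsing an already-collapsed table changes nothing
  out2 <- collapse_replicates(cbind(out[1:4, ], hemisphere = 1)[,
    c("fly_id", "hemisphere", "genotype", "age", "metric", "value")])
  expect_equal(out2$value[order(out2$fly_id)], out$value[order(out$fly_id)])
})

test_that("KS normality gate accepts normal and rejects exponential samples", {
  res <- vapply(1:100, function(s) {
    set.seed(s)
    c(normality_check(rnorm(500)), normality_check(rexp(500)))
  }, numeric(2))
  expect_gte(mean(res[1, ] > 0.05), 0.90)
  expect_gte(mean(res[2, ] < 0.05), 0.90)
  # declared edge cases
  expect_error(normality_check(c(1, 2)), "n >= 3")
  expect_identical(normality_check(rep(2, 10)), 0)
})

test_that("identical groups give t = 0, p = 1", {
  res <- compare_two_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_match(res$test_name, "^t ")
  expect_match(res$decision_path, "KS normality")
})

test_that("Mann-Whitney on {1,2} vs {3,4} gives exact two-sided p = 1/3", {
  res <- compare_two_groups(c(1, 2), c(3, 4), method = "mannwhitney")
  expect_equal(res$statistic, 0)  # U = 0
  expect_equal(res$p_value, 1 / 3, tolerance = 1e-12)

  # enumeration oracle: all 6 assignments of ranks {1..4} into two pairs
  combos <- combn(4, 2)
  U <- apply(combos, 2, function(ix) {
    ra <- ix; sum(ra) - 2 * 3 / 2  # rank-sum minus min: U statistic of group a
  })
  p_exact <- sum(U <= 0 | U >= 4) / ncol(combos)  # two-sided, U in {0..4}
  expect_equal(res$p_value, p_exact, tolerance = 1e-12)
})

test_that("swapping groups flips the statistic sign and keeps p", {
  set.seed(77)
  a <- rnorm(10, 1); b <- rnorm(10)
  r1 <- compare_two_groups(a, b)
  r2 <- compare_two_groups(b, a)
  expect_equal(r1$statistic, -r2$statistic)
  expect_equal(r1$p_value, r2$p_value)
})

test_that("non-normal input is routed to Mann-Whitney by the gate", {
  set.seed(99)
  a <- rexp(40); b <- rexp(40) + 1
  res <- compare_two_groups(a, b)
  expect_identical(res$test_name, "Mann-Whitney U")
  expect_match(res$decision_path, "gate failed")
  expect_error(compare_two_groups(c(1, 2), c(3, 4)), "insufficient n")
})

test_that("Sidak adjustment is the stated arithmetic and is monotone", {
  expect_equal(sidak_adjust(0.05, 2), 1 - (1 - 0.05)^2)  # 0.0975
  expect_equal(sidak_adjust(0.05, 2), 0.0975)
  expect_equal(sidak_adjust(0.2, 1), 0.2)
  p <- seq(0, 1, by = 0.05)
  expect_true(all(diff(sidak_adjust(p, 3)) >= 0))        # monotone in p
  for (pp in c(0.01, 0.2, 0.6))
    expect_true(all(diff(sidak_adjust(pp, 1:6)) >= 0))   # monotone in m
  expect_true(all(sidak_adjust(p, 50) <= 1))
})

two_way_table <- function(seed, shift_genotype = 0, shift_age = 0,
                          n = 10, jitter = 1) {
  set.seed(seed)
  g <- expand.grid(genotype = c("WT", "KO"), age = c("a10", "a30"),
                   i = seq_len(n))
  g$value <- rnorm(nrow(g), sd = jitter) +
    shift_genotype * (g$genotype == "KO") + shift_age * (g$age == "a30")
  g
}

test_that("null two-way data yield no significant contrasts", {
  res <- compare_two_way(two_way_table(5, jitter = 0.01), metric = "m")
  ctr <- res[grepl("@ age", res$contrast), ]
  expect_identical(nrow(ctr), 2L)
  expect_true(all(ctr$adjusted_p > 0.05))
  expect_true(all(ctr$adjusted_p >= ctr$p_value))
})

test_that("two-way ANOVA detects a shifted factor in >= 95% of seeds", {
  hits <- vapply(1:100, function(s) {
    tab <- two_way_table(s, shift_genotype = 1, n = 50)
    res <- compare_two_way(tab, metric = "m")
    res$p_value[res$contrast == "genotype"] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("Sidak-adjusted contrasts match emmeans' own adjustment", {
  tab <- two_way_table(11, shift_genotype = 0.8)
  res <- compare_two_way(tab, metric = "m")
  ctr <- res[grepl("@ age", res$contrast), ]
  fit <- lm(value ~ genotype * age, data = tab,
            contrasts = list(genotype = "contr.sum", age = "contr.sum"))
  raw <- summary(emmeans::contrast(emmeans::emmeans(fit, ~ genotype | age),
                                   method = "pairwise", adjust = "none"))
  expect_equal(ctr$adjusted_p, sidak_adjust(raw$p.value, nrow(raw)),
               tolerance = 1e-12)
  expect_equal(ctr$p_value, raw$p.value, tolerance = 1e-12)
})

test_that("unbalanced designs keep marginal tests order independent", {
  tab <- two_way_table(13, shift_genotype = 0.5, n = 24)
  tab <- tab[-(1:16), ]  # unbalance the first cell (N = 24 vs 8 style)
  r1 <- compare_two_way(tab, metric = "m")
  tab2 <- tab[rev(seq_len(nrow(tab))), ]
  r2 <- compare_two_way(tab2, metric = "m")
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-10)
})

test_that("empty cells are reported by name", {
  tab <- two_way_table(17)
  tab <- tab[!(tab$genotype == "KO" & tab$age == "a30"), ]
  expect_error(compare_two_way(tab, metric = "m"), "empty cell.*KO.*a30")
  one_age <- two_way_table(18)
  one_age$age <- "a10"
  expect_error(compare_two_way(one_age, "m"), "2 levels", fixed = TRUE)
})

test_that("type-I error of the gated two-group test is near alpha", {
  rej <- vapply(1:500, function(s) {
    set.seed(s)
    compare_two_groups(rnorm(10), rnorm(10))$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.07)
})
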