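# Effect sizes and random-effects pooling.

test_that("hedges_g reproduces the closed forms", {
  # n1 = n2 = 10, means 0 / 1, sds 1 / 1:
  # d = 1, J = 1 - 3/71, g = 0.9577465, v = 0.2 + g^2/40 = 0.2229320
  e <- hedges_g(group_summary(10, 0, 1), group_summary(10, 1, 1))
  expect_equal(e$g, 1 - 3 / 71, tolerance = 1e-12)
  expect_equal(e$g, 0.9577465, tolerance = 1e-6)
  expect_equal(e$variance, 0.2229320, tolerance = 1e-6)
  expect_equal(e$ci_low, e$g - qnorm(0.975) * sqrt(e$variance))
  # identical means -> null effect
  expect_equal(hedges_g(group_summary(8, 2.5, 1.1), group_summary(12, 2.5, 0.7))$g, 0)
})

test_that("hedges_g is antisymmetric under swapping case and control", {
  set.seed(11)
  for (i in 1:20) {
    a <- group_summary(sample(2:50, 1), rnorm(1), runif(1, 0.3, 2))
    b <- group_summary(sample(2:50, 1), rnorm(1), runif(1, 0.3, 2))
    expect_equal(hedges_g(a, b)$g, -hedges_g(b, a)$g, tolerance = 1e-12)
  }
})

test_that("hedges_g rejects degenerate and undersized inputs", {
  expect_error(hedges_g(group_summary(5, 0, 0), group_summary(5, 1, 0)),
               "degenerate")
  expect_error(group_summary(1, 0, 1), ">= 2")
  expect_error(group_summary(5, 0, -1), "sd")
})

test_that("pooling matches hand-evaluated cases", {
  # single study: pooled equals the study itself
  one <- hedges_g(group_summary(10, 0, 1), group_summary(12, 1, 1), "S1")
  p1 <- pool_random_effects(one)
  expect_equal(p1$smd, one$g)
  expect_equal(p1$ci_low, one$ci_low)
  expect_equal(p1$ci_high, one$ci_high)
  expect_equal(p1$df, 0L)
  expect_equal(p1$p_het, 1)
  # two equal effects: Q = 0, tau2 = 0, se = sqrt(1/(10 + 5))
  p2 <- pool_random_effects(data.frame(g = c(0.5, 0.5), variance = c(0.1, 0.2)))
  expect_equal(p2$Q, 0)
  expect_equal(p2$tau2, 0)
  expect_equal(p2$smd, 0.5)
  expect_equal(p2$se, sqrt(1 / 15), tolerance = 1e-12)
  expect_error(pool_random_effects(data.frame(g = numeric(0), variance = numeric(0))),
               "at least one")
})

test_that("DerSimonian-Laird pooling agrees with metafor on random fixtures", {
  skip_if_not_installed("metafor")
  for (seed in c(1, 2, 3, 4, 5)) {
    eff <- random_effects(k = sample(3:15, 1), seed = seed)
    mine <- pool_random_effects(eff)
    ref <- metafor::rma(yi = eff$g, vi = eff$variance, method = "DL")
    expect_equal(mine$smd, unname(ref$beta[1, 1]), tolerance = 1e-10)
    expect_equal(mine$se, ref$se, tolerance = 1e-10)
    expect_equal(mine$tau2, ref$tau2, tolerance = 1e-10)
    expect_equal(mine$Q, ref$QE, tolerance = 1e-10)
    expect_equal(mine$i2, ref$I2, tolerance = 1e-6)
  }
})

test_that("heterogeneity statistics respect their floors and bounds", {
  for (seed in 1:25) {
    eff <- random_effects(k = sample(2:12, 1), seed = 100 + seed)
    p <- pool_random_effects(eff)
    expect_gte(p$i2, 0); expect_lte(p$i2, 100)
    expect_gte(p$tau2, 0)
    expect_lte(p$ci_low, p$smd); expect_gte(p$ci_high, p$smd)
    # random-effects CI is never narrower than fixed-effects on same input
    pf <- pool_random_effects(eff, model = "fixed")
    expect_gte(p$ci_high - p$ci_low, pf$ci_high - pf$ci_low - 1e-12)
  }
  # equal variances, equal effects: exact identity, Q = 0
  eq <- data.frame(g = rep(0.42, 6), variance = rep(0.07, 6))
  pe <- pool_random_effects(eq)
  expect_equal(pe$Q, 0)
  expect_equal(pe$smd, 0.42)
})

test_that("pooling is antisymmetric when every study's group roles flip", {
  eff <- random_effects(8, seed = 77)
  neg <- eff; neg$g <- -neg$g
  a <- pool_random_effects(eff); b <- pool_random_effects(neg)
  expect_equal(a$smd, -b$smd, tolerance = 1e-12)
  expect_equal(a$ci_low, -b$ci_high, tolerance = 1e-12)
  expect_equal(a$ci_high, -b$ci_low, tolerance = 1e-12)
  expect_equal(a$i2, b$i2, tolerance = 1e-12)
})

test_that("unit-interval significance rule uses closed intervals", {
  expect_true(significance_rule(ci_low = 0.38, ci_high = 0.88))
  expect_false(significance_rule(ci_low = -2.71, ci_high = -0.16))
  expect_false(significance_rule(ci_low = -1.0, ci_high = 0.5))  # boundary touch
  expect_false(significance_rule(ci_low = 0.99, ci_high = 1.0))
  expect_true(significance_rule(ci_low = -0.99, ci_high = 0.99))
  p <- pool_random_effects(data.frame(g = 0.5, variance = 0.001))
  expect_identical(p$significance_flag, significance_rule(p))
})

test_that("leave-one-out pooling is symmetric, sized, and localises outliers", {
  same <- data.frame(study_id = c("A", "B", "C"),
                     g = rep(0.3, 3), variance = rep(0.05, 3))
  loo <- leave_one_out(same)
  expect_length(loo, 3)
  expect_named(loo, c("A", "B", "C"))
  for (r in loo) expect_equal(r$smd, 0.3)
  # one shifted study: omitting it minimises I2
  fx <- data.frame(study_id = paste0("S", 1:5),
                   g = c(0.5, 0.52, 0.48, 0.5, 3.0),
                   variance = rep(0.05, 5))
  tab <- pooled_table(leave_one_out(fx))
  expect_equal(tab$omitted[which.min(tab$i2)], "S5")
  expect_equal(nrow(tab), 5)
  expect_error(leave_one_out(fx[1, ]), "at least two")
})

test_that("subgroup pooling filters by stratum and validates labels", {
  st <- rbind(simulate_meta_studies(meta_sim_config(n_studies = 4, seed = 3)),
              simulate_meta_studies(meta_sim_config(n_studies = 3, seed = 4,
                                                    stratum = "cirrhosis")))
  p <- subgroup_compare(st, "cirrhosis")
  expect_equal(p$k, 3)
  direct <- pool_random_effects(study_effects(st[st$stratum == "cirrhosis", ]))
  expect_equal(p$smd, direct$smd)
  one <- subgroup_compare(st[c(1, 5:7), ], "tissue")  # single tissue study
  expect_equal(one$df, 0L)
  expect_error(subgroup_compare(st, "age"), "unknown stratum")
  expect_error(subgroup_compare(st[st$stratum == "tissue", ], "metastasis"),
               "no studies")
})

test_that("null simulated subgroups stay near zero with nominal rejection", {
  res <- vapply(1:60, function(r) {
    st <- simulate_meta_studies(meta_sim_config(
      n_studies = 6, delta = 0, tau = 0, seed = 4000 + r))
    p <- subgroup_compare(st, "tissue")
    c(smd = p$smd, reject = as.numeric(p$p < 0.05))
  }, numeric(2))
  expect_lt(abs(mean(res["smd", ])), 0.05)
  expect_lte(mean(res["reject", ]), 0.15)  # zero-crossing test near nominal
  # the unit-interval rule, by construction, treats a CI pinned near zero
  # as clearing both boundaries
  expect_true(significance_rule(ci_low = -0.2, ci_high = 0.2))
})

test_that("forest table carries per-study rows plus one pooled row", {
  eff <- random_effects(6, seed = 9)
  ft <- forest_table(eff)
  expect_equal(nrow(ft), 7)
  expect_equal(ft$study_id[7], "POOLED")
  expect_equal(sum(ft$weight_percent[1:6]), 100, tolerance = 1e-9)
})
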