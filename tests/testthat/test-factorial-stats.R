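make_2x2 <- function(a_eup = c(1, 2), a_tri = c(3, 4),
                     b_eup = c(1, 2), b_tri = c(3, 4)) {
  data.frame(
    score = c(a_eup, a_tri, b_eup, b_tri),
    model = rep(c("A", "B"), times = c(length(a_eup) + length(a_tri),
                                       length(b_eup) + length(b_tri))),
    genotype = c(rep("eup", length(a_eup)), rep("tri", length(a_tri)),
                 rep("eup", length(b_eup)), rep("tri", length(b_tri))))
}

test_that("hand-computed balanced 2x2 ANOVA is reproduced exactly", {
  # cells {1,2},{3,4},{1,2},{3,4}: SS_genotype = 8, MSE = 0.5, F = 16 on (1,4)
  an <- factorial_anova(score ~ model * genotype, make_2x2())
  row <- an$table[an$table$term == "genotype", ]
  expect_equal(row$F, 16, tolerance = 1e-10)
  expect_equal(row$df, 1)
  expect_equal(an$table$df[an$table$term == "Residuals"], 4)
  expect_equal(row$sum_sq, 8, tolerance = 1e-10)
})

test_that("equal cell means give zero F and p of one", {
  d <- make_2x2(c(1, 2), c(1, 2), c(1, 2), c(1, 2))
  an <- factorial_anova(score ~ model * genotype, d)
  eff <- an$table[an$table$term != "Residuals", ]
  expect_true(all(abs(eff$F) < 1e-10))
  expect_true(all(eff$p > 1 - 1e-6))
})

test_that("Type III SS match car::Anova and a model-comparison oracle when unbalanced", {
  set.seed(88)
  d <- data.frame(
    y = rnorm(22),
    f1 = rep(c("a", "b"), times = c(13, 9)),
    f2 = c(rep(c("u", "v"), times = c(4, 9)), rep(c("u", "v"), times = c(6, 3))))
  an <- factorial_anova(y ~ f1 * f2, d)

  fit <- lm(y ~ f1 * f2, data = d,
            contrasts = list(f1 = "contr.sum", f2 = "contr.sum"))
  ca <- car::Anova(fit, type = 3)
  for (term in c("f1", "f2", "f1:f2")) {
    expect_equal(an$table$sum_sq[an$table$term == term],
                 ca[term, "Sum Sq"], tolerance = 1e-8)
  }

  # independent oracle: RSS difference between the full sum-coded model
  # matrix and the matrix with each term's columns removed
  x <- model.matrix(~ f1 * f2, d,
                    contrasts.arg = list(f1 = "contr.sum", f2 = "contr.sum"))
  rss <- function(cols) {
    fit <- lm.fit(x[, cols, drop = FALSE], d$y)
    sum(fit$residuals^2)
  }
  full <- rss(seq_len(ncol(x)))
  asg <- attr(x, "assign")
  for (k in 1:3) {
    term <- c("f1", "f2", "f1:f2")[k]
    expect_equal(an$table$sum_sq[an$table$term == term],
                 rss(which(asg != k)) - full, tolerance = 1e-8)
  }
})

test_that("Type III equals sequential Type I on balanced designs", {
  set.seed(12)
  d <- make_2x2(rnorm(4), rnorm(4), rnorm(4), rnorm(4))
  an <- factorial_anova(score ~ model * genotype, d)
  a1 <- anova(lm(score ~ model * genotype, d))
  for (term in c("model", "genotype", "model:genotype")) {
    expect_equal(an$table$sum_sq[an$table$term == term],
                 a1[term, "Sum Sq"], tolerance = 1e-8)
  }
})

test_that("empty factorial cells raise an inestimability error naming the cell", {
  d <- make_2x2()
  d <- d[!(d$model == "B" & d$genotype == "tri"), ]
  expect_error(factorial_anova(score ~ model * genotype, d),
               "model=B, genotype=tri")
})

test_that("assumption gate keeps normal data untransformed and flags skew", {
  set.seed(505)
  flags_normal <- logical(200)
  for (i in 1:200) {
    d <- data.frame(y = rnorm(50), g = rep(c("a", "b"), 25))
    gr <- gate_assumptions(d, "y", "g")
    flags_normal[i] <- !gr$log_transformed
  }
  expect_gte(mean(flags_normal), 0.90)

  flags_skew <- logical(200)
  for (i in 1:200) {
    d <- data.frame(y = exp(rnorm(50, sd = 1.2)), g = rep(c("a", "b"), 25))
    gr <- gate_assumptions(d, "y", "g")
    flags_skew[i] <- gr$log_transformed
  }
  expect_gte(mean(flags_skew), 0.90)

  # non-positive values cannot be log-transformed
  d <- data.frame(y = c(exp(rnorm(30, sd = 2)), -1, rep(0.01, 19)),
                  g = rep(c("a", "b"), 25))
  gr <- gate_assumptions(d, "y", "g")
  expect_true(gr$untransformable)
  expect_false(gr$log_transformed)
})

test_that("Levene statistic is zero when every group has zero spread", {
  lv <- levene_test(c(5, 5, 5, 7, 7, 7), rep(c("a", "b"), each = 3))
  expect_equal(lv$statistic, 0)
  expect_equal(lv$p.value, 1)
  # matches car on regular data
  set.seed(9)
  y <- rnorm(40)
  g <- rep(letters[1:4], 10)
  lv2 <- levene_test(y, g)
  ca <- car::leveneTest(y, factor(g), center = mean)
  expect_equal(lv2$statistic, ca[["F value"]][1])
  expect_equal(lv2$p.value, ca[["Pr(>F)"]][1])
})

test_that("Welch reassessment behaves like the classical F when variances agree", {
  set.seed(71)
  # shifted copies of one sample: identical group variances by construction
  base <- rnorm(50)
  y <- c(base, base + 0.5, base + 1.0)
  g <- rep(c("a", "b", "c"), each = 50)
  w <- welch_reassess(y, g)
  classical <- summary(aov(y ~ factor(g)))[[1]]$`F value`[1]
  expect_lt(abs(w$statistic - classical) / classical, 0.05)

  # clearly separated groups
  w2 <- welch_reassess(c(rnorm(10), rnorm(10) + 10), rep(c("a", "b"), each = 10))
  expect_lt(w2$p.value, 1e-6)
  expect_error(welch_reassess(c(1, 1, 2, 3), rep(c("a", "b"), each = 2)),
               "zero variance")
  expect_error(welch_reassess(c(1, 2), c("a", "b")), "n >= 2")
})

test_that("Welch type-I error is calibrated under unequal variances", {
  set.seed(2024)
  rej <- logical(500)
  for (i in 1:500) {
    y <- c(rnorm(15, sd = 1), rnorm(8, sd = 4))
    g <- rep(c("a", "b"), times = c(15, 8))
    rej[i] <- welch_reassess(y, g)$p.value < 0.05
  }
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.08)
})

test_that("Sidak and Bonferroni closed forms are exact", {
  expect_equal(sidak_adjust(0.01, 3), 0.029701, tolerance = 1e-12)
  expect_equal(sidak_adjust(0.2, 1), 0.2)
  expect_equal(sidak_adjust(0.9, 10), 1)
  expect_equal(bonferroni_adjust(0.03, 2), 0.06, tolerance = 1e-12)
  expect_equal(bonferroni_adjust(0.6, 2), 1)
  # Bonferroni is never smaller than Sidak for the same p and m
  p <- seq(0.001, 0.5, by = 0.013)
  for (m in c(2, 5, 10)) {
    expect_true(all(bonferroni_adjust(p, m) >= sidak_adjust(p, m) - 1e-15))
  }
  expect_error(sidak_adjust(0.1, 0), "m must be")
})

test_that("pairwise comparisons use cell means and the pooled residual MS", {
  set.seed(15)
  d <- data.frame(score = rnorm(24, mean = rep(c(0, 1, 0, 0), each = 6)),
                  genotype = rep(c("eup", "tri"), each = 6, times = 2),
                  sex = rep(c("M", "F"), each = 12))
  an <- factorial_anova(score ~ genotype * sex, d)
  pw <- sidak_pairwise(an, compare = "genotype", within = "sex")
  expect_equal(nrow(pw), 2)
  expect_equal(pw$m[1], 2)
  for (i in 1:2) {
    s <- pw$slice[i]
    dd <- d[d$sex == s, ]
    expect_equal(pw$estimate[i],
                 mean(dd$score[dd$genotype == "eup"]) -
                   mean(dd$score[dd$genotype == "tri"]), tolerance = 1e-10)
  }
  expect_true(all(pw$p_adj >= pw$p_raw - 1e-15))
  expect_true(all(pw$p_adj <= 1))
  # agreement with emmeans on raw t statistics
  em <- emmeans::emmeans(an$model, ~ genotype | sex)
  ct <- summary(emmeans::contrast(em, "pairwise", adjust = "none"))
  expect_equal(sort(abs(pw$t)), sort(abs(ct$t.ratio)), tolerance = 1e-8)
})

test_that("contrast estimates equal cell-mean differences and are corrected", {
  set.seed(16)
  d <- make_2x2(rnorm(4), rnorm(4) + 1, rnorm(4), rnorm(4) + 0.5)
  an <- factorial_anova(score ~ model * genotype, d)
  ct <- bonferroni_contrasts(an, list(
    A_tri_vs_eup = c("A/eup" = -1, "A/tri" = 1),
    B_tri_vs_eup = c("B/eup" = -1, "B/tri" = 1)))
  mA <- mean(d$score[d$model == "A" & d$genotype == "tri"]) -
    mean(d$score[d$model == "A" & d$genotype == "eup"])
  expect_equal(ct$estimate[ct$contrast == "A_tri_vs_eup"], mA,
               tolerance = 1e-10)
  expect_equal(ct$p_adj, pmin(1, 2 * ct$p_raw), tolerance = 1e-12)
  expect_error(bonferroni_contrasts(an, list(bad = c("C/eup" = 1))),
               "unknown cell")
  expect_error(bonferroni_contrasts(an, list()), "empty contrast set")
})

test_that("chi-square goodness of fit matches the closed form and chisq.test", {
  g <- chi_square_gof(c(60, 40), c(1, 1))
  expect_equal(g$statistic, 4, tolerance = 1e-12)
  expect_equal(g$df, 1)
  ref <- suppressWarnings(chisq.test(c(60, 40), p = c(0.5, 0.5)))
  expect_equal(g$p.value, ref$p.value, tolerance = 1e-12)

  perfect <- chi_square_gof(c(25, 25, 25, 25), rep(1, 4))
  expect_equal(perfect$statistic, 0)
  expect_equal(perfect$p.value, 1)

  # Mendelian 1:1:1:1 with a deficit category
  g4 <- chi_square_gof(c(30, 14, 28, 28), rep(1, 4))
  ref4 <- suppressWarnings(chisq.test(c(30, 14, 28, 28), p = rep(0.25, 4)))
  expect_equal(g4$statistic, unname(ref4$statistic), tolerance = 1e-12)

  expect_error(chi_square_gof(c(0, 0)), "total count is zero")
  expect_error(chi_square_gof(c(1.5, 2)), "integers")
  expect_error(chi_square_gof(c(10, 10), c(1, 0)), "positive")
})

test_that("group-mean correlation matches the hand Pearson formula", {
  gc <- groupmean_correlation(c(1, 2, 3), c(1, 3, 2))
  expect_equal(gc$r, 0.5, tolerance = 1e-12)
  expect_equal(gc$df, 1)
  # antisymmetry under sign flip of y
  gc2 <- groupmean_correlation(c(1, 2, 3), -c(1, 3, 2))
  expect_equal(gc2$r, -0.5, tolerance = 1e-12)
  expect_equal(abs(gc2$t), abs(gc$t), tolerance = 1e-12)
  # collinear means
  gc3 <- groupmean_correlation(1:4, 2 * (1:4) + 3)
  expect_equal(gc3$r, 1)
  expect_equal(gc3$p.value, 0)
  # weighting by n changes the estimate when groups differ in size
  gw <- groupmean_correlation(c(1, 2, 3), c(1, 3, 2), n = c(10, 10, 1))
  expect_false(isTRUE(all.equal(gw$r, 0.5)))
  expect_error(groupmean_correlation(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(groupmean_correlation(c(1, 2), c(1, 2)), "at least 3")
})
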