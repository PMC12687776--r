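#' Assumption gating for factorial ANOVA
#'
#' Tests normality of the full-factorial model residuals with Shapiro-Wilk
#' at `alpha`; on failure, and if all response values are positive, the
#' response is natural-log transformed and retested. Levene's test
#' (center = mean) across the factorial cells is recorded; a significant
#' Levene result flags the analysis for Welch reassessment downstream.
#'
#' @param data data.frame holding the response and factors.
#' @param response response column name.
#' @param factors character vector of between-subject factor columns.
#' @param alpha gate level.
#' @param on test residuals of the full model (`"residuals"`, default) or
#'   each cell's values (`"cells"`, flagged non-normal if any cell fails).
#' @return A list: `data` (response possibly log-transformed),
#'   `shapiro_p`, `shapiro_p_after`, `log_transformed`, `untransformable`,
#'   `levene_p`, `needs_welch`.
#' @export
gate_assumptions <- function(data, response, factors, alpha = 0.05,
                             on = c("residuals", "cells")) {
  on <- match.arg(on)
  y <- data[[response]]
  if (any(!is.finite(y))) stop_input("response contains non-finite values")
  cells <- interaction(data[factors], drop = TRUE)

  sw_p <- function(d) {
    if (on == "residuals") {
      f <- stats::as.formula(paste(response, "~", paste(factors, collapse = "*")))
      r <- stats::residuals(lm(f, data = d))
      shapiro.test(r)$p.value
    } else {
      min(tapply(d[[response]], cells, function(v) {
        if (length(v) < 3 || sd(v) == 0) return(1)
        shapiro.test(v)$p.value
      }))
    }
  }

  p1 <- sw_p(data)
  log_transformed <- FALSE
  untransformable <- FALSE
  p2 <- NA_real_
  if (p1 < alpha) {
    if (all(y > 0)) {
      data[[response]] <- log(y)
      log_transformed <- TRUE
      p2 <- sw_p(data)
    } else {
      untransformable <- TRUE
    }
  }
  lev <- levene_test(data[[response]], cells)
  list(data = data, shapiro_p = p1, shapiro_p_after = p2,
       log_transformed = log_transformed, untransformable = untransformable,
       levene_statistic = lev$statistic, levene_p = lev$p.value,
       needs_welch = isTRUE(lev$p.value < alpha))
}

#' Levene's test for homogeneity of variance (center = mean)
#'
#' Mean-centered Levene test across groups. When every group has zero
#' spread the statistic is taken as 0 (perfect homogeneity) rather than
#' the indeterminate 0/0.
#'
#' @param values numeric response.
#' @param groups grouping vector.
#' @return List with `statistic`, `df`, `p.value`.
#' @export
levene_test <- function(values, groups) {
  groups <- factor(groups)
  dev <- abs(values - stats::ave(values, groups))
  if (all(dev == 0)) {
    return(list(statistic = 0, df = c(nlevels(groups) - 1,
                                      length(values) - nlevels(groups)),
                p.value = 1))
  }
  lev <- car::leveneTest(values, groups, center = mean)
  list(statistic = lev[["F value"]][1],
       df = c(lev$Df[1], lev$Df[2]),
       p.value = lev[["Pr(>F)"]][1])
}

#' Factorial ANOVA with Type III sums of squares
#'
#' Fits the full-interaction fixed-effects linear model with sum-to-zero
#' factor coding and computes marginal (each-term-last, Type III) sums of
#' squares, the appropriate decomposition when group sizes differ. On a
#' balanced design Type III coincides with sequential Type I sums of
#' squares.
#'
#' @param formula model formula, e.g. `score ~ genotype * sex`; all
#'   right-hand-side terms must be categorical.
#' @param data data.frame.
#' @return Object of class `factorial_anova`: `table` (term, df, sum_sq,
#'   mean_sq, F, p plus a Residuals row), `model` (the underlying `lm`),
#'   `data`, `factors`.
#' @export
factorial_anova <- function(formula, data) {
  factors <- all.vars(formula[[3]])
  response <- all.vars(formula[[2]])
  for (f in factors) {
    data[[f]] <- factor(data[[f]])
    if (nlevels(data[[f]]) < 2) stop_input("factor %s has fewer than 2 levels", f)
  }
  counts <- table(data[factors])
  if (any(counts == 0)) {
    empty <- which(counts == 0, arr.ind = TRUE, useNames = FALSE)
    lab <- apply(empty, 1, function(i) {
      paste(mapply(function(f, k) paste0(f, "=", levels(data[[f]])[k]),
                   factors, i), collapse = ", ")
    })
    stop_input("empty factorial cell(s) make terms inestimable: %s",
               paste(lab, collapse = "; "))
  }
  contr <- setNames(rep(list("contr.sum"), length(factors)), factors)
  fit <- lm(formula, data = data, contrasts = contr)

  # each-term-last: refit dropping every term (marginality ignored on purpose)
  d1 <- drop1(fit, scope = . ~ ., test = "F")
  terms_ <- rownames(d1)[-1]
  res_df <- fit$df.residual
  res_ss <- sum(stats::residuals(fit)^2)
  tab <- data.frame(
    term = c(terms_, "Residuals"),
    df = c(d1$Df[-1], res_df),
    sum_sq = c(d1$`Sum of Sq`[-1], res_ss),
    stringsAsFactors = FALSE)
  tab$mean_sq <- tab$sum_sq / tab$df
  tab$F <- c(d1$`F value`[-1], NA)
  tab$p <- c(d1$`Pr(>F)`[-1], NA)
  structure(list(table = tab, model = fit, data = data,
                 factors = factors, response = response,
                 formula = formula),
            class = "factorial_anova")
}

#' @export
print.factorial_anova <- function(x, ...) {
  cat("Factorial ANOVA (Type III sums of squares, sum-to-zero coding)\n")
  cat(sprintf("  %s\n", deparse(x$formula)))
  tab <- x$table
  tab$sum_sq <- signif(tab$sum_sq, 6)
  tab$mean_sq <- signif(tab$mean_sq, 6)
  tab$F <- signif(tab$F, 5)
  tab$p <- signif(tab$p, 4)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Welch's heteroscedastic F reassessment
#'
#' One-way Welch test across the marginal groups of a flagged term, used as
#' a side-check when both Levene's test and the term's ANOVA p-value are
#' significant. If the Welch test disagrees, the term is reported
#' non-significant.
#'
#' @param values numeric response.
#' @param groups grouping vector (the flagged term's marginal groups).
#' @return List with `statistic`, `df` (num, denom), `p.value`.
#' @export
welch_reassess <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop_input("need at least 2 groups")
  ns <- tapply(values, groups, length)
  if (any(ns < 2)) stop_input("every group needs n >= 2")
  vs <- tapply(values, groups, var)
  if (any(vs == 0)) stop_input("a group has zero variance; Welch F is undefined")
  w <- oneway.test(values ~ groups, var.equal = FALSE)
  list(statistic = unname(w$statistic),
       df = unname(w$parameter),
       p.value = w$p.value)
}

#' Sidak and Bonferroni familywise adjustments
#'
#' Closed forms: Sidak `1 - (1 - p)^m`, Bonferroni `min(1, m p)`, both
#' capped at 1.
#'
#' @param p raw p-value(s).
#' @param m family size (number of comparisons performed), >= 1.
#' @return Adjusted p-value(s).
#' @export
sidak_adjust <- function(p, m) {
  if (m < 1) stop_input("family size m must be >= 1")
  pmin(1, 1 - (1 - p)^m)
}

#' @rdname sidak_adjust
#' @export
bonferroni_adjust <- function(p, m) {
  if (m < 1) stop_input("family size m must be >= 1")
  pmin(1, m * p)
}

#' Sidak-corrected pairwise comparisons within interaction slices
#'
#' Compares the levels of `compare` within every cell of the `within`
#' factors, using the factorial model's pooled residual mean square and
#' cell sizes. The family size `m` is the number of comparisons actually
#' performed in the stated slicing.
#'
#' @param fit a [factorial_anova()].
#' @param compare factor whose levels are compared.
#' @param within character vector of slicing factors (may be empty).
#' @return data.frame with one row per comparison: slice, levels compared,
#'   estimate, SE, t, df, `p_raw` and Sidak-adjusted `p_adj`.
#' @export
sidak_pairwise <- function(fit, compare, within = setdiff(fit$factors, compare)) {
  if (!inherits(fit, "factorial_anova")) stop_input("fit must be a factorial_anova")
  if (!compare %in% fit$factors) stop_input("%s is not a model factor", compare)
  data <- fit$data
  mse <- fit$table$mean_sq[fit$table$term == "Residuals"]
  df <- fit$table$df[fit$table$term == "Residuals"]

  slice <- if (length(within)) {
    interaction(data[within], drop = TRUE, sep = "/")
  } else {
    factor(rep("all", nrow(data)))
  }
  rows <- list()
  for (s in levels(slice)) {
    d <- data[slice == s, , drop = FALSE]
    lv <- levels(factor(d[[compare]]))
    if (length(lv) < 2) next
    for (i in seq_len(length(lv) - 1)) for (j in (i + 1):length(lv)) {
      xi <- d[[fit$response]][d[[compare]] == lv[i]]
      xj <- d[[fit$response]][d[[compare]] == lv[j]]
      est <- mean(xi) - mean(xj)
      se <- sqrt(mse * (1 / length(xi) + 1 / length(xj)))
      tval <- est / se
      rows[[length(rows) + 1L]] <- data.frame(
        slice = s, level_1 = lv[i], level_2 = lv[j],
        estimate = est, se = se, t = tval, df = df,
        p_raw = 2 * pt(-abs(tval), df), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop_input("no pairwise comparisons defined (m = 0)")
  out <- do.call(rbind, rows)
  out$m <- nrow(out)
  out$p_adj <- sidak_adjust(out$p_raw, nrow(out))
  out
}

#' Bonferroni-corrected contrasts on factorial cell means
#'
#' Estimates linear contrasts of the factorial cell means (e.g. genotype
#' differences within one mouse model) with the pooled residual variance,
#' and applies the Bonferroni correction over the contrast family.
#'
#' @param fit a [factorial_anova()].
#' @param contrasts named list; each element is a named numeric vector of
#'   weights over cell labels. Cells are labelled by joining factor levels
#'   with `"/"` in the order of `fit$factors`; unmentioned cells get
#'   weight 0.
#' @return data.frame with estimate, SE, t, df, `p_raw`, `p_adj`.
#' @export
bonferroni_contrasts <- function(fit, contrasts) {
  if (!inherits(fit, "factorial_anova")) stop_input("fit must be a factorial_anova")
  if (!length(contrasts)) stop_input("empty contrast set")
  data <- fit$data
  cell <- interaction(data[fit$factors], drop = FALSE, sep = "/")
  means <- tapply(data[[fit$response]], cell, mean)
  ns <- tapply(data[[fit$response]], cell, length)
  mse <- fit$table$mean_sq[fit$table$term == "Residuals"]
  df <- fit$table$df[fit$table$term == "Residuals"]

  rows <- lapply(names(contrasts), function(nm) {
    w <- contrasts[[nm]]
    bad <- setdiff(names(w), levels(cell))
    if (length(bad)) stop_input("contrast %s references unknown cell(s): %s",
                                nm, paste(bad, collapse = ", "))
    used <- names(w)[w != 0]
    if (any(is.na(means[used]))) {
      stop_input("contrast %s is inestimable: empty cell(s) %s", nm,
                 paste(used[is.na(means[used])], collapse = ", "))
    }
    est <- sum(w * means[names(w)])
    se <- sqrt(mse * sum(w^2 / ns[names(w)]))
    tval <- est / se
    data.frame(contrast = nm, estimate = est, se = se, t = tval, df = df,
               p_raw = 2 * pt(-abs(tval), df), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$m <- nrow(out)
  out$p_adj <- bonferroni_adjust(out$p_raw, nrow(out))
  out
}

#' Chi-square goodness of fit against expected ratios
#'
#' Tests observed category counts (e.g. offspring genotypes) against
#' expected ratios (e.g. Mendelian 1:1 transmission).
#'
#' @param observed non-negative integer counts.
#' @param expected_ratios positive ratios; normalized internally.
#' @return List with `statistic`, `df`, `p.value`, `expected`.
#' @export
chi_square_gof <- function(observed, expected_ratios = rep(1, length(observed))) {
  if (any(observed < 0) || any(observed != round(observed))) {
    stop_input("observed counts must be non-negative integers")
  }
  if (length(observed) != length(expected_ratios)) {
    stop_input("observed and expected_ratios differ in length")
  }
  if (any(expected_ratios <= 0)) stop_input("expected ratios must be positive")
  total <- sum(observed)
  if (total == 0) stop_input("total count is zero")
  e <- expected_ratios / sum(expected_ratios) * total
  stat <- sum((observed - e)^2 / e)
  df <- length(observed) - 1L
  list(statistic = stat, df = df,
       p.value = pchisq(stat, df, lower.tail = FALSE), expected = e)
}

#' Correlation of group means
#'
#' Pearson correlation across group means (optionally weighted by group
#' sample size), with significance from the two-tailed t distribution on
#' `k - 2` degrees of freedom, `k` the number of groups.
#'
#' @param x,y group means.
#' @param n optional group sizes used as weights; `NULL` for unweighted.
#' @return List with `r`, `t`, `df`, `p.value`, `k`.
#' @export
groupmean_correlation <- function(x, y, n = NULL) {
  k <- length(x)
  if (k < 3) stop_input("need at least 3 groups")
  if (length(y) != k) stop_input("x and y differ in length")
  w <- if (is.null(n)) rep(1, k) else n / sum(n) * k
  mx <- sum(w * x) / sum(w)
  my <- sum(w * y) / sum(w)
  sxx <- sum(w * (x - mx)^2)
  syy <- sum(w * (y - my)^2)
  if (sxx == 0 || syy == 0) {
    stop_input("zero variance in group means; correlation undefined")
  }
  r <- sum(w * (x - mx) * (y - my)) / sqrt(sxx * syy)
  if (abs(r) >= 1) {
    tval <- sign(r) * Inf
    p <- 0
  } else {
    tval <- r * sqrt((k - 2) / (1 - r^2))
    p <- 2 * pt(-abs(tval), k - 2)
  }
  list(r = r, t = tval, df = k - 2, p.value = p, k = k)
}
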