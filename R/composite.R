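#' Fit a first-principal-component composite scorer
#'
#' Fits a PCA to pooled, standardized bone variables and retains the first
#' component as a composite phenotype index. The loadings of PC1 weight
#' each animal's standardized variable vector into a single score per
#' compartment, so that correlated deficits spread over several variables
#' accumulate into one test statistic instead of being diluted across
#' many corrected univariate tests.
#'
#' The decomposition is of the sample covariance matrix of the pooled
#' values (inputs are z-scores, so this is close to the correlation
#' matrix; set `use_correlation = TRUE` to rescale columns explicitly).
#' Because an eigenvector's sign is arbitrary, the component is oriented so
#' that the `anchor` variable loads positively; with the default anchors
#' (bone volume fraction for trabecular, cortical area for cortical) a
#' lower composite score reads as a deficit.
#'
#' @param data data.frame of standardized values (one row per animal).
#' @param variables variables entering the component.
#' @param anchor variable whose loading is forced positive.
#' @param center center columns before the decomposition (the pooled
#'   z-scores have stratum means of exactly zero, so this is a numerical
#'   formality; it is kept explicit).
#' @param use_correlation decompose the correlation matrix instead of the
#'   covariance matrix.
#' @return An object of class `pc_composite` with components `loadings`
#'   (oriented PC1, unit norm), `rotation` (all components),
#'   `variance_explained`, `sdev`, `center`, `variables`, `anchor`, `n`.
#' @seealso [predict.pc_composite()], [orient_loadings()],
#'   [composite_scores()]
#' @export
pc_composite <- function(data, variables = trabecular_variables(),
                         anchor = if ("BVTV" %in% variables) "BVTV" else variables[1],
                         center = TRUE, use_correlation = FALSE) {
  miss <- setdiff(variables, names(data))
  if (length(miss)) stop_input("missing variable(s): %s",
                               paste(miss, collapse = ", "))
  if (length(variables) < 2) stop_input("need at least 2 variables")
  x <- as.matrix(data[variables])
  x <- x[complete.cases(x), , drop = FALSE]
  n <- nrow(x)
  if (n < 3) stop_input("need at least 3 complete animals")
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    stop_input("constant column(s): %s",
               paste(variables[sds == 0], collapse = ", "))
  }
  if (n <= length(variables)) {
    warning("fewer animals than variables + 1; components beyond rank ",
            n - 1, " have zero variance", call. = FALSE)
  }
  p <- prcomp(x, center = center, scale. = use_correlation)
  ve <- p$sdev^2 / sum(p$sdev^2)
  obj <- structure(list(
    loadings = p$rotation[, 1],
    rotation = p$rotation,
    variance_explained = ve,
    sdev = p$sdev,
    center = if (isTRUE(center)) p$center else setNames(rep(0, length(variables)), variables),
    scale = p$scale,
    variables = variables,
    anchor = anchor,
    n = n,
    call = match.call()), class = "pc_composite")
  orient_loadings(obj, anchor)
}

#' Resolve the sign of the first component
#'
#' Eigenvectors are defined up to sign; this fixes the convention by
#' negating PC1 if the anchor variable loads negatively. Idempotent.
#'
#' @param object a `pc_composite`.
#' @param anchor variable name with a nonzero PC1 loading.
#' @return The reoriented `pc_composite`.
#' @export
orient_loadings <- function(object, anchor = object$anchor) {
  if (!anchor %in% object$variables) {
    stop_input("anchor %s is not among the model variables", anchor)
  }
  l <- object$loadings[anchor]
  if (l == 0) {
    stop_input("anchor %s has a zero loading; choose a different anchor", anchor)
  }
  if (l < 0) {
    object$loadings <- -object$loadings
    object$rotation[, 1] <- -object$rotation[, 1]
  }
  object$anchor <- anchor
  object
}

#' Composite scores for standardized animals
#'
#' The score is the inner product of the oriented PC1 loadings with the
#' animal's standardized variable vector: `score = sum_v loading_v * z_v`.
#' Scored animals must be complete on the model's variables.
#'
#' @param object a `pc_composite`.
#' @param newdata data.frame of standardized values.
#' @param ... unused.
#' @return Numeric vector of scores, named by `animal_id` when present.
#' @export
predict.pc_composite <- function(object, newdata, ...) {
  miss <- setdiff(object$variables, names(newdata))
  if (length(miss)) {
    stop_input("newdata misses model variable(s): %s",
               paste(miss, collapse = ", "))
  }
  x <- as.matrix(newdata[object$variables])
  if (any(!complete.cases(x))) {
    stop_input("composite scores need complete standardized values")
  }
  s <- drop(x %*% object$loadings)
  if ("animal_id" %in% names(newdata)) names(s) <- newdata$animal_id
  s
}

#' @rdname predict.pc_composite
#' @param model a `pc_composite`.
#' @param data data.frame of standardized values.
#' @export
composite_scores <- function(model, data) {
  predict(model, data)
}

#' @export
fitted.pc_composite <- function(object, ...) {
  stop_input("pc_composite does not store its training data; use predict()")
}

#' @export
coef.pc_composite <- function(object, ...) object$loadings

#' @export
print.pc_composite <- function(x, ...) {
  cat(sprintf("PC1 composite scorer (%d variables, n = %d)\n",
              length(x$variables), x$n))
  cat(sprintf("  variance explained by PC1: %.1f%%\n",
              100 * x$variance_explained[1]))
  cat(sprintf("  anchor: %s (loading forced positive)\n", x$anchor))
  cat("  loadings:\n")
  print(round(x$loadings, 4))
  invisible(x)
}

#' @export
summary.pc_composite <- function(object, ...) {
  tab <- data.frame(variable = object$variables,
                    loading = unname(object$loadings))
  ve <- data.frame(component = paste0("PC", seq_along(object$variance_explained)),
                   variance_explained = object$variance_explained)
  out <- list(loadings = tab, variance = ve, n = object$n,
              anchor = object$anchor)
  class(out) <- "summary.pc_composite"
  out
}

#' @export
print.summary.pc_composite <- function(x, ...) {
  cat(sprintf("PC1 composite scorer, n = %d animals\n", x$n))
  print(x$loadings, row.names = FALSE)
  cat("\nVariance explained:\n")
  print(transform(x$variance,
                  variance_explained = round(variance_explained, 4)),
        row.names = FALSE)
  invisible(x)
}

#' @export
plot.pc_composite <- function(x, ...) {
  op <- par(mfrow = c(1, 2))
  on.exit(par(op))
  barplot(100 * x$variance_explained,
          names.arg = paste0("PC", seq_along(x$variance_explained)),
          ylab = "variance explained (%)", ...)
  barplot(x$loadings, ylab = "PC1 loading", las = 2, ...)
  abline(h = 0)
  invisible(x)
}

#' Write PC1 loadings to CSV
#'
#' @param object a `pc_composite`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_loadings <- function(object, path) {
  tab <- data.frame(variable = object$variables,
                    loading = unname(object$loadings),
                    variance_explained_pc1 = object$variance_explained[1])
  write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
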