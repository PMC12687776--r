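#' Default baseline means and standard deviations for bone variables
#'
#' Per-variable, per-model baselines used by the synthetic cohort generator.
#' Values are plausible magnitudes for murine distal femur trabecular and
#' midshaft cortical variables; the model-specific offsets emulate background
#' strain differences between colonies so that pooling raw values across
#' models is visibly inappropriate without standardization. These defaults
#' are assumptions of the simulator, not estimates from any dataset.
#'
#' @return A data.frame with columns `variable`, `Ts65Dn`, `Ts66Yah`
#'   (means) for `default_baseline_means()`, or `variable`, `sd` for
#'   `default_baseline_sds()` (SDs shared across models).
#' @export
default_baseline_means <- function() {
  v <- data.frame(
    variable = panel_variables(),
    Ts65Dn = c(
      0.22, 14.0, 0.046, 0.26, 2.9,          # trabecular
      1.75, 0.95, 0.80, 45.5, 0.185, 5.6, 3.9, 0.21, 0.12, 1.10),
    Ts66Yah = c(
      0.25, 12.0, 0.043, 0.29, 2.6,
      1.65, 0.88, 0.77, 46.5, 0.180, 5.4, 3.7, 0.19, 0.11, 1.15)
  )
  v
}

#' @rdname default_baseline_means
#' @export
default_baseline_sds <- function() {
  data.frame(
    variable = panel_variables(),
    sd = c(
      0.020, 2.2, 0.004, 0.030, 0.35,
      0.12, 0.09, 0.06, 2.8, 0.012, 0.30, 0.28, 0.030, 0.018, 0.045)
  )
}

#' Default compartment correlation matrices
#'
#' Trabecular: exchangeable correlation 0.6 in magnitude with `Tb.Sp`
#' anticorrelated with the other four variables. Cortical: the five size
#' variables (areas and perimeters) correlate at 0.7, `Ma.Ar`/`Ec.Pm` are
#' negatively correlated with `Ct.Ar_Tt.Ar` and `Ct.Th`, and `Ct.TMD` is
#' weakly coupled. Both matrices are symmetric positive definite.
#'
#' @param compartment `"trabecular"` or `"cortical"`.
#' @return A correlation matrix with unit diagonal.
#' @export
default_correlation <- function(compartment = c("trabecular", "cortical")) {
  compartment <- match.arg(compartment)
  if (compartment == "trabecular") {
    vars <- trabecular_variables()
    s <- ifelse(vars == "Tb.Sp", -1, 1)
    r <- 0.6 * tcrossprod(s)
    diag(r) <- 1
    dimnames(r) <- list(vars, vars)
    return(r)
  }
  vars <- cortical_variables()
  p <- length(vars)
  r <- diag(p)
  dimnames(r) <- list(vars, vars)
  size <- c("Tt.Ar", "Ma.Ar", "Ct.Ar", "Ps.Pm", "Ec.Pm", "Imax", "Imin")
  for (a in size) for (b in size) if (a != b) r[a, b] <- 0.7
  weak <- c("Ct.Ar_Tt.Ar", "Ct.Th", "Ct.TMD")
  for (a in weak) for (b in vars) if (a != b) {
    r[a, b] <- r[b, a] <- 0.10
  }
  r["Ct.Ar_Tt.Ar", "Ct.Th"] <- r["Ct.Th", "Ct.Ar_Tt.Ar"] <- 0.30
  # larger marrow cavity means a lower bone area fraction
  r["Ct.Ar_Tt.Ar", "Ma.Ar"] <- r["Ma.Ar", "Ct.Ar_Tt.Ar"] <- -0.20
  r["Ct.Ar_Tt.Ar", "Ec.Pm"] <- r["Ec.Pm", "Ct.Ar_Tt.Ar"] <- -0.20
  r
}

#' Configure a synthetic animal cohort
#'
#' Builds and validates the configuration consumed by [generate_cohort()].
#' Group sizes may be a single integer (balanced design) or a per-cell table
#' with an `n` column to emulate the unbalanced group sizes typical of mouse
#' studies (9-21 per group).
#'
#' Effects are additive on the raw variable scale in units of that
#' variable's within-model SD, so a `shift` of -1 on `BVTV` for
#' `genotype = "trisomic"` moves the trisomic group mean down by one SD.
#' Interaction effects use colon-joined terms and levels, e.g.
#' `term = "genotype:sex", level = "trisomic:M"`.
#'
#' @param n_per_group integer, or data.frame of factor columns plus `n`.
#' @param models,genotypes,sexes,ages,treatments factor levels to cross.
#'   Levels must come from the declared level sets (Ts65Dn/Ts66Yah,
#'   euploid/trisomic, M/F, P36/6wk/9wk/16wk, none/vehicle/L21).
#' @param effects data.frame with columns `term`, `level`, `variable`,
#'   `shift` (SD units), or `NULL` for no effects.
#' @param baseline_means,baseline_sds baselines per variable (see
#'   [default_baseline_means()]).
#' @param correlation named list with `trabecular` and `cortical`
#'   correlation matrices.
#' @param missing_frac fraction of panel cells set missing at random.
#' @param seed integer seed; mandatory for reproducibility.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = 12,
                          models = c("Ts65Dn", "Ts66Yah"),
                          genotypes = c("euploid", "trisomic"),
                          sexes = c("M", "F"),
                          ages = "6wk",
                          treatments = "none",
                          effects = NULL,
                          baseline_means = default_baseline_means(),
                          baseline_sds = default_baseline_sds(),
                          correlation = list(
                            trabecular = default_correlation("trabecular"),
                            cortical = default_correlation("cortical")),
                          missing_frac = 0,
                          seed = 1L) {
  lv <- cohort_factor_levels()
  chk_levels <- function(x, which) {
    bad <- setdiff(x, lv[[which]])
    if (length(bad)) {
      stop_input("unknown %s level(s): %s", which, paste(bad, collapse = ", "))
    }
  }
  chk_levels(models, "model")
  chk_levels(genotypes, "genotype")
  chk_levels(sexes, "sex")
  chk_levels(ages, "age")
  chk_levels(treatments, "treatment")

  for (comp in names(correlation)) {
    r <- correlation[[comp]]
    if (!isSymmetric(unname(r)) || any(abs(diag(r) - 1) > 1e-12)) {
      stop_input("correlation matrix for %s must be symmetric with unit diagonal",
                 comp)
    }
    ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) {
      stop_input("correlation matrix for %s is not positive definite", comp)
    }
  }
  if (any(baseline_sds$sd <= 0)) stop_input("all baseline SDs must be > 0")
  if (!is.null(effects)) {
    need <- c("term", "level", "variable", "shift")
    if (!all(need %in% names(effects))) {
      stop_input("effects needs columns %s", paste(need, collapse = ", "))
    }
    if (any(!is.finite(effects$shift))) stop_input("effect shifts must be finite")
    bad <- setdiff(effects$variable, panel_variables())
    if (length(bad)) stop_input("unknown effect variable(s): %s",
                                paste(bad, collapse = ", "))
  }
  if (missing_frac < 0 || missing_frac >= 1) {
    stop_input("missing_frac must be in [0, 1)")
  }
  if (is.null(seed) || !is.finite(seed)) stop_input("seed is mandatory")

  cells <- expand.grid(model = models, genotype = genotypes, sex = sexes,
                       age = ages, treatment = treatments,
                       stringsAsFactors = FALSE,
                       KEEP.OUT.ATTRS = FALSE)
  if (is.data.frame(n_per_group)) {
    key <- intersect(names(n_per_group), names(cells))
    if (!length(key) || !"n" %in% names(n_per_group)) {
      stop_input("per-cell n table needs factor columns plus an `n` column")
    }
    cells <- merge(cells, n_per_group, by = key, all.x = TRUE, sort = FALSE)
    if (any(is.na(cells$n))) stop_input("per-cell n table misses some cells")
  } else {
    if (n_per_group < 1) stop_input("n_per_group must be positive")
    cells$n <- as.integer(n_per_group)
  }
  cells <- cells[order(cells$model, cells$genotype, cells$sex, cells$age,
                       cells$treatment), , drop = FALSE]
  rownames(cells) <- NULL

  structure(list(cells = cells, effects = effects,
                 baseline_means = baseline_means,
                 baseline_sds = baseline_sds,
                 correlation = correlation,
                 missing_frac = missing_frac,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# summed SD-unit shift for one factorial cell and one variable set
cell_shifts <- function(effects, cell, variables) {
  shift <- setNames(numeric(length(variables)), variables)
  if (is.null(effects)) return(shift)
  for (i in seq_len(nrow(effects))) {
    term <- strsplit(effects$term[i], ":", fixed = TRUE)[[1]]
    level <- strsplit(effects$level[i], ":", fixed = TRUE)[[1]]
    if (length(term) != length(level)) {
      stop_input("effect term %s and level %s differ in arity",
                 effects$term[i], effects$level[i])
    }
    if (!all(term %in% names(cell))) {
      stop_input("effect term references unknown factor: %s", effects$term[i])
    }
    if (all(unlist(cell[term]) == level)) {
      v <- effects$variable[i]
      if (v %in% variables) shift[v] <- shift[v] + effects$shift[i]
    }
  }
  shift
}

#' Generate a synthetic animal cohort
#'
#' Draws, for every factorial cell, the trabecular and cortical variable
#' panels from multivariate normal distributions with mean
#' `baseline + summed SD-unit effects` and covariance `D R D` (`D` the
#' diagonal of baseline SDs, `R` the configured compartment correlation
#' matrix). Body weight and femur length are drawn from sex- and
#' age-dependent baselines with a shared size factor. Output is
#' deterministic given the config seed.
#'
#' @param config a [cohort_config()].
#' @param seed optional override of `config$seed`.
#' @return A data.frame with one row per animal: factor columns
#'   (`animal_id`, `model`, `genotype`, `sex`, `age`, `dyrk1a_copies`,
#'   `treatment`), `body_weight` (g), `femur_length` (mm), then the 15
#'   panel variables.
#' @export
generate_cohort <- function(config, seed = NULL) {
  if (!inherits(config, "cohort_config")) {
    stop_input("config must come from cohort_config()")
  }
  set.seed(if (is.null(seed)) config$seed else as.integer(seed))
  cells <- config$cells
  mu_tab <- config$baseline_means
  sd_tab <- setNames(config$baseline_sds$sd, config$baseline_sds$variable)
  comps <- list(trabecular = trabecular_variables(),
                cortical = cortical_variables())

  wt_base <- c(P36 = 16, `6wk` = 19, `9wk` = 23, `16wk` = 27)
  fl_base <- c(P36 = 12.6, `6wk` = 13.8, `9wk` = 14.8, `16wk` = 15.6)

  out <- vector("list", nrow(cells))
  idx <- 0L
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, , drop = FALSE]
    n <- cell$n
    panel <- matrix(NA_real_, n, 0)
    for (comp in names(comps)) {
      vars <- comps[[comp]]
      r <- config$correlation[[comp]]
      if (is.null(r)) stop_input("no correlation matrix for %s", comp)
      r <- r[vars, vars]
      sds <- sd_tab[vars]
      mu <- mu_tab[[cell$model]][match(vars, mu_tab$variable)] +
        cell_shifts(config$effects, cell, vars) * sds
      sigma <- diag(sds) %*% r %*% diag(sds)
      x <- MASS::mvrnorm(n, mu = mu, Sigma = sigma)
      if (n == 1L) x <- matrix(x, nrow = 1)
      colnames(x) <- vars
      panel <- cbind(panel, x)
    }
    size <- rnorm(n)  # shared size factor ties weight to femur length
    sexf <- if (cell$sex == "F") -1.2 else 0
    wt <- wt_base[[cell$age]] + sexf + 1.4 * size + rnorm(n, sd = 0.8)
    fl <- fl_base[[cell$age]] + 0.1 * sexf + 0.25 * size + rnorm(n, sd = 0.15)
    rec <- data.frame(
      animal_id = sprintf("A%05d", idx + seq_len(n)),
      model = cell$model, genotype = cell$genotype, sex = cell$sex,
      age = cell$age,
      dyrk1a_copies = if (cell$genotype == "trisomic") "3" else "2",
      treatment = cell$treatment,
      body_weight = round(wt, 2), femur_length = round(fl, 2),
      stringsAsFactors = FALSE)
    out[[i]] <- cbind(rec, as.data.frame(panel))
    idx <- idx + n
  }
  cohort <- do.call(rbind, out)
  rownames(cohort) <- NULL
  if (config$missing_frac > 0) {
    vars <- panel_variables()
    m <- as.matrix(cohort[vars])
    holes <- runif(length(m)) < config$missing_frac
    m[holes] <- NA_real_
    cohort[vars] <- m
  }
  cohort
}

#' Read or write a cohort CSV
#'
#' One row per animal; factor columns then the 15 panel variables under the
#' exact headers `BMD, BVTV, Tb.Th, Tb.Sp, Tb.N, Tt.Ar, Ma.Ar, Ct.Ar,
#' Ct.Ar_Tt.Ar, Ct.Th, Ps.Pm, Ec.Pm, Imax, Imin, Ct.TMD`.
#'
#' @param cohort a cohort data.frame.
#' @param path file path.
#' @return `read_cohort()` returns the cohort data.frame;
#'   `write_cohort()` returns `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  x <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  miss <- setdiff(c("animal_id"), names(x))
  if (length(miss)) stop_input("cohort CSV misses column(s): %s",
                               paste(miss, collapse = ", "))
  x
}

#' Generate a synthetic three-point-bend force-displacement curve
#'
#' Produces a piecewise-linear curve: an optional compliance toe below the
#' 0.2 N preload, an elastic segment of the given stiffness, a post-yield
#' segment of the given slope, and a sharp drop at the failure displacement.
#' Gaussian noise of SD `noise_sd` is added to force. The generating
#' parameter values are attached as the `truth` attribute for recovery
#' studies.
#'
#' @param stiffness elastic slope, N/mm.
#' @param yield_force force at the elastic/post-yield break, N.
#' @param postyield_slope slope beyond yield, N/mm; must be < `stiffness`.
#' @param failure_displacement displacement at fracture, micrometers
#'   (measured from the preload zero).
#' @param noise_sd Gaussian force noise SD, N.
#' @param toe if `TRUE`, prepend a quadratic toe rising to the 0.2 N
#'   preload.
#' @param step_um displacement sampling increment, micrometers.
#' @param seed optional seed for the noise.
#' @return A data.frame of class `bend_curve` with columns
#'   `displacement_um`, `force_n` and attribute `truth`.
#' @export
generate_bend_curve <- function(stiffness, yield_force, postyield_slope = 0,
                                failure_displacement = 800, noise_sd = 0,
                                toe = FALSE, step_um = 2, seed = NULL) {
  if (stiffness <= 0) stop_input("stiffness must be > 0")
  if (postyield_slope >= stiffness) {
    stop_input("postyield_slope must be smaller than stiffness (no detectable yield)")
  }
  preload <- 0.2
  d_yield <- (yield_force - preload) / stiffness * 1000  # um past preload zero
  if (d_yield <= 0) stop_input("yield force must exceed the preload")
  if (failure_displacement <= d_yield) {
    stop_input("failure_displacement must lie beyond the yield displacement")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))

  d <- seq(0, failure_displacement, by = step_um)
  f <- ifelse(d <= d_yield,
              preload + stiffness * d / 1000,
              yield_force + postyield_slope * (d - d_yield) / 1000)
  ultimate <- f[length(f)]
  # post-failure cliff so failure detection has samples to see
  d_post <- failure_displacement + step_um * seq_len(3)
  f_post <- c(0.05, 0.02, 0.01) * ultimate
  d <- c(d, d_post); f <- c(f, f_post)

  if (toe) {
    d_toe <- seq(-60, -step_um, by = step_um)
    f_toe <- preload * ((d_toe + 60) / 60)^2
    d <- c(d_toe, d) + 60
    f <- c(f_toe, f)
  }
  if (noise_sd > 0) f <- f + rnorm(length(f), sd = noise_sd)

  curve <- data.frame(displacement_um = d, force_n = f)
  attr(curve, "truth") <- list(
    stiffness = stiffness, yield_force = yield_force,
    postyield_slope = postyield_slope,
    failure_displacement = failure_displacement,
    ultimate_force = max(yield_force, ultimate), preload = preload)
  class(curve) <- c("bend_curve", "data.frame")
  curve
}

#' Generate a binary annulus cross-section mask
#'
#' A pixel belongs to the cortex if and only if its center lies between the
#' inner and outer circles. The grid is padded at least two pixels beyond
#' the outer circle.
#'
#' @param outer_radius,inner_radius radii in mm; `inner_radius = 0` gives a
#'   solid disc.
#' @param pixel_size_um pixel edge length, micrometers.
#' @param center_offset length-2 integer offset of the circle center, in
#'   pixels.
#' @return A `cross_section_mask` (see [cross_section_mask()]).
#' @export
generate_annulus_mask <- function(outer_radius, inner_radius = 0,
                                  pixel_size_um = 10,
                                  center_offset = c(0, 0)) {
  if (pixel_size_um <= 0) stop_input("pixel_size_um must be > 0")
  if (outer_radius <= inner_radius || inner_radius < 0) {
    stop_input("need outer_radius > inner_radius >= 0")
  }
  px_mm <- pixel_size_um / 1000
  r_out <- outer_radius / px_mm
  if (r_out < 1 || (inner_radius > 0 && inner_radius / px_mm < 1)) {
    stop_input("radii must be at least one pixel")
  }
  pad <- 3
  half <- ceiling(r_out + pad + max(abs(center_offset)))
  n <- 2L * half + 1L
  cx <- half + 1 + center_offset[1]
  cy <- half + 1 + center_offset[2]
  xx <- matrix(rep(seq_len(n), each = n), n)   # column index = x
  yy <- matrix(rep(seq_len(n), times = n), n)  # row index = y
  rr2 <- (xx - cx)^2 + (yy - cy)^2
  grid <- rr2 <= r_out^2
  if (inner_radius > 0) grid <- grid & rr2 > (inner_radius / px_mm)^2
  cross_section_mask(grid, pixel_size_um = pixel_size_um)
}
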