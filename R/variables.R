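#' Bone variable panels
#'
#' Canonical variable names (CSV headers) for the two bone compartments, in
#' the order used throughout the package.
#'
#' Trabecular panel: `BMD` (g/cm^3), `BVTV` (bone volume fraction, %),
#' `Tb.Th` (mm), `Tb.Sp` (mm), `Tb.N` (1/mm). Trabecular separation is
#' expected to be inversely correlated with the other four variables, which
#' drives the sign convention of the composite score.
#'
#' Cortical panel (full): `Tt.Ar`, `Ma.Ar`, `Ct.Ar` (mm^2), `Ct.Ar_Tt.Ar`
#' (%), `Ct.Th` (mm), `Ps.Pm`, `Ec.Pm` (mm), `Imax`, `Imin` (mm^4),
#' `Ct.TMD` (g/cm^3). The cortical composite score uses the seven-variable
#' subset returned by `cortical_variables(composite = TRUE)` (areas,
#' thickness, perimeters and tissue mineral density).
#'
#' @param composite logical; if `TRUE`, return only the variables entering
#'   the cortical composite score.
#' @return Character vector of variable names.
#' @export
trabecular_variables <- function() {
  c("BMD", "BVTV", "Tb.Th", "Tb.Sp", "Tb.N")
}

#' @rdname trabecular_variables
#' @export
cortical_variables <- function(composite = FALSE) {
  if (composite) {
    c("Tt.Ar", "Ma.Ar", "Ct.Ar", "Ct.Th", "Ps.Pm", "Ec.Pm", "Ct.TMD")
  } else {
    c("Tt.Ar", "Ma.Ar", "Ct.Ar", "Ct.Ar_Tt.Ar", "Ct.Th", "Ps.Pm", "Ec.Pm",
      "Imax", "Imin", "Ct.TMD")
  }
}

#' @rdname trabecular_variables
#' @export
panel_variables <- function() {
  c(trabecular_variables(), cortical_variables())
}

# factor columns of a cohort table, in canonical order
cohort_factor_columns <- function() {
  c("animal_id", "model", "genotype", "sex", "age", "dyrk1a_copies",
    "treatment")
}

# declared level sets for cohort factors
cohort_factor_levels <- function() {
  list(
    model = c("Ts65Dn", "Ts66Yah"),
    genotype = c("euploid", "trisomic"),
    sex = c("M", "F"),
    age = c("P36", "6wk", "9wk", "16wk"),
    dyrk1a_copies = c("1", "2", "3"),
    treatment = c("none", "vehicle", "L21")
  )
}

compartment_variables <- function(compartment) {
  switch(match.arg(compartment, c("trabecular", "cortical")),
    trabecular = trabecular_variables(),
    cortical = cortical_variables(composite = TRUE)
  )
}

stop_input <- function(...) {
  stop(sprintf(...), call. = FALSE)
}
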