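#' Validate bone variable panels
#'
#' Screens a cohort table for structural problems before standardization:
#' duplicate animal ids, non-finite values, negative values in quantities
#' that must be non-negative, cortical area exceeding total area, and
#' missing panel cells. Rows violating hard invariants are excluded; rows
#' with missing cells in a compartment are flagged for exclusion from that
#' compartment's standardization and PCA (complete-case per compartment).
#'
#' @param table cohort data.frame (see [read_cohort()]).
#' @param variables panel variables to check; defaults to all present.
#' @return A list with `data` (cleaned table), `exclusions` (data.frame of
#'   `animal_id`, `reason`), and `incomplete` (data.frame of `animal_id`,
#'   `compartment` for compartment-level drops).
#' @export
validate_panels <- function(table, variables = NULL) {
  if (is.null(table) || !nrow(table)) stop_input("empty cohort table")
  if (is.null(variables)) variables <- intersect(panel_variables(), names(table))
  excl <- data.frame(animal_id = character(), reason = character(),
                     stringsAsFactors = FALSE)
  add_excl <- function(ids, reason) {
    if (length(ids)) {
      excl <<- rbind(excl, data.frame(animal_id = ids, reason = reason,
                                      stringsAsFactors = FALSE))
    }
  }
  dup <- table$animal_id[duplicated(table$animal_id)]
  add_excl(unique(dup), "duplicate animal_id")

  m <- as.matrix(table[variables])
  bad_inf <- rowSums(!is.finite(m) & !is.na(m)) > 0
  add_excl(table$animal_id[bad_inf], "non-finite value")

  nonneg <- setdiff(variables, character())  # all panel variables are non-negative
  bad_neg <- rowSums(m[, intersect(nonneg, colnames(m)), drop = FALSE] < 0,
                     na.rm = TRUE) > 0
  add_excl(table$animal_id[bad_neg], "negative value")

  if (all(c("Ct.Ar", "Tt.Ar") %in% variables)) {
    bad_area <- !is.na(table$Ct.Ar) & !is.na(table$Tt.Ar) &
      table$Ct.Ar > table$Tt.Ar
    add_excl(table$animal_id[bad_area], "Ct.Ar exceeds Tt.Ar")
  }

  keep <- !(table$animal_id %in% excl$animal_id) & !duplicated(table$animal_id)
  clean <- table[keep, , drop = FALSE]

  incomplete <- data.frame(animal_id = character(), compartment = character(),
                           stringsAsFactors = FALSE)
  for (comp in c("trabecular", "cortical")) {
    vars <- intersect(compartment_variables(comp), variables)
    if (!length(vars)) next
    holes <- !complete.cases(clean[vars])
    if (any(holes)) {
      incomplete <- rbind(incomplete, data.frame(
        animal_id = clean$animal_id[holes], compartment = comp,
        stringsAsFactors = FALSE))
    }
  }
  list(data = clean, exclusions = excl, incomplete = incomplete)
}

#' Standardize bone variables within mouse model
#'
#' Converts each variable to a z-score using the mean and SD of all animals
#' of the same stratum, by default (model, sex, age). Both genotypes of a
#' model are pooled within a stratum, so model-specific background strain
#' and scanner offsets are removed while genotype contrasts are preserved.
#' The SD uses the sample (n - 1) denominator. Animals missing any of
#' `variables` are dropped (complete-case).
#'
#' @param table cohort data.frame.
#' @param variables variables to standardize.
#' @param stratify_by factor columns defining the strata.
#' @return A data.frame with the non-panel columns of `table` plus the
#'   standardized `variables`; attribute `provenance` records per-stratum
#'   `n`, `mean` and `sd` per variable.
#' @export
standardize_within_model <- function(table,
                                     variables = trabecular_variables(),
                                     stratify_by = c("model", "sex", "age")) {
  miss <- setdiff(c(variables, stratify_by), names(table))
  if (length(miss)) stop_input("missing column(s): %s",
                               paste(miss, collapse = ", "))
  keep <- complete.cases(table[variables])
  table <- table[keep, , drop = FALSE]
  if (!nrow(table)) stop_input("no complete rows to standardize")

  stratum <- interaction(table[stratify_by], drop = TRUE, sep = "/")
  prov <- list()
  out <- table
  for (s in levels(stratum)) {
    rows <- which(stratum == s)
    if (length(rows) < 2) {
      stop_input("stratum %s has n = %d (< 2)", s, length(rows))
    }
    for (v in variables) {
      x <- table[[v]][rows]
      mu <- mean(x)
      sdev <- sd(x)
      if (sdev == 0) {
        stop_input("stratum %s has zero SD for variable %s", s, v)
      }
      out[[v]][rows] <- (x - mu) / sdev
      prov[[length(prov) + 1L]] <- data.frame(
        stratum = s, variable = v, n = length(rows), mean = mu, sd = sdev,
        stringsAsFactors = FALSE)
    }
  }
  attr(out, "provenance") <- do.call(rbind, prov)
  attr(out, "standardized_variables") <- variables
  out
}

#' Write the standardization provenance table
#'
#' @param standardized output of [standardize_within_model()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_standardization_provenance <- function(standardized, path) {
  prov <- attr(standardized, "provenance")
  if (is.null(prov)) stop_input("no provenance attribute found")
  write.csv(prov, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
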