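#' Build a pipeline configuration
#'
#' Declarative configuration for [run_pipeline()]. Unknown keys are
#' errors, not warnings.
#'
#' @param cohort either `list(source = "synthetic", config = <cohort_config>)`
#'   or `list(source = "csv", path = <file>)`.
#' @param compartments compartments to score.
#' @param design right-hand-side factors of the factorial comparison on
#'   the composite scores, e.g. `c("model", "genotype")`.
#' @param stratify_scores factor(s) defining separate PCA strata (the
#'   composite scorer is refit per stratum, never reused across them);
#'   default per sex.
#' @param anchors orientation anchor per compartment.
#' @param standardize_by strata for within-model standardization.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort,
                            compartments = c("trabecular", "cortical"),
                            design = c("model", "genotype"),
                            stratify_scores = "sex",
                            anchors = list(trabecular = "BVTV",
                                           cortical = "Ct.Ar"),
                            standardize_by = c("model", "sex", "age")) {
  if (!is.list(cohort) || is.null(cohort$source)) {
    stop_input("cohort must be a list with a `source` key")
  }
  if (!cohort$source %in% c("synthetic", "csv")) {
    stop_input("cohort source must be 'synthetic' or 'csv'")
  }
  extra <- setdiff(names(cohort), c("source", "config", "path"))
  if (length(extra)) stop_input("unknown cohort key(s): %s",
                                paste(extra, collapse = ", "))
  compartments <- match.arg(compartments, c("trabecular", "cortical"),
                            several.ok = TRUE)
  structure(list(cohort = cohort, compartments = compartments,
                 design = design, stratify_scores = stratify_scores,
                 anchors = anchors, standardize_by = standardize_by),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path config file path (`.yaml`/`.yml`/`.json`).
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop_input("unsupported config format: .%s", ext))
  known <- c("cohort", "compartments", "design", "stratify_scores",
             "anchors", "standardize_by")
  extra <- setdiff(names(raw), known)
  if (length(extra)) stop_input("unknown config key(s): %s",
                                paste(extra, collapse = ", "))
  if (identical(raw$cohort$source, "synthetic")) {
    cc <- raw$cohort$config
    raw$cohort$config <- do.call(cohort_config, if (is.null(cc)) list() else cc)
  }
  do.call(pipeline_config, raw)
}

#' Run the composite-score pipeline
#'
#' Executes the stages in order: simulate or ingest the cohort, validate
#' panels, standardize within model, fit the PC1 composite scorer per
#' score stratum and compartment, score every complete animal, run the
#' factorial ANOVA on the scores, and persist all intermediate tables
#' together with a run manifest.
#'
#' @param config a [pipeline_config()] or path to a YAML/JSON config.
#' @param seed integer seed used for the synthetic cohort source.
#' @param out_dir output directory (created if absent).
#' @return Invisibly, a list with the scores table, ANOVA tables, fitted
#'   scorers and the manifest.
#' @export
run_pipeline <- function(config, seed = 1L, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config")) {
    stop_input("config must be a pipeline_config or a path")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage_log <- list()
  log_stage <- function(name, rows, note = "") {
    stage_log[[length(stage_log) + 1L]] <<- list(stage = name, rows = rows,
                                                 note = note)
  }

  # stage: cohort
  if (config$cohort$source == "synthetic") {
    cohort <- generate_cohort(config$cohort$config, seed = seed)
  } else {
    cohort <- read_cohort(config$cohort$path)
  }
  write_cohort(cohort, file.path(out_dir, "cohort.csv"))
  log_stage("cohort", nrow(cohort))

  # stage: validate (compartment-incomplete animals go to the log too, so
  # every input animal is accounted for in scores or exclusions)
  val <- validate_panels(cohort)
  excl <- val$exclusions
  inc <- val$incomplete[val$incomplete$compartment %in% config$compartments, ,
                        drop = FALSE]
  if (nrow(inc)) {
    excl <- rbind(excl, data.frame(
      animal_id = inc$animal_id,
      reason = sprintf("incomplete %s panel", inc$compartment),
      stringsAsFactors = FALSE))
  }
  write.csv(excl, file.path(out_dir, "exclusions.csv"), row.names = FALSE)
  log_stage("validate", nrow(val$data), sprintf("%d excluded", nrow(excl)))

  scores_all <- list()
  anova_rows <- list()
  loadings_rows <- list()
  models <- list()
  for (comp in config$compartments) {
    vars <- compartment_variables(comp)
    dropped <- val$incomplete$animal_id[val$incomplete$compartment == comp]
    dat <- val$data[!val$data$animal_id %in% dropped, , drop = FALSE]
    z <- standardize_within_model(dat, variables = vars,
                                  stratify_by = config$standardize_by)
    write_standardization_provenance(
      z, file.path(out_dir, sprintf("standardization_%s.csv", comp)))
    log_stage(sprintf("standardize_%s", comp), nrow(z))

    stratum <- if (length(config$stratify_scores)) {
      interaction(z[config$stratify_scores], drop = TRUE, sep = "/")
    } else {
      factor(rep("all", nrow(z)))
    }
    for (s in levels(stratum)) {
      zs <- z[stratum == s, , drop = FALSE]
      fit <- pc_composite(zs, variables = vars,
                          anchor = config$anchors[[comp]])
      models[[paste(comp, s, sep = "/")]] <- fit
      loadings_rows[[length(loadings_rows) + 1L]] <- data.frame(
        compartment = comp, stratum = s, variable = fit$variables,
        loading = unname(fit$loadings),
        variance_explained_pc1 = fit$variance_explained[1],
        anchor = fit$anchor, n = fit$n, stringsAsFactors = FALSE)
      sc <- predict(fit, zs)
      scores_all[[length(scores_all) + 1L]] <- data.frame(
        zs[intersect(cohort_factor_columns(), names(zs))],
        compartment = comp, stratum = s, score = unname(sc),
        stringsAsFactors = FALSE)

      form <- stats::as.formula(paste("score ~",
                                      paste(config$design, collapse = "*")))
      an <- factorial_anova(form, data = scores_all[[length(scores_all)]])
      tab <- an$table
      tab <- cbind(analysis = sprintf("%s composite, %s", comp, s), tab)
      anova_rows[[length(anova_rows) + 1L]] <- tab
    }
    log_stage(sprintf("composite_%s", comp), length(levels(stratum)),
              "one PCA per stratum")
  }
  scores <- do.call(rbind, scores_all)
  anova_tab <- do.call(rbind, anova_rows)
  loadings_tab <- do.call(rbind, loadings_rows)
  write.csv(scores, file.path(out_dir, "scores.csv"), row.names = FALSE)
  write.csv(anova_tab, file.path(out_dir, "anova.csv"), row.names = FALSE)
  write.csv(loadings_tab, file.path(out_dir, "loadings.csv"),
            row.names = FALSE)
  log_stage("stats", nrow(anova_tab))

  manifest <- list(
    seed = seed,
    timestamp = format(Sys.time(), tz = "UTC"),
    package_version = as.character(utils::packageVersion("bonescore")),
    stages = stage_log,
    files = as.list(tools::md5sum(list.files(out_dir, pattern = "\\.csv$",
                                             full.names = TRUE))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(scores = scores, anova = anova_tab,
                 loadings = loadings_tab, models = models,
                 manifest = manifest, out_dir = out_dir))
}

#' Render a text report from pipeline outputs
#'
#' Summarizes loadings, variance explained, orientation anchors, ANOVA
#' tables and the exclusion log into a single human-readable file.
#'
#' @param out_dir directory written by [run_pipeline()].
#' @param path report path; defaults to `report.txt` inside `out_dir`.
#' @return `path`, invisibly.
#' @export
render_report <- function(out_dir, path = file.path(out_dir, "report.txt")) {
  need <- file.path(out_dir, c("loadings.csv", "anova.csv", "exclusions.csv"))
  missing_files <- need[!file.exists(need)]
  if (length(missing_files)) {
    stop_input("missing pipeline output(s): %s",
               paste(basename(missing_files), collapse = ", "))
  }
  loadings <- read.csv(file.path(out_dir, "loadings.csv"))
  anova_tab <- read.csv(file.path(out_dir, "anova.csv"))
  excl <- read.csv(file.path(out_dir, "exclusions.csv"))

  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("Composite bone score report")
  w("===========================")
  w("")
  for (key in unique(paste(loadings$compartment, loadings$stratum, sep = "/"))) {
    sub <- loadings[paste(loadings$compartment, loadings$stratum,
                          sep = "/") == key, ]
    w("PCA stratum %s (n = %d): PC1 variance explained = %.2f%%, anchor = %s",
      key, sub$n[1], 100 * sub$variance_explained_pc1[1], sub$anchor[1])
    for (i in seq_len(nrow(sub))) {
      w("  %-12s loading %+0.4f", sub$variable[i], sub$loading[i])
    }
  }
  w("")
  w("Factorial ANOVA (Type III) on composite scores")
  for (an in unique(anova_tab$analysis)) {
    sub <- anova_tab[anova_tab$analysis == an, ]
    w("- %s", an)
    for (i in seq_len(nrow(sub))) {
      if (sub$term[i] == "Residuals") {
        w("    Residuals: df = %d, SS = %.4f", sub$df[i], sub$sum_sq[i])
      } else {
        w("    %-24s F(%d, %d) = %8.4f, p = %.4g", sub$term[i], sub$df[i],
          sub$df[nrow(sub)], sub$F[i], sub$p[i])
      }
    }
  }
  w("")
  if (nrow(excl)) {
    w("Excluded animals:")
    for (i in seq_len(nrow(excl))) w("  %s: %s", excl$animal_id[i],
                                     excl$reason[i])
  } else {
    w("Excluded animals: none")
  }
  invisible(path)
}
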