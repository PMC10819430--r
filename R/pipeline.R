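#' Run the full binding-analysis pipeline
#'
#' Orchestrates the stages end to end: titration spectra -> Stern-Volmer
#' quenching and mechanism classification -> double-logarithmic binding
#' constants -> Van't Hoff thermodynamics and force classification ->
#' probe competition and site assignment -> MM/GBSA validation and
#' affinity ranking -> metric correlation. Stages whose inputs are absent
#' from the configuration are skipped (with a message); a failing stage
#' aborts with the stage named.
#'
#' @param config Path to a YAML configuration file, or an equivalent
#'   named list. Recognised keys:
#' \describe{
#'   \item{titration_csv}{path(s) to long-format titration CSVs
#'     (see [read_titration_csv()]); drives the quenching, affinity and
#'     thermodynamics stages.}
#'   \item{competition_csv}{CSV with `system`, `probe`, `kb_free`,
#'     `kb_probe`; drives displacement and site assignment.}
#'   \item{gbsa_csv}{CSV for [read_gbsa_table()]; drives validation and
#'     ranking.}
#'   \item{metrics_csv}{CSV with a `compound` column plus numeric metric
#'     columns; drives [pearson_matrix()].}
#'   \item{tau0_s, kq_limit, near_zero_kj_mol, dominance_pct, policy,
#'     reference_nm, site_map, seed}{analysis parameters with the
#'     defaults documented on the stage functions.}
#' }
#' @param out_dir If given, stage outputs are written there as CSVs plus
#'   a combined `report.json`; re-running on identical inputs yields
#'   byte-identical files.
#' @return A list of class `analysis_report` with elements `sv`,
#'   `mechanism`, `binding`, `thermo`, `competition`, `site_assignment`,
#'   `gbsa`, `ranking`, `correlation` (absent stages are `NULL`).
#' @export
run_full_analysis <- function(config, out_dir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) abort_config(paste0("config file not found: ", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort_config("config must be a YAML file path or a named list")
  allowed <- c("titration_csv", "competition_csv", "gbsa_csv", "metrics_csv",
               "tau0_s", "kq_limit", "near_zero_kj_mol", "dominance_pct",
               "policy", "reference_nm", "site_map", "seed")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown) > 0) {
    abort_config(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  tau0_s <- config$tau0_s %||% 1e-8
  kq_limit <- config$kq_limit %||% 2.0e10
  near_zero <- config$near_zero_kj_mol %||% 10
  dominance <- config$dominance_pct %||% 80
  policy <- config$policy %||% "fixed_reference"
  reference_nm <- config$reference_nm
  site_map <- if (is.null(config$site_map)) default_site_map()
    else unlist(config$site_map)

  report <- list(sv = NULL, mechanism = NULL, binding = NULL, thermo = NULL,
                 competition = NULL, site_assignment = NULL, gbsa = NULL,
                 ranking = NULL, correlation = NULL)

  run_stage <- function(stage, code) {
    tryCatch(code, error = function(e) {
      abort(paste0("stage '", stage, "' failed: ", conditionMessage(e)),
            class = "quenchbind_stage_error", parent = e)
    })
  }

  if (!is.null(config$titration_csv)) {
    titr <- run_stage("spectra", {
      purrr::map(config$titration_csv, read_titration_csv) |> purrr::list_rbind() |>
        as_titration()
    })
    report$sv <- run_stage("quenching",
      sv_table(titr, tau0_s = tau0_s, policy = policy, reference_nm = reference_nm))
    report$mechanism <- run_stage("quenching",
      classify_mechanism(report$sv, kq_limit = kq_limit))
    report$binding <- run_stage("affinity",
      binding_table(titr, policy = policy, reference_nm = reference_nm))
    if (dplyr::n_distinct(report$binding$temperature_K) >= 2) {
      report$thermo <- run_stage("thermo",
        thermo_table(report$binding[, c("temperature_K", "kb")],
                     near_zero_kj_mol = near_zero))
    } else {
      message("thermo stage skipped: fewer than 2 temperatures")
    }
  } else {
    message("spectra/quenching/affinity/thermo stages skipped: no titration_csv")
  }

  if (!is.null(config$competition_csv)) {
    comp <- run_stage("competition",
      competition_table(readr::read_csv(config$competition_csv, comment = "#",
                                        show_col_types = FALSE, progress = FALSE)))
    report$competition <- comp
    report$site_assignment <- run_stage("competition",
      assign_binding_site(comp, site_map = site_map, dominance_pct = dominance))
  } else {
    message("competition stage skipped: no competition_csv")
  }

  if (!is.null(config$gbsa_csv)) {
    report$gbsa <- run_stage("energetics", read_gbsa_table(config$gbsa_csv))
    report$ranking <- run_stage("energetics", rank_by_affinity(report$gbsa))
  } else {
    message("energetics stage skipped: no gbsa_csv")
  }

  if (!is.null(config$metrics_csv)) {
    report$correlation <- run_stage("correlation",
      pearson_matrix(readr::read_csv(config$metrics_csv, comment = "#",
                                     show_col_types = FALSE, progress = FALSE)))
  } else {
    message("correlation stage skipped: no metrics_csv")
  }

  class(report) <- "analysis_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("quenchbind analysis report\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    status <- if (is.null(v)) "skipped"
      else if (inherits(v, "pearson_matrix")) sprintf("%d compounds", v$n_compounds)
      else sprintf("%d row(s)", nrow(v))
    cat(sprintf("  %-16s %s\n", nm, status))
  }
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  emit <- function(df, name) {
    if (!is.null(df)) readr::write_csv(df, file.path(out_dir, paste0(name, ".csv")),
                                       progress = FALSE)
  }
  emit(report$sv, "stern_volmer")
  emit(report$mechanism, "mechanism")
  emit(report$binding, "binding")
  if (!is.null(report$thermo)) {
    emit(tidyr::unnest(report$thermo, "delta_g"), "thermo")
  }
  emit(report$competition, "competition")
  emit(report$site_assignment, "site_assignment")
  emit(report$gbsa, "gbsa")
  emit(report$ranking, "ranking")
  if (!is.null(report$correlation)) {
    emit(tidy(report$correlation), "correlation")
  }
  json <- purrr::map(unclass(report), function(v) {
    if (is.null(v)) return(NULL)
    if (inherits(v, "pearson_matrix")) return(tidy(v))
    if ("delta_g" %in% names(v)) return(tidyr::unnest(v, "delta_g"))
    v
  })
  jsonlite::write_json(json[!vapply(json, is.null, logical(1))],
                       file.path(out_dir, "report.json"),
                       dataframe = "rows", digits = NA, pretty = TRUE)
  invisible(out_dir)
}
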