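#' Double-logarithmic binding fit
#'
#' Estimates the binding constant Kb and the apparent number of binding
#' sites n from the double-logarithmic (modified Stern-Volmer) relation
#' `log10((F0 - F)/F) = log10(Kb) + n log10([Q])`, fitted by ordinary
#' least squares over the nonzero ligand concentrations. The
#' concentration used is the total added ligand, the convention of the
#' underlying relation (free-ligand depletion is not modelled). The
#' zero-concentration point only supplies F0; points where F has not
#' dropped below F0 are an error rather than being clipped, since they
#' indicate absent quenching.
#'
#' @inheritParams stern_volmer_fit
#' @return Object of class `binding_fit`: `temperature_K`, `kb` (L/mol),
#'   `n_sites`, `kb_stderr_log10` (standard error of the log10 intercept),
#'   `n_stderr`, `r_squared`, plus `data` and `model`. [tidy()] and
#'   [glance()] methods are provided.
#' @export
#' @examples
#' s <- simulate_titration(sim_config(kb = 1e5, noise_sd_rel = 0), 298)
#' glance(double_log_fit(s))
double_log_fit <- function(series,
                           policy = c("fixed_reference", "per_spectrum_max"),
                           reference_nm = NULL) {
  policy <- match.arg(policy)
  fs <- series_intensities(series, policy = policy, reference_nm = reference_nm)
  if (dplyr::n_distinct(fs$series_id, fs$temperature_K) > 1) {
    abort_validation("double_log_fit expects a single series; see binding_table() for many")
  }
  double_log_fit_points(fs$ligand_conc_M, fs$f, temperature_K = fs$temperature_K[1],
                        series_id = fs$series_id[1])
}

double_log_fit_points <- function(conc, f, temperature_K, series_id = NA_character_) {
  if (!any(conc == 0)) abort_validation("double-log fit needs the zero-ligand (F0) point")
  f0 <- f[conc == 0][1]
  nz <- conc > 0
  if (sum(nz) < 3) abort_validation("double-log fit needs at least 3 nonzero-concentration points")
  if (any(f[nz] >= f0)) {
    bad <- conc[nz][f[nz] >= f0][1]
    abort_domain(sprintf("no quenching at concentration %g mol/L (F >= F0)", bad))
  }
  fnz <- f[nz]
  d <- tibble(ligand_conc_M = conc[nz], f = fnz,
              log_q = log10(conc[nz]), log_ff = log10((f0 - fnz) / fnz))
  model <- lm(log_ff ~ log_q, data = d)
  sm <- suppressWarnings(summary(model))
  r2 <- if (stats::var(d$log_ff) < 1e-30) 1 else sm$r.squared
  structure(list(series_id = series_id, temperature_K = temperature_K,
                 kb = unname(10^coef(model)[1]),
                 n_sites = unname(coef(model)[2]),
                 kb_stderr_log10 = unname(sm$coefficients[1, 2]),
                 n_stderr = unname(sm$coefficients[2, 2]),
                 r_squared = r2, f0 = f0, data = d, model = model),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("Double-logarithmic binding fit (%s, %g K)\n", x$series_id, x$temperature_K))
  cat(sprintf("  Kb = %.4g L/mol   n = %.3f +/- %.3f   r^2 = %.4f\n",
              x$kb, x$n_sites, x$n_stderr, x$r_squared))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.binding_fit <- function(x, ...) {
  sm <- summary(x$model)$coefficients
  tibble(term = c("log10_kb", "n_sites"), estimate = unname(sm[, 1]),
         std.error = unname(sm[, 2]))
}

#' @exportS3Method generics::glance
glance.binding_fit <- function(x, ...) {
  tibble(series_id = x$series_id, temperature_K = x$temperature_K,
         kb = x$kb, n_sites = x$n_sites, kb_stderr_log10 = x$kb_stderr_log10,
         n_stderr = x$n_stderr, r_squared = x$r_squared)
}

#' Binding fits for every series of a titration table
#'
#' @inheritParams double_log_fit
#' @param titr Titration table with one or more series.
#' @return One [glance()] row per (series, temperature), ordered by
#'   temperature; feed the `temperature_K`/`kb` columns to
#'   [vant_hoff_fit()].
#' @export
binding_table <- function(titr,
                          policy = c("fixed_reference", "per_spectrum_max"),
                          reference_nm = NULL) {
  policy <- match.arg(policy)
  fs <- series_intensities(titr, policy = policy, reference_nm = reference_nm)
  fs |>
    dplyr::group_by(.data$series_id, .data$temperature_K) |>
    dplyr::group_split() |>
    purrr::map(function(d) glance(double_log_fit_points(d$ligand_conc_M, d$f,
                                                        temperature_K = d$temperature_K[1],
                                                        series_id = d$series_id[1]))) |>
    purrr::list_rbind() |>
    dplyr::arrange(.data$temperature_K)
}
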