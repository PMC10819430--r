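#' Stern-Volmer quenching fit
#'
#' Fits the Stern-Volmer law `F0/F = 1 + Ksv [Q]` by ordinary least
#' squares. The ligand-free point enters the regression as the (0, 1)
#' anchor, since the law forces the intercept toward one. The bimolecular
#' quenching rate constant is `Kq = Ksv / tau0`, with the unquenched
#' fluorophore lifetime `tau0` defaulting to 1e-8 s.
#'
#' @param series A titration table containing exactly one series (one
#'   temperature); see [as_titration()].
#' @param tau0_s Unquenched fluorescence lifetime (s).
#' @param policy,reference_nm Intensity extraction policy passed to
#'   [series_intensities()].
#' @return An object of class `sv_fit` with elements `temperature_K`,
#'   `ksv` (L/mol), `ksv_stderr`, `kq` (L/mol/s), `intercept`,
#'   `r_squared`, `n_points`, the underlying `data` and `model`.
#'   [tidy()] gives per-term coefficients, [glance()] a one-row summary.
#' @export
#' @examples
#' s <- simulate_titration(sim_config(mode = "stern_volmer", ksv = 2.5e4,
#'                                    noise_sd_rel = 0), 298)
#' glance(stern_volmer_fit(s))
stern_volmer_fit <- function(series, tau0_s = 1e-8,
                             policy = c("fixed_reference", "per_spectrum_max"),
                             reference_nm = NULL) {
  policy <- match.arg(policy)
  fs <- series_intensities(series, policy = policy, reference_nm = reference_nm)
  if (dplyr::n_distinct(fs$series_id, fs$temperature_K) > 1) {
    abort_validation("stern_volmer_fit expects a single series; see sv_table() for many")
  }
  sv_fit_points(fs$ligand_conc_M, fs$f, temperature_K = fs$temperature_K[1],
                series_id = fs$series_id[1], tau0_s = tau0_s)
}

sv_fit_points <- function(conc, f, temperature_K, series_id = NA_character_,
                          tau0_s = 1e-8) {
  if (length(conc) < 3) abort_validation("Stern-Volmer fit needs at least 3 points")
  if (!any(conc == 0)) abort_validation("Stern-Volmer fit needs the zero-ligand (F0) point")
  if (any(f <= 0)) abort_domain("all intensities must be positive")
  f0 <- f[conc == 0][1]
  d <- tibble(ligand_conc_M = conc, f = f, ratio = f0 / f)
  model <- lm(ratio ~ ligand_conc_M, data = d)
  sm <- suppressWarnings(summary(model))
  r2 <- if (stats::var(d$ratio) < 1e-30) 1 else sm$r.squared
  ksv <- unname(coef(model)[2])
  structure(list(series_id = series_id, temperature_K = temperature_K,
                 ksv = ksv, ksv_stderr = unname(sm$coefficients[2, 2]),
                 kq = ksv / tau0_s, tau0_s = tau0_s,
                 intercept = unname(coef(model)[1]),
                 r_squared = r2, n_points = nrow(d), data = d, model = model),
            class = "sv_fit")
}

#' @export
print.sv_fit <- function(x, ...) {
  cat(sprintf("Stern-Volmer fit (%s, %g K)\n", x$series_id, x$temperature_K))
  cat(sprintf("  Ksv = %.4g +/- %.2g L/mol   Kq = %.4g L/mol/s (tau0 = %g s)\n",
              x$ksv, x$ksv_stderr, x$kq, x$tau0_s))
  cat(sprintf("  intercept = %.4f   r^2 = %.4f   n = %d\n",
              x$intercept, x$r_squared, x$n_points))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.sv_fit <- function(x, ...) {
  sm <- summary(x$model)$coefficients
  tibble(term = c("intercept", "ksv"), estimate = unname(sm[, 1]),
         std.error = unname(sm[, 2]))
}

#' @exportS3Method generics::glance
glance.sv_fit <- function(x, ...) {
  tibble(series_id = x$series_id, temperature_K = x$temperature_K,
         ksv = x$ksv, ksv_stderr = x$ksv_stderr, kq = x$kq,
         intercept = x$intercept, r_squared = x$r_squared,
         n_points = x$n_points)
}

#' Stern-Volmer fits for every series of a titration table
#'
#' @inheritParams stern_volmer_fit
#' @param titr Titration table with one or more series.
#' @return A tibble with one [glance()] row per (series, temperature).
#' @export
sv_table <- function(titr, tau0_s = 1e-8,
                     policy = c("fixed_reference", "per_spectrum_max"),
                     reference_nm = NULL) {
  policy <- match.arg(policy)
  fs <- series_intensities(titr, policy = policy, reference_nm = reference_nm)
  fs |>
    dplyr::group_by(.data$series_id, .data$temperature_K) |>
    dplyr::group_split() |>
    purrr::map(function(d) glance(sv_fit_points(d$ligand_conc_M, d$f,
                                                temperature_K = d$temperature_K[1],
                                                series_id = d$series_id[1],
                                                tau0_s = tau0_s))) |>
    purrr::list_rbind() |>
    dplyr::arrange(.data$temperature_K)
}

#' Classify the quenching mechanism from multi-temperature fits
#'
#' Static quenching (ground-state complex formation) weakens with
#' temperature, so a Ksv that falls as T rises indicates a static
#' mechanism. A rising Ksv indicates collisional (dynamic) quenching -
#' unless Kq exceeds the diffusion-controlled limit
#' (about 2e10 L/mol/s), which no purely collisional process can, in
#' which case the call is a mixed static/dynamic mechanism.
#'
#' Decision table on the temperature-ordered Ksv trend:
#' decreasing -> static; increasing with max(Kq) > `kq_limit` -> mixed;
#' increasing otherwise -> dynamic; flat or non-monotonic -> static if
#' max(Kq) > `kq_limit`, else indeterminate.
#'
#' @param fits Data frame with columns `temperature_K`, `ksv`, `kq` (such
#'   as [sv_table()] output), at least two distinct temperatures. A
#'   `system` column, if present, is classified group-wise.
#' @param kq_limit Diffusion-limited quenching rate constant (L/mol/s).
#' @param flat_tol Relative tolerance below which the Ksv trend counts as
#'   flat.
#' @return Tibble with columns `mechanism` (`static`, `dynamic`, `mixed`
#'   or `indeterminate`), `trend`, `kq_exceeds_diffusion_limit`,
#'   `evidence` (one row per system).
#' @export
#' @examples
#' fits <- tibble::tibble(temperature_K = c(298, 304, 310),
#'                        ksv = c(2.52e4, 2.35e4, 1.27e4))
#' fits$kq <- fits$ksv / 1e-8
#' classify_mechanism(fits)
classify_mechanism <- function(fits, kq_limit = 2.0e10, flat_tol = 1e-6) {
  required <- c("temperature_K", "ksv", "kq")
  missing <- setdiff(required, names(fits))
  if (length(missing) > 0) {
    abort_format(paste0("fits are missing column(s): ", paste(missing, collapse = ", ")))
  }
  if ("system" %in% names(fits)) {
    return(fits |>
             dplyr::group_by(.data$system) |>
             dplyr::group_split() |>
             purrr::map(function(d) {
               dplyr::bind_cols(tibble(system = d$system[1]),
                                classify_mechanism(d[setdiff(names(d), "system")],
                                                   kq_limit, flat_tol))
             }) |>
             purrr::list_rbind())
  }
  d <- dplyr::arrange(fits, .data$temperature_K)
  if (dplyr::n_distinct(d$temperature_K) < 2) {
    abort_validation("mechanism classification needs at least 2 distinct temperatures")
  }
  dk <- diff(d$ksv)
  scale <- max(abs(d$ksv))
  trend <- if (all(abs(dk) <= flat_tol * scale)) "flat"
    else if (all(dk < 0)) "decreasing"
    else if (all(dk > 0)) "increasing"
    else "non_monotonic"
  exceeds <- max(d$kq) > kq_limit
  mechanism <- switch(trend,
    decreasing = "static",
    increasing = if (exceeds) "mixed" else "dynamic",
    if (exceeds) "static" else "indeterminate")
  evidence <- sprintf(
    "Ksv %s over %g-%g K (%s L/mol); max Kq = %.3g L/mol/s %s diffusion limit %.2g",
    trend, min(d$temperature_K), max(d$temperature_K),
    paste(signif(d$ksv, 3), collapse = ", "),
    max(d$kq), if (exceeds) "exceeds" else "within", kq_limit)
  tibble(mechanism = mechanism, trend = trend,
         kq_exceeds_diffusion_limit = exceeds, evidence = evidence)
}
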