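#' Gibbs free energy of binding from the binding constant
#'
#' `dG = -R T ln(Kb)`, with R = 8.314 J/mol/K, reported in kJ/mol.
#'
#' @param kb Binding constant (L/mol), positive; vectorised.
#' @param temperature_K Temperature (K), positive; recycled against `kb`.
#' @return Gibbs energy change in kJ/mol (negative for Kb > 1).
#' @export
#' @examples
#' gibbs_from_kb(7.81e6, 298) # about -39.32 kJ/mol
gibbs_from_kb <- function(kb, temperature_K) {
  if (any(!is.finite(kb)) || any(kb <= 0)) abort_domain("kb must be positive and finite")
  if (any(!is.finite(temperature_K)) || any(temperature_K <= 0)) {
    abort_domain("temperature_K must be positive and finite")
  }
  -.R_GAS * temperature_K * log(kb) / 1000
}

#' Van't Hoff fit of binding enthalpy and entropy
#'
#' Ordinary least squares of `ln(Kb)` against `1/T` under the Van't Hoff
#' relation `ln Kb = -dH/(R T) + dS/R`, assuming a
#' temperature-independent enthalpy over the fitted range.
#'
#' @param data Data frame with columns `temperature_K` and `kb` (one row
#'   per temperature, at least two distinct temperatures, all `kb > 0`).
#' @return Object of class `vant_hoff_fit` with `delta_h_kj_mol`
#'   (= -R * slope / 1000), `delta_s_j_mol_k` (= R * intercept),
#'   `r_squared`, `data`, `model`. [tidy()]/[glance()] methods provided.
#' @export
#' @examples
#' vh <- vant_hoff_fit(tibble::tibble(temperature_K = c(298, 304, 310),
#'                                    kb = c(1.59e5, 4.55e4, 2.99e4)))
#' glance(vh)
vant_hoff_fit <- function(data) {
  missing <- setdiff(c("temperature_K", "kb"), names(data))
  if (length(missing) > 0) {
    abort_format(paste0("data is missing column(s): ", paste(missing, collapse = ", ")))
  }
  d <- dplyr::arrange(as_tibble(data), .data$temperature_K)
  if (dplyr::n_distinct(d$temperature_K) < 2) {
    abort_validation("Van't Hoff fit needs at least 2 distinct temperatures")
  }
  if (any(!is.finite(d$kb)) || any(d$kb <= 0)) abort_domain("all kb must be positive")
  d$inv_t <- 1 / d$temperature_K
  d$ln_kb <- log(d$kb)
  model <- lm(ln_kb ~ inv_t, data = d)
  sm <- suppressWarnings(summary(model))
  r2 <- if (stats::var(d$ln_kb) < 1e-30) 1 else sm$r.squared
  structure(list(delta_h_kj_mol = unname(-.R_GAS * coef(model)[2] / 1000),
                 delta_s_j_mol_k = unname(.R_GAS * coef(model)[1]),
                 delta_h_stderr_kj_mol = unname(.R_GAS * sm$coefficients[2, 2] / 1000),
                 delta_s_stderr_j_mol_k = unname(.R_GAS * sm$coefficients[1, 2]),
                 r_squared = r2, data = d, model = model),
            class = "vant_hoff_fit")
}

#' @export
print.vant_hoff_fit <- function(x, ...) {
  cat("Van't Hoff fit\n")
  cat(sprintf("  dH = %.2f kJ/mol   dS = %.1f J/mol/K   r^2 = %.4f   (n = %d)\n",
              x$delta_h_kj_mol, x$delta_s_j_mol_k, x$r_squared, nrow(x$data)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.vant_hoff_fit <- function(x, ...) {
  tibble(term = c("delta_h_kj_mol", "delta_s_j_mol_k"),
         estimate = c(x$delta_h_kj_mol, x$delta_s_j_mol_k),
         std.error = c(x$delta_h_stderr_kj_mol, x$delta_s_stderr_j_mol_k))
}

#' @exportS3Method generics::glance
glance.vant_hoff_fit <- function(x, ...) {
  tibble(delta_h_kj_mol = x$delta_h_kj_mol, delta_s_j_mol_k = x$delta_s_j_mol_k,
         r_squared = x$r_squared, n_temperatures = nrow(x$data))
}

#' Classify the dominant interaction force from (dH, dS) signs
#'
#' Ross-style sign rules for the dominant non-covalent force of a
#' protein-ligand association: both positive -> hydrophobic; both
#' negative -> hydrogen bonding / van der Waals; enthalpy near zero (or
#' negative) with positive entropy -> electrostatic. The near-zero band
#' takes precedence so that a small |dH| with dS > 0 is read as
#' electrostatic rather than hydrophobic.
#'
#' @param delta_h_kj_mol Binding enthalpy (kJ/mol); vectorised.
#' @param delta_s_j_mol_k Binding entropy (J/mol/K); recycled.
#' @param near_zero_kj_mol Half-width of the "dH close to zero" band.
#' @return Character vector: `"hydrophobic"`, `"hbond_vdw"`,
#'   `"electrostatic"` or `"undetermined"`.
#' @export
#' @examples
#' classify_forces(-278.25, -805.8) # hbond_vdw
#' classify_forces(146.68, 593.3)   # hydrophobic
classify_forces <- function(delta_h_kj_mol, delta_s_j_mol_k, near_zero_kj_mol = 10) {
  if (any(!is.finite(delta_h_kj_mol)) || any(!is.finite(delta_s_j_mol_k))) {
    abort_domain("classify_forces requires finite inputs")
  }
  n <- max(length(delta_h_kj_mol), length(delta_s_j_mol_k))
  dh <- rep_len(delta_h_kj_mol, n)
  ds <- rep_len(delta_s_j_mol_k, n)
  out <- character(n)
  for (i in seq_len(n)) {
    out[i] <- if (abs(dh[i]) <= near_zero_kj_mol && ds[i] > 0) "electrostatic"
      else if (dh[i] > 0 && ds[i] > 0) "hydrophobic"
      else if (dh[i] < 0 && ds[i] < 0) "hbond_vdw"
      else if (dh[i] < 0 && ds[i] > 0) "electrostatic"
      else "undetermined"
  }
  out
}

#' Full thermodynamic analysis of a (temperature, Kb) table
#'
#' Runs the Van't Hoff fit, computes the per-temperature Gibbs energy via
#' `-R T ln Kb` (reported from the binding constants directly, not from
#' `dH - T dS`), and classifies the dominant interaction force. A
#' `system` column, if present, is analysed group-wise.
#'
#' @inheritParams vant_hoff_fit
#' @inheritParams classify_forces
#' @return A tibble with one row per system (or a single unnamed row):
#'   `delta_h_kj_mol`, `delta_s_j_mol_k`, `r_squared`, `force_class`, and
#'   a `delta_g` list-column of per-temperature tibbles
#'   (`temperature_K`, `kb`, `delta_g_kj_mol`).
#' @export
thermo_table <- function(data, near_zero_kj_mol = 10) {
  if ("system" %in% names(data)) {
    return(data |>
             dplyr::group_by(.data$system) |>
             dplyr::group_split() |>
             purrr::map(function(d) {
               dplyr::bind_cols(tibble(system = d$system[1]),
                                thermo_table(d[setdiff(names(d), "system")],
                                             near_zero_kj_mol))
             }) |>
             purrr::list_rbind())
  }
  fit <- vant_hoff_fit(data)
  dg <- tibble(temperature_K = fit$data$temperature_K, kb = fit$data$kb,
               delta_g_kj_mol = gibbs_from_kb(fit$data$kb, fit$data$temperature_K))
  tibble(delta_h_kj_mol = fit$delta_h_kj_mol,
         delta_s_j_mol_k = fit$delta_s_j_mol_k,
         r_squared = fit$r_squared,
         force_class = classify_forces(fit$delta_h_kj_mol, fit$delta_s_j_mol_k,
                                       near_zero_kj_mol),
         delta_g = list(dg))
}
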