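#' Plot a titration's emission spectra
#'
#' One curve per ligand concentration, coloured by concentration;
#' faceted by series when several are present.
#'
#' @param object A titration tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.titration <- function(object, ...) {
  ggplot2::ggplot(object,
    ggplot2::aes(x = .data$wavelength_nm, y = .data$intensity,
                 colour = .data$ligand_conc_M * 1e6,
                 group = .data$ligand_conc_M)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~ series_id) +
    ggplot2::labs(x = "Emission wavelength (nm)", y = "Fluorescence intensity",
                  colour = "[Q] (µM)") +
    ggplot2::theme_minimal()
}

#' Stern-Volmer diagnostic plot
#'
#' F0/F against ligand concentration with the fitted line.
#'
#' @param object An [stern_volmer_fit()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.sv_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$ligand_conc_M, y = .data$ratio)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$ksv,
                         linetype = "dashed") +
    ggplot2::labs(x = "[Q] (mol/L)", y = expression(F[0] / F),
                  title = sprintf("Stern-Volmer: Ksv = %.3g L/mol (%g K)",
                                  object$ksv, object$temperature_K)) +
    ggplot2::theme_minimal()
}

#' Double-logarithmic binding plot
#'
#' log10((F0-F)/F) against log10([Q]) with the fitted line whose slope is
#' the apparent site number and whose intercept encodes log10(Kb).
#'
#' @param object A [double_log_fit()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.binding_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$log_q, y = .data$log_ff)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = log10(object$kb), slope = object$n_sites,
                         linetype = "dashed") +
    ggplot2::labs(x = "log10 [Q]", y = "log10 ((F0 - F)/F)",
                  title = sprintf("Kb = %.3g L/mol, n = %.2f (%g K)",
                                  object$kb, object$n_sites, object$temperature_K)) +
    ggplot2::theme_minimal()
}

#' Van't Hoff plot
#'
#' ln(Kb) against 1/T with the fitted line; the slope carries -dH/R and
#' the intercept dS/R.
#'
#' @param object A [vant_hoff_fit()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.vant_hoff_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$inv_t, y = .data$ln_kb)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$delta_s_j_mol_k / .R_GAS,
                         slope = -object$delta_h_kj_mol * 1000 / .R_GAS,
                         linetype = "dashed") +
    ggplot2::labs(x = "1/T (1/K)", y = "ln Kb",
                  title = sprintf("dH = %.1f kJ/mol, dS = %.1f J/mol/K",
                                  object$delta_h_kj_mol, object$delta_s_j_mol_k)) +
    ggplot2::theme_minimal()
}

#' Correlation heat map
#'
#' Tile map of the signed Pearson matrix.
#'
#' @param object A [pearson_matrix()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pearson_matrix <- function(object, ...) {
  r <- object$r
  long <- tibble(metric_1 = rep(rownames(r), times = ncol(r)),
                 metric_2 = rep(colnames(r), each = nrow(r)),
                 r = as.vector(r))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric_1, y = .data$metric_2,
                                     fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal()
}
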