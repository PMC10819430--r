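#' Site-marker displacement ratio
#'
#' Percent decrease of the binding constant when a site-marker probe is
#' pre-bound: `phi = (Kb_free - Kb_probe) / Kb_free * 100`. A large phi
#' means the ligand and the probe compete for the same subdomain.
#' Negative values (binding enhancement) are allowed and flagged with a
#' warning.
#'
#' @param kb_free Binding constant without the probe (L/mol), positive.
#' @param kb_probe Binding constant with the probe present (L/mol),
#'   positive; recycled against `kb_free`.
#' @return Displacement percentage, vectorised; always <= 100.
#' @export
#' @examples
#' displacement_ratio(7.81e6, 1.33e5) # 98.3%
displacement_ratio <- function(kb_free, kb_probe) {
  if (any(!is.finite(kb_free)) || any(kb_free <= 0) ||
      any(!is.finite(kb_probe)) || any(kb_probe <= 0)) {
    abort_domain("binding constants must be positive and finite")
  }
  phi <- (kb_free - kb_probe) / kb_free * 100
  if (any(phi < 0)) {
    warn(sprintf("%d probe condition(s) show binding enhancement (phi < 0)",
                 sum(phi < 0)))
  }
  phi
}

#' Displacement table for probe competition data
#'
#' @param data Data frame with columns `probe`, `kb_free`, `kb_probe`
#'   (and optionally `system`).
#' @return The input tibble with a `phi_pct` column appended.
#' @export
competition_table <- function(data) {
  missing <- setdiff(c("probe", "kb_free", "kb_probe"), names(data))
  if (length(missing) > 0) {
    abort_format(paste0("competition data is missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  dplyr::mutate(as_tibble(data),
                phi_pct = displacement_ratio(.data$kb_free, .data$kb_probe))
}

#' Default probe-to-subdomain map for serum albumin
#'
#' Warfarin marks subdomain IIA (Sudlow site I), ibuprofen subdomain IIIA
#' (Sudlow site II), lidocaine subdomain IB.
#'
#' @return Named character vector mapping probe name to subdomain.
#' @export
default_site_map <- function() {
  c(warfarin = "IIA", ibuprofen = "IIIA", lidocaine = "IB")
}

#' Assign the binding subdomain from probe displacement results
#'
#' The probe with the largest displacement ratio wins (ties broken
#' alphabetically by probe name); its subdomain is the assigned binding
#' site. The assignment is flagged `dominant` when the winning phi
#' reaches the dominance threshold.
#'
#' @param results Data frame with columns `probe` and `phi_pct`, e.g.
#'   from [competition_table()]; a `system` column, if present, is
#'   handled group-wise.
#' @param site_map Named character vector mapping each probe to a
#'   subdomain; defaults to [default_site_map()]. Probes missing from the
#'   map are a configuration error.
#' @param dominance_pct Threshold (percent) above which the winning probe
#'   is considered to dominate the site assignment.
#' @return Tibble with one row per system: `assigned_site`,
#'   `winning_probe`, `phi_winning`, `margin` (phi lead over the
#'   runner-up, `NA` with a single probe), `dominant`.
#' @export
#' @examples
#' res <- tibble::tibble(probe = c("warfarin", "ibuprofen", "lidocaine"),
#'                       phi_pct = c(98.3, 13.8, 43.9))
#' assign_binding_site(res)
assign_binding_site <- function(results, site_map = default_site_map(),
                                dominance_pct = 80) {
  missing <- setdiff(c("probe", "phi_pct"), names(results))
  if (length(missing) > 0) {
    abort_format(paste0("results are missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (nrow(results) == 0) abort_validation("at least one competition result is required")
  if ("system" %in% names(results)) {
    return(results |>
             dplyr::group_by(.data$system) |>
             dplyr::group_split() |>
             purrr::map(function(d) {
               dplyr::bind_cols(tibble(system = d$system[1]),
                                assign_binding_site(d[setdiff(names(d), "system")],
                                                    site_map, dominance_pct))
             }) |>
             purrr::list_rbind())
  }
  unknown <- setdiff(results$probe, names(site_map))
  if (length(unknown) > 0) {
    abort_config(paste0("probe(s) not in site map: ", paste(unknown, collapse = ", ")))
  }
  d <- dplyr::arrange(as_tibble(results), dplyr::desc(.data$phi_pct), .data$probe)
  winner <- d[1, ]
  margin <- if (nrow(d) > 1) winner$phi_pct - d$phi_pct[2] else NA_real_
  tibble(assigned_site = unname(site_map[winner$probe]),
         winning_probe = winner$probe,
         phi_winning = winner$phi_pct,
         margin = margin,
         dominant = winner$phi_pct >= dominance_pct)
}
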