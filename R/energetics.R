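#' Read and validate an MM/GBSA energy-decomposition table
#'
#' The decomposition splits the end-point binding free energy into van
#' der Waals (`de_vdw`), electrostatic (`de_elec`), polar solvation
#' (`dg_gb`) and non-polar solvation (`dg_sa`) terms, all in kcal/mol;
#' their sum is the binding free energy `dg_bind`.
#'
#' @param path CSV with columns `system`, `de_vdw`, `de_elec`, `dg_gb`,
#'   `dg_sa` and optionally `dg_bind`.
#' @return Tibble with the components, `dg_bind` (computed as the
#'   component sum when absent), `component_sum`, `residual`
#'   (`dg_bind - component_sum`) and `consistent`
#'   (|residual| <= `tolerance`). Inconsistent printed totals trigger a
#'   warning naming the residual but are kept as given.
#' @param tolerance Consistency tolerance in kcal/mol; 0.01 matches
#'   tables printed at two decimals.
#' @export
read_gbsa_table <- function(path, tolerance = 0.01) {
  if (!file.exists(path)) abort_format(paste0("file not found: ", path))
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
  validate_gbsa(df, tolerance = tolerance)
}

#' @rdname read_gbsa_table
#' @param data Data frame with the decomposition columns.
#' @export
validate_gbsa <- function(data, tolerance = 0.01) {
  required <- c("system", "de_vdw", "de_elec", "dg_gb", "dg_sa")
  missing <- setdiff(required, names(data))
  if (length(missing) > 0) {
    abort_format(paste0("decomposition table is missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  if (nrow(data) == 0) abort_validation("decomposition table is empty")
  d <- as_tibble(data)
  comps <- as.matrix(d[, c("de_vdw", "de_elec", "dg_gb", "dg_sa")])
  if (any(!is.finite(comps))) abort_validation("all energy components must be finite")
  d$component_sum <- rowSums(comps)
  if (!"dg_bind" %in% names(d) || all(is.na(d$dg_bind))) {
    d$dg_bind <- d$component_sum
  }
  d$dg_bind <- ifelse(is.na(d$dg_bind), d$component_sum, d$dg_bind)
  d$residual <- d$dg_bind - d$component_sum
  # small fp guard so a residual exactly at the printed precision passes
  d$consistent <- abs(d$residual) <= tolerance + 1e-9
  if (any(!d$consistent)) {
    bad <- d[!d$consistent, ]
    warn(sprintf("dg_bind inconsistent with component sum for %s (residual %s kcal/mol)",
                 paste(bad$system, collapse = ", "),
                 paste(sprintf("%.3f", bad$residual), collapse = ", ")))
  }
  d
}

#' Total binding energy from decomposition components
#'
#' @param data Data frame (or one-row record) with `de_vdw`, `de_elec`,
#'   `dg_gb`, `dg_sa` in kcal/mol.
#' @return Numeric vector of component sums, one per row.
#' @export
#' @examples
#' total_binding_energy(data.frame(de_vdw = -28.64, de_elec = -29.20,
#'                                 dg_gb = 24.50, dg_sa = -5.49))
total_binding_energy <- function(data) {
  required <- c("de_vdw", "de_elec", "dg_gb", "dg_sa")
  missing <- setdiff(required, names(data))
  if (length(missing) > 0) {
    abort_format(paste0("missing component column(s): ", paste(missing, collapse = ", ")))
  }
  comps <- as.matrix(as.data.frame(data)[, required])
  if (any(!is.finite(comps))) abort_validation("all energy components must be finite")
  unname(rowSums(comps))
}

#' Rank systems by binding free energy
#'
#' @param data Data frame with `system` and `dg_bind` (kcal/mol).
#' @return Tibble `system`, `dg_bind`, `rank`, ascending in `dg_bind`
#'   (most negative, i.e. strongest binder, first); ties break
#'   alphabetically by system name.
#' @export
rank_by_affinity <- function(data) {
  missing <- setdiff(c("system", "dg_bind"), names(data))
  if (length(missing) > 0) {
    abort_format(paste0("missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (nrow(data) == 0) abort_validation("at least one record is required")
  out <- as_tibble(data)[, c("system", "dg_bind")] |>
    dplyr::arrange(.data$dg_bind, .data$system)
  out$rank <- seq_len(nrow(out))
  out
}

#' Pearson correlation matrix across compound metrics
#'
#' Product-moment correlations between per-compound metrics (binding
#' constants, energies, molecular descriptors...), pairwise-complete on
#' missing values. Metrics with fewer than two distinct values have no
#' defined correlation and are reported as `NA`, not zero. Signed
#' coefficients are kept alongside a magnitude view, since inverse
#' relationships between affinities and (negative) energies are usually
#' quoted by |r|.
#'
#' @param data Data frame whose first column (or a `compound` column)
#'   identifies compounds and whose remaining numeric columns are
#'   metrics; at least 3 compounds.
#' @return Object of class `pearson_matrix`: list with `r` (signed
#'   matrix), `abs_r`, and `n_compounds`. [tidy()] returns the long
#'   pair table.
#' @export
#' @examples
#' m <- tibble::tibble(compound = letters[1:4], a = 1:4, b = c(2, 4, 6, 9))
#' pearson_matrix(m)$r
pearson_matrix <- function(data) {
  d <- as_tibble(data)
  id_col <- if ("compound" %in% names(d)) "compound"
    else if (!is.numeric(d[[1]])) names(d)[1]
    else NULL
  if (!is.null(id_col)) d <- d[, setdiff(names(d), id_col)]
  if (!all(vapply(d, is.numeric, logical(1)))) {
    abort_format("all metric columns must be numeric")
  }
  if (nrow(d) < 3) abort_validation("correlation needs at least 3 compounds")
  x <- as.matrix(d)
  r <- suppressWarnings(cor(x, use = "pairwise.complete.obs", method = "pearson"))
  constant <- vapply(seq_len(ncol(x)), function(j) {
    v <- x[, j][is.finite(x[, j])]
    length(unique(v)) < 2
  }, logical(1))
  r[constant, ] <- NA_real_
  r[, constant] <- NA_real_
  diag(r)[!constant] <- 1
  structure(list(r = r, abs_r = abs(r), n_compounds = nrow(d)),
            class = "pearson_matrix")
}

#' @export
print.pearson_matrix <- function(x, ...) {
  cat(sprintf("Pearson correlation matrix over %d compounds\n", x$n_compounds))
  print(round(x$r, 2))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pearson_matrix <- function(x, ...) {
  r <- x$r
  pairs <- which(upper.tri(r), arr.ind = TRUE)
  tibble(metric_1 = rownames(r)[pairs[, 1]], metric_2 = colnames(r)[pairs[, 2]],
         r = r[pairs], abs_r = abs(r[pairs]))
}
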