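#' Validate a long-format titration table
#'
#' A titration table holds one or more emission-titration series in long
#' format: one row per (series, ligand concentration, emission wavelength).
#' Each series is one protein solution at one temperature, scanned at a
#' ladder of ligand concentrations that must include the ligand-free
#' reference (the F0 spectrum).
#'
#' @param df Data frame with columns `series_id`, `temperature_K`,
#'   `ligand_conc_M`, `wavelength_nm`, `intensity`, and optionally matched
#'   absorbance columns `a_ex`, `a_em` (constant within a spectrum) for
#'   inner-filter correction.
#' @param protein_conc_M,excitation_nm Optional metadata stored as
#'   attributes; `NA` when unknown.
#'
#' @details Invariants enforced: all intensities finite; ligand
#'   concentrations finite and non-negative with exactly one zero
#'   concentration per series; wavelengths strictly increasing within each
#'   spectrum; `a_ex`/`a_em` either both present or both absent.
#'   Synchronous-fluorescence scans (constant excitation-emission offset)
#'   are stored the same way, with the scan axis in `wavelength_nm`.
#'
#' @return A tibble of class `titration`, sorted by series, concentration
#'   and wavelength.
#' @export
#' @examples
#' sim <- simulate_titration(sim_config(noise_sd_rel = 0), 298)
#' as_titration(sim)
as_titration <- function(df, protein_conc_M = NA_real_, excitation_nm = NA_real_) {
  required <- c("series_id", "temperature_K", "ligand_conc_M", "wavelength_nm", "intensity")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort_format(paste0("titration table is missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  has_aex <- "a_ex" %in% names(df)
  has_aem <- "a_em" %in% names(df)
  if (xor(has_aex, has_aem)) {
    abort_validation("absorbance columns a_ex and a_em must both be present or both absent")
  }
  df <- as_tibble(df)
  for (col in c("temperature_K", "ligand_conc_M", "wavelength_nm", "intensity")) {
    if (!is.numeric(df[[col]])) abort_format(paste0("column ", col, " must be numeric"))
  }
  if (!all(is.finite(df$intensity))) abort_validation("intensities must be finite")
  if (!all(is.finite(df$ligand_conc_M)) || any(df$ligand_conc_M < 0)) {
    abort_validation("ligand concentrations must be finite and non-negative")
  }
  if (has_aex) {
    aa <- c(df$a_ex, df$a_em)
    if (!all(is.finite(aa)) || any(aa < 0)) {
      abort_domain("absorbances a_ex/a_em must be finite and non-negative")
    }
  }

  # per-spectrum wavelength monotonicity is checked in file order
  check <- df |>
    dplyr::group_by(.data$series_id, .data$temperature_K, .data$ligand_conc_M) |>
    dplyr::summarise(mono = all(diff(.data$wavelength_nm) > 0), .groups = "drop")
  if (!all(check$mono)) {
    bad <- check[!check$mono, ]
    abort_validation(sprintf(
      "wavelengths must be strictly increasing within each spectrum (series %s, conc %.3g)",
      bad$series_id[1], bad$ligand_conc_M[1]))
  }

  zeros <- df |>
    dplyr::distinct(.data$series_id, .data$temperature_K, .data$ligand_conc_M) |>
    dplyr::group_by(.data$series_id, .data$temperature_K) |>
    dplyr::summarise(n_zero = sum(.data$ligand_conc_M == 0), .groups = "drop")
  if (any(zeros$n_zero != 1)) {
    bad <- zeros[zeros$n_zero != 1, ]
    abort_validation(sprintf(
      "series %s at %g K must contain exactly one zero-concentration (F0) spectrum, found %d",
      bad$series_id[1], bad$temperature_K[1], bad$n_zero[1]))
  }

  out <- dplyr::arrange(df, .data$series_id, .data$temperature_K,
                        .data$ligand_conc_M, .data$wavelength_nm)
  attr(out, "protein_conc_M") <- protein_conc_M
  attr(out, "excitation_nm") <- excitation_nm
  attr(out, "ground_truth") <- attr(df, "ground_truth", exact = TRUE)
  class(out) <- c("titration", class(tibble()))
  out
}

#' Read a titration CSV
#'
#' Reads the long-format titration dialect: UTF-8, comma-separated, header
#' row, one row per wavelength, concentrations in mol/L. Lines starting
#' with `#` are treated as comments; fixture files written by
#' [write_fixture()] carry their generating ground truth there, and it is
#' restored as the `ground_truth` attribute.
#'
#' @param path Path to a CSV file with columns `series_id`,
#'   `temperature_K`, `ligand_conc_M`, `wavelength_nm`, `intensity` and
#'   optionally `a_ex`, `a_em`.
#' @param series_id If given, keep only this series.
#' @return A validated [as_titration()] tibble.
#' @export
read_titration_csv <- function(path, series_id = NULL) {
  if (!file.exists(path)) abort_format(paste0("file not found: ", path))
  header <- parse_fixture_header(path)
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  required <- c("series_id", "temperature_K", "ligand_conc_M", "wavelength_nm", "intensity")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort_format(paste0(path, " is missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (!is.null(series_id)) {
    df <- df[df$series_id == series_id, , drop = FALSE]
    if (nrow(df) == 0) abort_validation(paste0("no rows for series_id ", series_id))
  }
  attr(df, "ground_truth") <- header$ground_truth
  as_titration(df,
               protein_conc_M = header$protein_conc_M %||% NA_real_,
               excitation_nm = header$excitation_nm %||% NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Inner-filter correction
#'
#' Corrects an observed fluorescence intensity for primary and secondary
#' inner-filter attenuation using the sample absorbances at the excitation
#' and emission wavelengths: `F_corr = F_obs * 10^((A_ex + A_em)/2)`.
#' The corrected intensity is never smaller than the observed one.
#'
#' @param f_obs Observed intensity (arbitrary units), non-negative.
#' @param a_ex,a_em Absorbances at the excitation and emission wavelengths.
#' @return Corrected intensity, vectorised over the inputs.
#' @export
#' @examples
#' correct_inner_filter(100, 0.1, 0.1) # 100 * 10^0.1
correct_inner_filter <- function(f_obs, a_ex, a_em) {
  if (!all(is.finite(f_obs)) || !all(is.finite(a_ex)) || !all(is.finite(a_em))) {
    abort_domain("inner-filter correction requires finite inputs")
  }
  if (any(f_obs < 0)) abort_domain("observed intensity must be non-negative")
  if (any(a_ex < 0) || any(a_em < 0)) abort_domain("absorbances must be non-negative")
  f_obs * 10^((a_ex + a_em) / 2)
}

#' Extract per-point fluorescence intensities from a titration
#'
#' Reduces each spectrum of each series to the single intensity F used by
#' the Stern-Volmer and double-logarithmic fits. Inner-filter correction is
#' applied first whenever the absorbance columns are present.
#'
#' @param titr A [as_titration()] table (one or more series).
#' @param policy `"fixed_reference"` reads the intensity at one emission
#'   wavelength for every spectrum (the textbook Stern-Volmer convention);
#'   `"per_spectrum_max"` takes each spectrum's maximum, tracking a
#'   drifting peak.
#' @param reference_nm Emission wavelength for `fixed_reference`; defaults
#'   to the peak wavelength of the zero-ligand spectrum of each series.
#'   Must lie within every spectrum's wavelength range.
#' @return Tibble with columns `series_id`, `temperature_K`,
#'   `ligand_conc_M`, `f`, sorted by ascending concentration within series;
#'   the `ligand_conc_M == 0` row carries F0.
#' @export
series_intensities <- function(titr,
                               policy = c("fixed_reference", "per_spectrum_max"),
                               reference_nm = NULL) {
  policy <- match.arg(policy)
  titr <- as_titration(titr,
                       protein_conc_M = attr(titr, "protein_conc_M") %||% NA_real_,
                       excitation_nm = attr(titr, "excitation_nm") %||% NA_real_)
  has_ife <- all(c("a_ex", "a_em") %in% names(titr))

  one_series <- function(d) {
    if (has_ife) {
      d$intensity <- correct_inner_filter(d$intensity, d$a_ex, d$a_em)
    }
    specs <- split(d, d$ligand_conc_M)
    concs <- as.numeric(names(specs))
    if (policy == "fixed_reference") {
      ref <- reference_nm
      if (is.null(ref)) {
        f0spec <- specs[[which(concs == 0)]]
        ref <- f0spec$wavelength_nm[which.max(f0spec$intensity)]
      }
      f <- vapply(specs, function(s) {
        if (ref < min(s$wavelength_nm) || ref > max(s$wavelength_nm)) {
          abort_domain(sprintf("reference wavelength %.1f nm outside spectrum range", ref))
        }
        s$intensity[which.min(abs(s$wavelength_nm - ref))]
      }, numeric(1))
    } else {
      f <- vapply(specs, function(s) max(s$intensity), numeric(1))
    }
    tibble(series_id = d$series_id[1], temperature_K = d$temperature_K[1],
           ligand_conc_M = concs, f = unname(f)) |>
      dplyr::arrange(.data$ligand_conc_M)
  }

  titr |>
    dplyr::group_by(.data$series_id, .data$temperature_K) |>
    dplyr::group_split() |>
    purrr::map(one_series) |>
    purrr::list_rbind()
}

#' Peak position, shift and quench percentage of a spectrum
#'
#' Locates the emission maximum of a spectrum, reports its signed shift
#' against a reference spectrum (negative = blue/hypsochromic, positive =
#' red/bathochromic) and the percent quench of the peak intensity relative
#' to the reference maximum.
#'
#' @param spectrum,reference Data frames with columns `wavelength_nm` and
#'   `intensity` (a single spectrum each).
#' @param shift_tolerance_nm Shifts within this tolerance classify as
#'   `"none"`; default 0.5 nm absorbs grid resolution.
#' @param refine If `TRUE`, the peak wavelength is refined by three-point
#'   parabolic interpolation around the grid argmax (off by default so
#'   results are grid-exact and bit-reproducible).
#' @return One-row tibble: `lambda_max_nm`, `f_max`, `delta_lambda_nm`,
#'   `shift_class` (`"blue"`, `"red"` or `"none"`), `quench_pct`.
#' @export
peak_metrics <- function(spectrum, reference, shift_tolerance_nm = 0.5,
                         refine = FALSE) {
  sp <- check_spectrum(spectrum, "spectrum")
  rf <- check_spectrum(reference, "reference")
  f0_max <- max(rf$intensity)
  if (f0_max <= 0) abort_domain("reference spectrum must have a positive maximum")

  lam <- peak_lambda(sp, refine)
  lam_ref <- peak_lambda(rf, refine)
  f_max <- max(sp$intensity)
  delta <- lam - lam_ref
  shift_class <- if (delta < -shift_tolerance_nm) "blue"
    else if (delta > shift_tolerance_nm) "red" else "none"
  tibble(lambda_max_nm = lam, f_max = f_max, delta_lambda_nm = delta,
         shift_class = shift_class,
         quench_pct = (f0_max - f_max) / f0_max * 100)
}

check_spectrum <- function(s, what) {
  if (!all(c("wavelength_nm", "intensity") %in% names(s))) {
    abort_format(paste0(what, " needs columns wavelength_nm and intensity"))
  }
  if (nrow(s) == 0) abort_validation(paste0(what, " is empty"))
  if (any(diff(s$wavelength_nm) <= 0)) {
    abort_validation(paste0(what, " wavelengths must be strictly increasing"))
  }
  s
}

peak_lambda <- function(s, refine) {
  i <- which.max(s$intensity)
  lam <- s$wavelength_nm[i]
  if (refine && i > 1 && i < nrow(s)) {
    # parabola through the three samples bracketing the argmax
    x <- s$wavelength_nm[(i - 1):(i + 1)]
    y <- s$intensity[(i - 1):(i + 1)]
    denom <- (x[1] - x[2]) * (x[1] - x[3]) * (x[2] - x[3])
    a <- (x[3] * (y[2] - y[1]) + x[2] * (y[1] - y[3]) + x[1] * (y[3] - y[2])) / denom
    b <- (x[3]^2 * (y[1] - y[2]) + x[2]^2 * (y[3] - y[1]) + x[1]^2 * (y[2] - y[3])) / denom
    if (a < 0) lam <- -b / (2 * a)
  }
  lam
}

#' Read a dense excitation-emission matrix CSV
#'
#' @param path CSV with columns `excitation_nm`, `emission_nm`,
#'   `intensity`, one row per grid point (dense grid).
#' @return Tibble of class `eem_grid`.
#' @export
read_eem_csv <- function(path) {
  if (!file.exists(path)) abort_format(paste0("file not found: ", path))
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
  as_eem(df)
}

#' @rdname read_eem_csv
#' @param df Data frame with the three EEM columns.
#' @export
as_eem <- function(df) {
  required <- c("excitation_nm", "emission_nm", "intensity")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort_format(paste0("EEM table is missing column(s): ", paste(missing, collapse = ", ")))
  }
  ex <- sort(unique(df$excitation_nm))
  em <- sort(unique(df$emission_nm))
  if (nrow(df) != length(ex) * length(em)) {
    abort_validation("EEM grid must be dense (every excitation x emission pair present)")
  }
  out <- dplyr::arrange(as_tibble(df), .data$excitation_nm, .data$emission_nm)
  class(out) <- c("eem_grid", class(tibble()))
  out
}

#' Locate EEM peaks near seed positions
#'
#' For each seed (a labelled approximate peak position, e.g. peak A at
#' 280/337 nm for the tryptophan/tyrosine band of a protein), returns the
#' maximal grid point within the search radius. Intensity changes between
#' two grids (e.g. with and without ligand) are left to the caller as
#' simple percentage ratios of the returned intensities.
#'
#' @param grid An [as_eem()] grid.
#' @param seeds Data frame with columns `label`, `excitation_nm`,
#'   `emission_nm`; every seed must lie within the grid axes.
#' @param search_radius_nm Euclidean search radius around each seed.
#' @return Tibble with one row per seed: `label`, `excitation_nm`,
#'   `emission_nm`, `intensity`.
#' @export
eem_peaks <- function(grid, seeds, search_radius_nm = 15) {
  grid <- as_eem(grid)
  if (!all(c("label", "excitation_nm", "emission_nm") %in% names(seeds))) {
    abort_format("seeds need columns label, excitation_nm, emission_nm")
  }
  purrr::pmap(seeds[, c("label", "excitation_nm", "emission_nm")],
    function(label, excitation_nm, emission_nm) {
      if (excitation_nm < min(grid$excitation_nm) || excitation_nm > max(grid$excitation_nm) ||
          emission_nm < min(grid$emission_nm) || emission_nm > max(grid$emission_nm)) {
        abort_domain(sprintf("seed %s (%g/%g nm) lies outside the grid", label,
                             excitation_nm, emission_nm))
      }
      d2 <- (grid$excitation_nm - excitation_nm)^2 + (grid$emission_nm - emission_nm)^2
      win <- grid[d2 <= search_radius_nm^2, ]
      if (nrow(win) == 0) abort_domain(sprintf("no grid points within %g nm of seed %s",
                                               search_radius_nm, label))
      best <- win[which.max(win$intensity), ]
      tibble(label = label, excitation_nm = best$excitation_nm,
             emission_nm = best$emission_nm, intensity = best$intensity)
    }) |>
    purrr::list_rbind()
}
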