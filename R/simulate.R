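#' Configuration for the titration simulator
#'
#' Builds the parameter set for [simulate_titration()]. The defaults
#' reproduce the conditions of a serum-albumin quenching assay: 1 uM
#' protein excited at 275 nm, ligand added to 0-18 uM in 3 uM steps, three
#' temperatures (298, 304, 310 K), a tryptophan-like emission band at
#' 337 nm that blue-shifts toward 317 nm as the bound fraction grows, and
#' 1% multiplicative detector noise.
#'
#' @param kb Binding constant (L/mol) used at every temperature, unless
#'   `delta_h_kj_mol`/`delta_s_j_mol_k` are supplied, in which case the
#'   per-temperature Kb follows the Van't Hoff relation
#'   `ln Kb = -dH/(R T) + dS/R`.
#' @param n_sites Apparent number of binding sites (Hill-like exponent).
#' @param delta_h_kj_mol,delta_s_j_mol_k Optional binding enthalpy
#'   (kJ/mol) and entropy (J/mol/K) driving the temperature dependence.
#' @param f0 Ligand-free peak intensity (arbitrary units).
#' @param peak_free_nm,peak_bound_nm Emission peak of the free and the
#'   fully bound protein; the simulated peak sits at
#'   `peak_free + (peak_bound - peak_free) * b(Q)` where `b` is the bound
#'   fraction.
#' @param bandwidth_nm Gaussian band standard deviation.
#' @param concentrations_M Ligand concentration ladder; must include 0.
#' @param temperatures_K Temperatures simulated by [simulate_study()].
#' @param wavelength_range_nm,wavelength_step_nm Emission scan grid.
#' @param mode `"binding"` uses the static 1:n model
#'   `F(Q) = f0 / (1 + Kb Q^n)` (the exact inverse of the
#'   double-logarithmic fit); `"stern_volmer"` uses the linear law
#'   `F0/F = 1 + Ksv Q`.
#' @param ksv Stern-Volmer constant for `mode = "stern_volmer"`.
#' @param a_ex,a_em Optional per-concentration absorbances; when given the
#'   emitted intensities are attenuated by `10^-((a_ex + a_em)/2)`, which
#'   [correct_inner_filter()] inverts exactly.
#' @param noise_sd_rel Relative standard deviation of multiplicative
#'   Gaussian noise applied last; 0 gives the exact forward model.
#' @param seed Integer seed; a fixed seed gives bit-identical output.
#' @param protein_conc_M,excitation_nm Metadata carried on the series.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(kb = 1e5,
                       n_sites = 1,
                       delta_h_kj_mol = NULL,
                       delta_s_j_mol_k = NULL,
                       f0 = 1000,
                       peak_free_nm = 337,
                       peak_bound_nm = 317,
                       bandwidth_nm = 25,
                       concentrations_M = c(0, 3, 6, 9, 12, 15, 18) * 1e-6,
                       temperatures_K = c(298, 304, 310),
                       wavelength_range_nm = c(275, 500),
                       wavelength_step_nm = 1,
                       mode = c("binding", "stern_volmer"),
                       ksv = NULL,
                       a_ex = NULL,
                       a_em = NULL,
                       noise_sd_rel = 0.01,
                       seed = 1L,
                       protein_conc_M = 1e-6,
                       excitation_nm = 275) {
  mode <- match.arg(mode)
  cfg <- list(kb = kb, n_sites = n_sites, delta_h_kj_mol = delta_h_kj_mol,
              delta_s_j_mol_k = delta_s_j_mol_k, f0 = f0,
              peak_free_nm = peak_free_nm, peak_bound_nm = peak_bound_nm,
              bandwidth_nm = bandwidth_nm, concentrations_M = concentrations_M,
              temperatures_K = temperatures_K,
              wavelength_range_nm = wavelength_range_nm,
              wavelength_step_nm = wavelength_step_nm, mode = mode, ksv = ksv,
              a_ex = a_ex, a_em = a_em, noise_sd_rel = noise_sd_rel,
              seed = as.integer(seed), protein_conc_M = protein_conc_M,
              excitation_nm = excitation_nm)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (!any(cfg$concentrations_M == 0)) {
    abort_validation("concentrations_M must include the zero (F0) point")
  }
  if (any(cfg$concentrations_M < 0)) abort_validation("concentrations must be non-negative")
  if (cfg$bandwidth_nm <= 0) abort_validation("bandwidth_nm must be positive")
  if (cfg$f0 <= 0) abort_validation("f0 must be positive")
  if (is.null(cfg$delta_h_kj_mol) != is.null(cfg$delta_s_j_mol_k)) {
    abort_validation("delta_h_kj_mol and delta_s_j_mol_k must be given together")
  }
  if (is.null(cfg$delta_h_kj_mol) && (!is.numeric(cfg$kb) || cfg$kb <= 0)) {
    abort_validation("kb must be positive")
  }
  if (cfg$mode == "stern_volmer" && (is.null(cfg$ksv) || cfg$ksv < 0)) {
    abort_validation("mode 'stern_volmer' requires a non-negative ksv")
  }
  for (ab in c("a_ex", "a_em")) {
    v <- cfg[[ab]]
    if (!is.null(v) && length(v) != length(cfg$concentrations_M)) {
      abort_validation(paste0(ab, " must have one value per concentration"))
    }
  }
  if (cfg$noise_sd_rel < 0) abort_validation("noise_sd_rel must be non-negative")
  invisible(cfg)
}

#' Kb at a given temperature under the configured Van't Hoff parameters
#'
#' @param config A [sim_config()].
#' @param temperature_K Temperature in kelvin.
#' @return The binding constant used by the simulator at that temperature.
#' @export
kb_at_temperature <- function(config, temperature_K) {
  if (!is.null(config$delta_h_kj_mol)) {
    exp(-config$delta_h_kj_mol * 1000 / (.R_GAS * temperature_K) +
          config$delta_s_j_mol_k / .R_GAS)
  } else {
    config$kb
  }
}

#' Simulate one emission-titration series
#'
#' Forward model of a static-quenching titration: the quenched intensity
#' follows `F(Q) = f0 / (1 + Kb Q^n)` (total added ligand concentration,
#' matching the fitting convention), each spectrum is a Gaussian emission
#' band of height F(Q) whose centre moves from the free to the bound peak
#' in proportion to the bound fraction `b(Q) = Kb Q^n / (1 + Kb Q^n)`,
#' optional inner-filter attenuation divides the intensities by
#' `10^((A_ex + A_em)/2)`, and multiplicative Gaussian noise is applied
#' last under the configured seed.
#'
#' @param config A [sim_config()].
#' @param temperature_K Temperature to simulate; defaults to the first
#'   configured temperature.
#' @param series_id Series label; default `"sim_<T>K"`.
#' @return A [as_titration()] tibble carrying the generating parameters in
#'   its `ground_truth` attribute (see [ground_truth()]).
#' @export
#' @examples
#' s <- simulate_titration(sim_config(noise_sd_rel = 0), 298)
#' ground_truth(s)$kb_true
simulate_titration <- function(config, temperature_K = NULL, series_id = NULL) {
  validate_sim_config(config)
  temperature_K <- temperature_K %||% config$temperatures_K[1]
  series_id <- series_id %||% sprintf("sim_%gK", temperature_K)
  kb_t <- kb_at_temperature(config, temperature_K)

  wl <- seq(config$wavelength_range_nm[1], config$wavelength_range_nm[2],
            by = config$wavelength_step_nm)
  concs <- sort(config$concentrations_M)
  occ <- kb_t * concs^config$n_sites          # Kb Q^n
  if (config$mode == "stern_volmer") occ <- config$ksv * concs
  f_q <- config$f0 / (1 + occ)
  bound <- occ / (1 + occ)
  centre <- config$peak_free_nm + (config$peak_bound_nm - config$peak_free_nm) * bound

  rows <- purrr::map(seq_along(concs), function(i) {
    intensity <- f_q[i] * exp(-(wl - centre[i])^2 / (2 * config$bandwidth_nm^2))
    out <- tibble(series_id = series_id, temperature_K = temperature_K,
                  ligand_conc_M = concs[i], wavelength_nm = wl,
                  intensity = intensity)
    if (!is.null(config$a_ex)) {
      out$a_ex <- config$a_ex[i]
      out$a_em <- config$a_em[i]
      out$intensity <- out$intensity / 10^((out$a_ex + out$a_em) / 2)
    }
    out
  })
  df <- purrr::list_rbind(rows)

  if (config$noise_sd_rel > 0) {
    # one substream per (seed, temperature) so multi-T studies differ
    df$intensity <- with_preserved_seed(
      config$seed + as.integer(round(temperature_K)),
      df$intensity * (1 + rnorm(nrow(df), sd = config$noise_sd_rel)))
  }

  truth <- list(series_id = series_id, temperature_K = temperature_K,
                kb_true = kb_t, n_true = config$n_sites,
                delta_h_kj_mol = config$delta_h_kj_mol,
                delta_s_j_mol_k = config$delta_s_j_mol_k,
                f0 = config$f0, peak_free_nm = config$peak_free_nm,
                peak_bound_nm = config$peak_bound_nm,
                bandwidth_nm = config$bandwidth_nm, mode = config$mode,
                ksv = config$ksv, noise_sd_rel = config$noise_sd_rel,
                seed = config$seed)
  attr(df, "ground_truth") <- truth
  as_titration(df, protein_conc_M = config$protein_conc_M,
               excitation_nm = config$excitation_nm)
}

#' Simulate a full multi-temperature study
#'
#' @param config A [sim_config()]; one series per configured temperature.
#' @return A combined [as_titration()] tibble; per-temperature ground
#'   truths are stored as a named list attribute.
#' @export
simulate_study <- function(config) {
  series <- purrr::map(config$temperatures_K,
                       function(tk) simulate_titration(config, tk))
  truths <- purrr::map(series, ground_truth)
  names(truths) <- purrr::map_chr(truths, "series_id")
  out <- purrr::list_rbind(series)
  attr(out, "ground_truth") <- truths
  as_titration(out, protein_conc_M = config$protein_conc_M,
               excitation_nm = config$excitation_nm)
}

#' Ground truth of a simulated series
#'
#' @param x A simulated titration (or one read back from a fixture file).
#' @return The generating parameter list, or `NULL` for real data.
#' @export
ground_truth <- function(x) attr(x, "ground_truth", exact = TRUE)

#' Write a titration fixture CSV
#'
#' Emits the long-format titration CSV dialect, preceded by a commented
#' header block (`# key: value`) carrying the series metadata and, for
#' simulated data, the generating ground truth. [read_titration_csv()]
#' restores both, so write-then-read round-trips the series to 15
#' significant digits.
#'
#' @param titr A titration tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fixture <- function(titr, path) {
  truth <- ground_truth(titr)
  lines <- c()
  meta <- list(protein_conc_M = attr(titr, "protein_conc_M"),
               excitation_nm = attr(titr, "excitation_nm"))
  for (k in names(meta)) {
    if (!is.null(meta[[k]]) && !is.na(meta[[k]])) {
      lines <- c(lines, sprintf("# %s: %s", k, format(meta[[k]], digits = 15)))
    }
  }
  if (!is.null(truth)) {
    flat <- if (!is.null(truth$series_id)) list(truth) else truth
    for (tr in flat) {
      keep <- tr[!vapply(tr, is.null, logical(1))]
      kv <- paste(names(keep),
                  vapply(keep, function(v) format(v, digits = 15), character(1)),
                  sep = "=", collapse = "; ")
      lines <- c(lines, paste0("# truth: ", kv))
    }
  }
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con)
  df <- as.data.frame(titr)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) format(v, digits = 15, trim = TRUE,
                                                scientific = NA))
  writeLines(paste(names(df), collapse = ","), con)
  writeLines(do.call(paste, c(unname(df), sep = ",")), con)
  invisible(path)
}

parse_fixture_header <- function(path) {
  lines <- readLines(path, n = 50, warn = FALSE)
  lines <- lines[startsWith(lines, "#")]
  out <- list(ground_truth = NULL)
  truths <- list()
  for (ln in lines) {
    body <- sub("^#\\s*", "", ln)
    if (startsWith(body, "truth:")) {
      kvs <- strsplit(sub("^truth:\\s*", "", body), ";\\s*")[[1]]
      tr <- list()
      for (kv in kvs) {
        parts <- strsplit(kv, "=", fixed = TRUE)[[1]]
        key <- trimws(parts[1])
        val <- trimws(paste(parts[-1], collapse = "="))
        numval <- suppressWarnings(as.numeric(val))
        tr[[key]] <- if (is.na(numval)) val else numval
      }
      truths[[length(truths) + 1]] <- tr
    } else if (grepl(":", body, fixed = TRUE)) {
      parts <- strsplit(body, ":", fixed = TRUE)[[1]]
      key <- trimws(parts[1])
      val <- suppressWarnings(as.numeric(trimws(paste(parts[-1], collapse = ":"))))
      if (!is.na(val)) out[[key]] <- val
    }
  }
  if (length(truths) == 1) {
    out$ground_truth <- truths[[1]]
  } else if (length(truths) > 1) {
    names(truths) <- purrr::map_chr(truths, function(tr) as.character(tr$series_id))
    out$ground_truth <- truths
  }
  out
}
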