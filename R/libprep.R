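#' Library preparation computations
#'
#' Amplicons are quantified fluorometrically against an 8-point DNA standard
#' series (0-100 ng/ul), converted to molecules/ul via their lengths, and
#' combined into two pools (the 5 shortest amplicons in the short pool, the
#' remaining 12 in the long pool) with a fixed number of molecules per
#' amplicon, scaled by the per-amplicon pooling factor.
#'
#' @name libprep
NULL

#' Fit a quantification standard curve
#'
#' Ordinary least-squares fit of fluorescence signal against known standard
#' concentrations, with the coefficient of determination as run QC
#' (validation criterion `r_squared > threshold`).
#'
#' @param standards A data frame with columns `conc` (ng/ul) and `signal`.
#' @param threshold QC bound on r-squared (default 0.98).
#' @return An object of class `standard_curve`: `slope`, `intercept`
#'   (signal per ng/ul), `r_squared`, `pass`, `threshold`, `n`.
#' @export
fit_standard_curve <- function(standards, threshold = 0.98) {
  stopifnot(all(c("conc", "signal") %in% names(standards)))
  if (nrow(standards) < 2) abort("need at least 2 standards")
  if (length(unique(standards$conc)) < 2) {
    abort("degenerate standard series: all concentrations identical")
  }
  fit <- stats::lm(signal ~ conc, data = standards)
  # summary.lm warns on exactly collinear (noise-free) standards; harmless
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(
    list(
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      r_squared = r2,
      threshold = threshold,
      pass = r2 > threshold,
      n = nrow(standards)
    ),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("<standard_curve> signal = %.4g * conc + %.4g, r2 = %.4f [%s]\n",
              x$slope, x$intercept, x$r_squared,
              if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' @rdname fit_standard_curve
#' @param x A `standard_curve`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.standard_curve <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept, r_squared = x$r_squared,
         threshold = x$threshold, pass = x$pass, n = x$n)
}

#' Convert signals to concentrations with a standard curve
#'
#' @param curve A `standard_curve`.
#' @param signal Numeric vector of fluorescence signals.
#' @return Concentrations in ng/ul (clamped at 0).
#' @export
signal_to_concentration <- function(curve, signal) {
  pmax(0, (signal - curve$intercept) / curve$slope)
}

#' Convert a dsDNA concentration to molecules per microliter
#'
#' `molecules/ul = conc[ng/ul] * 1e-9 / (length * m_bp) * N_A`, with the
#' average double-stranded base-pair mass `m_bp` = 660 g/mol/bp.
#'
#' @param conc Concentration in ng/ul (vectorised).
#' @param length Amplicon length in bp.
#' @param bp_mass Average base-pair mass in g/mol/bp.
#' @return Molecules per microliter.
#' @examples
#' concentration_to_molecules(100, 500)  # ~1.825e11
#' @export
concentration_to_molecules <- function(conc, length, bp_mass = 660) {
  if (any(length <= 0)) abort("amplicon length must be positive")
  if (any(conc < 0)) abort("concentration must be >= 0")
  conc * 1e-9 / (length * bp_mass) * 6.02214076e23
}

#' Compute the two-pool equimolar pooling plan
#'
#' Each amplicon contributes `pooling_factor * base_molecules` molecules to
#' its pool; the pipetted volume is that target divided by the measured
#' molecules/ul. Amplicons with no measurable product are flagged `failed`
#' (for re-PCR), not silently dropped; volumes above `max_volume` are flagged
#' `low_yield` but never rescaled.
#'
#' @param quants A data frame with columns `amplicon` and `conc` (ng/ul),
#'   one row per panel amplicon.
#' @param panel An `hla_panel`.
#' @param base_molecules Molecules per factor-1 amplicon (default 1e9).
#' @param max_volume Warning threshold in ul (default 20).
#' @param bp_mass Average base-pair mass, g/mol/bp.
#' @return A tibble (class `pool_plan`): `amplicon`, `pool`,
#'   `pooling_factor`, `conc`, `molecules_per_ul`, `target_molecules`,
#'   `volume_ul`, `status`. Attributes `base_molecules` and
#'   `dilution_target_molecules` (5e5, the final library dilution) carry the
#'   plan metadata.
#' @export
compute_pool_plan <- function(quants, panel, base_molecules = 1e9,
                              max_volume = 20, bp_mass = 660) {
  stopifnot(all(c("amplicon", "conc") %in% names(quants)))
  amp <- panel$amplicons
  missing <- setdiff(amp$amplicon, quants$amplicon)
  if (length(missing) > 0) {
    abort(sprintf("no quantification for amplicon(s): %s",
                  paste(missing, collapse = ", ")))
  }
  plan <- amp |>
    dplyr::select("amplicon", "pool", "pooling_factor", "length") |>
    dplyr::left_join(quants[c("amplicon", "conc")], by = "amplicon") |>
    dplyr::mutate(
      molecules_per_ul = concentration_to_molecules(.data$conc, .data$length,
                                                    bp_mass),
      target_molecules = .data$pooling_factor * base_molecules,
      volume_ul = ifelse(.data$molecules_per_ul > 0,
                         .data$target_molecules / .data$molecules_per_ul,
                         NA_real_),
      status = dplyr::case_when(
        molecules_per_ul <= 0 ~ "failed",
        volume_ul > max_volume ~ "low_yield",
        TRUE ~ "ok"
      )
    ) |>
    dplyr::select(-"length")
  attr(plan, "base_molecules") <- base_molecules
  attr(plan, "dilution_target_molecules") <- 5e5
  class(plan) <- c("pool_plan", class(plan))
  plan
}

#' Write a pooling plan with its QC block
#'
#' Emits the plan as TSV plus a JSON sidecar carrying the standard-curve QC
#' (r-squared, threshold, pass/fail) and the plan metadata.
#'
#' @param plan A `pool_plan`.
#' @param curve The `standard_curve` used for quantification.
#' @param path Output TSV path (the JSON sidecar gets extension `.json`).
#' @return `path`, invisibly.
#' @export
write_pool_plan <- function(plan, curve, path) {
  readr::write_tsv(as_tibble(plan), path)
  qc <- list(
    qc = glance.standard_curve(curve),
    base_molecules = attr(plan, "base_molecules"),
    dilution_target_molecules = attr(plan, "dilution_target_molecules")
  )
  jsonlite::write_json(qc, sub("\\.tsv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
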