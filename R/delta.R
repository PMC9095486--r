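# Characterization of unknown mass shifts by bounded composition search.

#' Mass difference between an observed and a predicted species
#'
#' @param observed,predicted Neutral monoisotopic masses in Da.
#' @param units `"Da"` or `"mmu"` (millimass units, 1 mmu = 1e-3 Da).
#' @return The signed difference `observed - predicted`.
#' @examples
#' mass_delta(79.97067, comp_mass("HPO3"), "mmu") # 4.35 mmu
#' @export
mass_delta <- function(observed, predicted, units = c("Da", "mmu")) {
  units <- match.arg(units)
  d <- observed - predicted
  if (units == "mmu") d * 1000 else d
}

#' Round half away from zero
#'
#' Presentation-layer rounding (4.35 mmu prints as 4.4), as opposed to the
#' round-half-even convention of [base::round()].
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Search elemental compositions explaining a mass shift
#'
#' Exhaustively enumerates compositions over C, H, N, O, P, S within
#' element-count bounds and returns every composition whose monoisotopic
#' mass lies within `tol_mmu` of the target shift, sorted by absolute error
#' and then total atom count. The default bounds are sized for
#' single-residue modifications. The search is complete: any in-bounds
#' composition is found when its exact mass is queried.
#'
#' @param delta Target mass shift in Da.
#' @param tol_mmu Tolerance in millimass units (1e-3 Da).
#' @param bounds Named integer vector of maximum element counts.
#' @return A tibble with columns `formula`, `C`, `H`, `N`, `O`, `P`, `S`,
#'   `mass`, `error_mmu` (signed, candidate subtracted from target),
#'   `error_ppm`, `n_atoms`. Zero rows if nothing matches; a zero-mass
#'   query returns the empty composition.
#' @examples
#' formula_search(79.97067, tol_mmu = 10) # HPO3 on top, +4.35 mmu error
#' @export
formula_search <- function(delta, tol_mmu = 10,
                           bounds = c(C = 10, H = 20, N = 5, O = 10, P = 2, S = 2)) {
  if (tol_mmu <= 0) {
    rlang::abort("`tol_mmu` must be positive.")
  }
  if (!all(ELEMENTS %in% names(bounds))) {
    rlang::abort("`bounds` must name all of C, H, N, O, P, S.")
  }
  grid <- expand.grid(purrr::map(
    as.list(bounds[ELEMENTS]), ~ 0:.x
  ), KEEP.OUT.ATTRS = FALSE)
  mass <- as.matrix(grid) %*% ATOMIC_MASSES[ELEMENTS]
  err_mmu <- (delta - mass) * 1000
  keep <- abs(err_mmu) <= tol_mmu
  grid <- grid[keep, , drop = FALSE]
  out <- tibble::as_tibble(grid)
  out$mass <- as.numeric(mass[keep])
  out$error_mmu <- as.numeric(err_mmu[keep])
  out$error_ppm <- ifelse(out$mass > 0, out$error_mmu / out$mass * 1000, NA_real_)
  out$n_atoms <- rowSums(grid)
  out$formula <- purrr::pmap_chr(
    out[ELEMENTS],
    function(...) format_formula(elem_comp(c(...)))
  )
  out <- out[order(abs(out$error_mmu), out$n_atoms), ]
  out[c("formula", ELEMENTS, "mass", "error_mmu", "error_ppm", "n_atoms")]
}
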