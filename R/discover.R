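# End-to-end discovery workflow: digest a reference sequence, explain
# observed precursors, characterize the mass shift, localize it by CID
# and quantify its stoichiometry.

#' Validated run configuration
#'
#' Bundles the tolerances and instrument conventions shared across the
#' pipeline stages, with the package defaults documented in one place:
#' 10 ppm precursor / 20 ppm product-ion tolerance (Orbitrap-class
#' accuracy), 10 mmu composition-search tolerance, negative polarity,
#' singly charged product ions.
#'
#' @param tol_ppm_precursor,tol_ppm_product Match tolerances in ppm.
#' @param tol_mmu Composition-search tolerance in millimass units.
#' @param enzyme Digestion enzyme.
#' @param charges Product-ion charge states.
#' @param polarity `"-"` or `"+"`.
#' @param seed Seed recorded in reports.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(tol_ppm_precursor = 10, tol_ppm_product = 20,
                       tol_mmu = 10, enzyme = "T1", charges = 1L,
                       polarity = "-", seed = 1L) {
  stopifnot(
    tol_ppm_precursor > 0, tol_ppm_product > 0, tol_mmu > 0,
    enzyme %in% c("T1", "A", "I", "P1"),
    all(charges >= 1), polarity %in% c("-", "+")
  )
  structure(
    list(
      tol_ppm_precursor = tol_ppm_precursor,
      tol_ppm_product = tol_ppm_product,
      tol_mmu = tol_mmu, enzyme = enzyme, charges = as.integer(charges),
      polarity = polarity, seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

#' Discover and characterize an unknown modification
#'
#' Runs the discovery workflow end to end: digests the reference sequence
#' in silico, assigns each observed CID spectrum's precursor to the
#' digest fragment that minimizes the residual mass shift, characterizes
#' that shift by bounded composition search, localizes it within the
#' fragment from the c/y product ions, and (when an XIC table is given)
#' reports the modification stoichiometry.
#'
#' The reference sequence carries the known modifications but not the
#' unknown one, so a genuinely modified fragment shows up as a precursor
#' whose observed neutral mass exceeds the prediction by the
#' modification's mass.
#'
#' @param seq Reference `mod_seq` (without the unknown modification).
#' @param spectra List of `spectrum` objects with precursor annotations
#'   (`precursor_mz`, `precursor_z`).
#' @param xic Optional XIC table for [stoichiometry()].
#' @param config A [run_config()].
#' @param max_delta Largest unexplained shift considered (Da).
#' @param bases Candidate residue codes for localization (default the
#'   uridine family, the base class of the discovery).
#' @return A `discovery_report`: list with `assignments` (one row per
#'   spectrum: fragment, observed/predicted mass, delta in Da and mmu, top
#'   composition, localized site in parent coordinates, ambiguity flag),
#'   `localizations` (per-spectrum position tables), `stoichiometry`, and
#'   the configuration.
#' @export
discover <- function(seq, spectra, xic = NULL, config = run_config(),
                     max_delta = 150, bases = NULL) {
  seq <- mod_seq(seq)
  if (inherits(spectra, "spectrum")) spectra <- list(spectra)
  d <- digest(seq, config$enzyme)
  d <- d[d$length >= 2, ]
  if (is.null(bases)) {
    reg <- mod_registry()
    bases <- reg$code[reg$family == "U"]
  }
  loc_tables <- list()
  rows <- purrr::imap_dfr(spectra, function(sp, name) {
    pm <- attr(sp, "precursor_mz")
    pz <- attr(sp, "precursor_z")
    if (is.null(pm) || is.null(pz)) {
      rlang::abort("Every spectrum needs precursor_mz and precursor_z.")
    }
    observed <- mass_from_mz(pm, pz, spec_polarity(sp))
    deltas <- observed - d$mass
    ok <- which(abs(deltas) <= max_delta)
    if (length(ok) == 0) {
      return(tibble::tibble(
        spectrum = as.character(name), fragment = NA_character_,
        start = NA_integer_, end = NA_integer_,
        observed_mass = observed, predicted_mass = NA_real_,
        delta_da = NA_real_, formula = NA_character_,
        formula_error_mmu = NA_real_, site = NA_integer_,
        site_base = NA_character_, ambiguous = NA
      ))
    }
    best <- ok[which.min(abs(deltas[ok]))]
    frag <- d$fragment[[best]]
    delta <- deltas[best]
    cand <- formula_search(delta, tol_mmu = config$tol_mmu)
    loc <- localize_delta(
      frag, sp, delta,
      tol_ppm = config$tol_ppm_product,
      charges = config$charges, bases = bases
    )
    loc$parent_position <- loc$position + attr(frag, "start") - 1L
    loc_tables[[as.character(name)]] <<- loc
    top <- loc[loc$top, ]
    tibble::tibble(
      spectrum = as.character(name),
      fragment = d$seq[best],
      start = d$start[best], end = d$end[best],
      observed_mass = observed, predicted_mass = d$mass[best],
      delta_da = delta,
      formula = if (nrow(cand) > 0) cand$formula[1] else NA_character_,
      formula_error_mmu = if (nrow(cand) > 0) cand$error_mmu[1] else NA_real_,
      site = top$parent_position[1],
      site_base = top$base[1],
      ambiguous = nrow(top) > 1
    )
  })
  stoich <- if (!is.null(xic)) stoichiometry(xic) else NULL
  structure(
    list(
      assignments = rows,
      localizations = loc_tables,
      stoichiometry = stoich,
      config = config
    ),
    class = "discovery_report"
  )
}

#' @export
print.discovery_report <- function(x, ...) {
  cat("== Modification discovery report ==\n")
  a <- x$assignments
  hit <- a[!is.na(a$delta_da) & abs(a$delta_da) > 0.5, ]
  cat(sprintf(
    "%d spectra analyzed; %d carry an unexplained mass shift\n",
    nrow(a), nrow(hit)
  ))
  for (i in seq_len(nrow(hit))) {
    cat(sprintf(
      "  %s: fragment %s (%d-%d), delta %.5f Da -> %s (%.1f mmu), site %d (%s)%s\n",
      hit$spectrum[i], hit$fragment[i], hit$start[i], hit$end[i],
      hit$delta_da[i], hit$formula[i],
      round_half_up(hit$formula_error_mmu[i], 1),
      hit$site[i], hit$site_base[i],
      if (isTRUE(hit$ambiguous[i])) " [ambiguous]" else ""
    ))
  }
  if (!is.null(x$stoichiometry)) {
    s <- x$stoichiometry
    for (i in seq_len(nrow(s))) {
      cat(sprintf(
        "  stoichiometry %s [%s]: %.1f%%\n",
        s$site[i], s$condition[i], s$percent[i]
      ))
    }
  }
  invisible(x)
}
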