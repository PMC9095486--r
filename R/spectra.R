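# CID c/y-ion ladder prediction, peak matching, site localization and
# shotgun fragment identification.

MASS_HPO3 <- function() comp_mass("HPO3")
MASS_H2O <- function() comp_mass("H2O")

#' Construct a spectrum
#'
#' A `spectrum` is a tibble of `(mz, intensity)` peaks sorted by m/z, with
#' polarity and optional precursor information as attributes.
#'
#' @param peaks A data frame with columns `mz` and `intensity`.
#' @param polarity `"+"` or `"-"` (negative mode is the RNA default).
#' @param precursor_mz,precursor_z Optional precursor ion annotation.
#' @return A `spectrum` tibble.
#' @export
spectrum <- function(peaks, polarity = c("-", "+"),
                     precursor_mz = NULL, precursor_z = NULL) {
  polarity <- match.arg(polarity)
  peaks <- tibble::as_tibble(peaks)[c("mz", "intensity")]
  if (nrow(peaks) > 0 &&
    (any(!is.finite(peaks$mz)) || any(!is.finite(peaks$intensity)) ||
      any(peaks$intensity < 0))) {
    rlang::abort("Peak m/z and intensities must be finite; intensities >= 0.")
  }
  peaks <- peaks[order(peaks$mz), ]
  tibble::new_tibble(
    peaks,
    polarity = polarity,
    precursor_mz = precursor_mz,
    precursor_z = precursor_z,
    class = "spectrum"
  )
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf(
    "<spectrum> %d peaks, polarity %s\n", nrow(x), attr(x, "polarity")
  ))
  NextMethod()
}

spec_polarity <- function(x) attr(x, "polarity") %||% "-"

#' Predict the CID c/y fragment-ion ladder of a digestion fragment
#'
#' Collision-induced dissociation of an oligonucleotide cleaves the
#' backbone into complementary c ions (5' side, ending in a 3'-phosphate)
#' and y ions (3' side, starting with a 5'-OH). For a fragment of length n
#' the ladder holds neutral masses c_1..c_(n-1) and y_1..y_(n-1); by
#' construction M(c_i) + M(y_(n-i)) = M(fragment) + M(H2O) for every i.
#'
#' @param frag A `mod_fragment` (or `mod_seq`) of length >= 2.
#' @return A `cid_ladder` tibble with columns `ion`, `series`, `index`,
#'   `neutral_mass`, carrying the fragment as an attribute.
#' @export
cid_ladder <- function(frag) {
  frag <- mod_seq(frag)
  n <- nrow(frag)
  if (n < 2) {
    rlang::abort("A CID ladder needs a fragment of length >= 2.")
  }
  res_mass <- purrr::pmap_dbl(
    list(frag$base, frag$sugar2p, frag$adducts), residue_mass
  )
  link <- MASS_HPO3() - MASS_H2O()
  term <- seq_termini(frag)
  t5 <- if (term[["five_prime"]] == "P") MASS_HPO3() else 0
  t3 <- switch(term[["three_prime"]],
    OH = 0, P = MASS_HPO3(), cycP = MASS_HPO3() - MASS_H2O()
  )
  i <- seq_len(n - 1)
  c_mass <- cumsum(res_mass)[i] + (i - 1) * link + t5 + MASS_HPO3()
  y_mass <- rev(cumsum(rev(res_mass)))[i + 1] + (n - i - 1) * link + t3
  # y_mass above is y_(n-i); re-index so row j is y_j
  y_mass <- rev(y_mass)
  out <- tibble::tibble(
    ion = c(paste0("c", i), paste0("y", i)),
    series = rep(c("c", "y"), each = n - 1),
    index = c(i, i),
    neutral_mass = c(c_mass, y_mass)
  )
  tibble::new_tibble(out, fragment = frag, class = "cid_ladder")
}

#' Match a predicted ladder against an observed spectrum
#'
#' Every predicted ion (each ladder entry at each charge in `charges`,
#' spectrum polarity) is matched to the nearest observed peak; the match is
#' kept when the error is within `tol_ppm`. One observed peak may satisfy
#' several predicted ions — all assignments are reported. Coverage is the
#' fraction of predicted ions that found a peak.
#'
#' @param ladder A `cid_ladder`.
#' @param spec A `spectrum`.
#' @param tol_ppm Match tolerance in ppm (default 20, product-ion accuracy
#'   of an Orbitrap-class instrument).
#' @param charges Integer vector of product-ion charge states.
#' @return A `match_report` tibble with columns `ion`, `series`, `index`,
#'   `charge`, `predicted_mz`, `observed_mz`, `error_ppm`, `intensity`,
#'   `matched`; the coverage is available via [coverage()].
#' @export
match_peaks <- function(ladder, spec, tol_ppm = 20, charges = 1L) {
  if (tol_ppm <= 0) {
    rlang::abort("`tol_ppm` must be positive.")
  }
  if (nrow(spec) == 0) {
    rlang::abort("Cannot match against an empty spectrum.")
  }
  polarity <- spec_polarity(spec)
  pred <- tidyr::crossing(
    tibble::as_tibble(ladder),
    charge = as.integer(charges)
  )
  pred$predicted_mz <- mz(pred$neutral_mass, pred$charge, polarity)
  fi <- findInterval(pred$predicted_mz, spec$mz)
  lo <- pmax(fi, 1L)
  hi <- pmin(fi + 1L, length(spec$mz))
  d_lo <- abs(pred$predicted_mz - spec$mz[lo])
  d_hi <- abs(pred$predicted_mz - spec$mz[hi])
  idx <- ifelse(fi == 0L, hi, ifelse(d_hi < d_lo, hi, lo))
  obs_mz <- spec$mz[idx]
  err <- (obs_mz - pred$predicted_mz) / pred$predicted_mz * 1e6
  matched <- abs(err) <= tol_ppm
  out <- tibble::tibble(
    ion = pred$ion,
    series = pred$series,
    index = pred$index,
    charge = pred$charge,
    predicted_mz = pred$predicted_mz,
    observed_mz = ifelse(matched, obs_mz, NA_real_),
    error_ppm = ifelse(matched, err, NA_real_),
    intensity = ifelse(matched, spec$intensity[idx], NA_real_),
    matched = matched
  )
  tibble::new_tibble(
    out,
    coverage = mean(matched),
    tol_ppm = tol_ppm,
    class = "match_report"
  )
}

#' Coverage of a match report
#'
#' @param x A `match_report`.
#' @return Fraction of predicted ions matched, in `[0, 1]`.
#' @export
coverage <- function(x) attr(x, "coverage")

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf(
    "<match_report> coverage %.3f at %.1f ppm\n",
    coverage(x), attr(x, "tol_ppm")
  ))
  NextMethod()
}

#' Localize an unknown mass shift within a fragment
#'
#' Places a mass delta on each candidate residue in turn, rebuilds the c/y
#' ladder, and scores the placement by the number of matched product ions
#' (ties broken by summed absolute ppm error, then by lower position).
#' Returns every candidate, flagging as `top` all positions whose score is
#' within `margin` ions of the best — ties are reported as a set, never
#' silently resolved, because positional ambiguity is resolved chemically,
#' not computationally.
#'
#' @param frag_unmod The unmodified `mod_fragment`.
#' @param spec Observed `spectrum` of the modified species.
#' @param delta Mass shift in Da (e.g. 79.96632 for a phosphate).
#' @param tol_ppm Product-ion tolerance in ppm.
#' @param charges Product-ion charge states.
#' @param bases Optional residue-code restriction for candidate positions
#'   (e.g. `"U"` to consider only uridines).
#' @param margin Report as `top` every position within this many matched
#'   ions of the best score.
#' @return A tibble with columns `position`, `base`, `n_matched`,
#'   `sum_abs_ppm`, `top`, sorted best first.
#' @export
localize_delta <- function(frag_unmod, spec, delta, tol_ppm = 20,
                           charges = 1L, bases = NULL, margin = 0) {
  frag <- mod_seq(frag_unmod)
  n <- nrow(frag)
  if (n < 2) {
    rlang::abort("Localization needs a fragment of length >= 2.")
  }
  ladder <- cid_ladder(frag)
  cand <- seq_len(n)
  if (!is.null(bases)) {
    cand <- cand[frag$base[cand] %in% bases]
  }
  scores <- purrr::map_dfr(cand, function(p) {
    shifted <- ladder
    shifted$neutral_mass <- ladder$neutral_mass +
      delta * ((ladder$series == "c" & ladder$index >= p) |
        (ladder$series == "y" & ladder$index >= n - p + 1))
    rep <- match_peaks(shifted, spec, tol_ppm = tol_ppm, charges = charges)
    tibble::tibble(
      position = p,
      base = frag$base[p],
      n_matched = sum(rep$matched),
      sum_abs_ppm = sum(abs(rep$error_ppm), na.rm = TRUE)
    )
  })
  scores <- dplyr::arrange(
    scores,
    dplyr::desc(.data$n_matched), .data$sum_abs_ppm, .data$position
  )
  scores$top <- scores$n_matched >= max(scores$n_matched) - margin
  scores
}

#' Identify digest fragments from observed precursor ions
#'
#' Matches every observed precursor against all in-silico digest fragments
#' of a sequence set, optionally also against a hypothesized
#' 2'-phosphorylated variant (+HPO3) of every fragment that contains a
#' uridine with a free 2'-OH — the shotgun screen used to detect a
#' 2'-phosphouridine across tRNA species. Ambiguous matches (isomeric or
#' isobaric fragments) are all listed, never collapsed.
#'
#' @param precursors A tibble with columns `mz` and `z` (and optionally
#'   `polarity`, defaulting to negative).
#' @param seqs A `mod_seq` or list of them.
#' @param enzyme Digestion enzyme (see [digest()]).
#' @param tol_ppm Precursor tolerance in ppm (default 10).
#' @param missed Missed cleavages for the digest.
#' @param add_2p_variants Also hypothesize a +HPO3 variant on U-containing
#'   fragments.
#' @return A tibble of assignments: `sequence`, `fragment`, `start`, `end`,
#'   `variant_2p`, `charge`, `predicted_mz`, `observed_mz`, `ppm`.
#' @export
identify_fragments <- function(precursors, seqs, enzyme = "T1",
                               tol_ppm = 10, missed = 0L,
                               add_2p_variants = TRUE) {
  if (inherits(seqs, "mod_seq")) seqs <- list(seqs)
  if (length(seqs) == 0) {
    rlang::abort("`seqs` must contain at least one sequence.")
  }
  cand <- purrr::map_dfr(seqs, function(s) {
    d <- digest(s, enzyme, missed = missed)
    base <- tibble::tibble(
      sequence = seq_id(s), fragment = d$seq, start = d$start, end = d$end,
      variant_2p = FALSE, neutral_mass = d$mass
    )
    if (add_2p_variants) {
      reg <- mod_registry()
      u_codes <- reg$code[reg$family == "U"]
      has_u <- purrr::map_lgl(
        d$fragment,
        ~ any(.x$base %in% u_codes & .x$sugar2p == "OH")
      )
      var <- base[has_u, ]
      var$variant_2p <- TRUE
      var$neutral_mass <- var$neutral_mass + MASS_HPO3()
      base <- dplyr::bind_rows(base, var)
    }
    base
  })
  empty <- tibble::tibble(
    sequence = character(), fragment = character(),
    start = integer(), end = integer(), variant_2p = logical(),
    charge = integer(), predicted_mz = double(),
    observed_mz = double(), ppm = double()
  )
  if (is.null(precursors) || nrow(precursors) == 0) {
    return(empty)
  }
  if (!"polarity" %in% names(precursors)) {
    precursors$polarity <- "-"
  }
  hits <- purrr::pmap_dfr(
    list(precursors$mz, precursors$z, precursors$polarity),
    function(obs_mz, z, polarity) {
      pred_mz <- mz(cand$neutral_mass, z, polarity)
      ppm <- (obs_mz - pred_mz) / pred_mz * 1e6
      keep <- abs(ppm) <= tol_ppm
      if (!any(keep)) {
        return(empty)
      }
      out <- cand[keep, c("sequence", "fragment", "start", "end", "variant_2p")]
      out$charge <- as.integer(z)
      out$predicted_mz <- pred_mz[keep]
      out$observed_mz <- obs_mz
      out$ppm <- ppm[keep]
      out
    }
  )
  hits
}
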