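# In-silico ribonuclease digestion and chemical-treatment transforms.
#
# RNase T1/A/I cleave 3' of their target bases through the 2'-OH
# (transesterification): a 2'-O-methyl or 2'-phosphate on the residue 5' of
# the bond blocks cleavage. Nuclease P1 hydrolyses every linkage except 3'
# of a 2'-phosphorylated residue, which is why a 2'-phosphouridine survives
# a P1 digest as a diagnostic dinucleotide.

#' Construct a digestion fragment
#'
#' A `mod_fragment` is a `mod_seq` that remembers where it came from:
#' parent id, 1-based inclusive start/end coordinates and the number of
#' permitted-but-skipped internal cleavage sites.
#'
#' @param parent A `mod_seq`.
#' @param start,end 1-based inclusive positions in the parent.
#' @param five_prime,three_prime Terminal chemistry of the fragment.
#' @param missed Count of internal missed cleavages.
#' @return A `mod_fragment`.
#' @export
mod_fragment <- function(parent, start, end,
                         five_prime = "OH", three_prime = "OH",
                         missed = 0L) {
  parent <- mod_seq(parent)
  n <- nrow(parent)
  if (start < 1 || end > n || start > end) {
    rlang::abort(sprintf(
      "Fragment coordinates [%d, %d] out of range for a %d-nt parent.",
      start, end, n
    ))
  }
  res <- tibble::as_tibble(parent[start:end, ])
  out <- new_mod_seq(
    res,
    id = sprintf("%s:%d-%d", seq_id(parent), start, end),
    five_prime = five_prime, three_prime = three_prime,
    class = "mod_fragment"
  )
  attr(out, "parent_id") <- seq_id(parent)
  attr(out, "start") <- as.integer(start)
  attr(out, "end") <- as.integer(end)
  attr(out, "missed") <- as.integer(missed)
  out
}

#' @rdname mod_fragment
#' @param x A `mod_fragment`.
#' @return `fragment_coords()` a named integer vector `start`, `end`,
#'   `missed`, plus the parent id as an attribute-free list element.
#' @export
fragment_coords <- function(x) {
  list(
    parent_id = attr(x, "parent_id"),
    start = attr(x, "start"),
    end = attr(x, "end"),
    missed = attr(x, "missed")
  )
}

enzyme_target_codes <- function(enzyme, t1_bases = NULL, a_bases = NULL) {
  reg <- mod_registry()
  switch(enzyme,
    T1 = if (is.null(t1_bases)) reg$code[reg$family == "G"] else t1_bases,
    A = if (is.null(a_bases)) reg$code[reg$family %in% c("C", "U")] else a_bases,
    I = reg$code,
    P1 = reg$code,
    rlang::abort(sprintf("Unknown enzyme '%s'.", enzyme))
  )
}

#' Which internucleotide bonds does an enzyme cut?
#'
#' Bond `i` joins residues `i` and `i + 1`. A bond is cut when the residue
#' 5' of it is an enzyme target and its 2'-sugar state does not block the
#' chemistry: RNase T1/A/I require a free 2'-OH on that residue, nuclease
#' P1 is blocked only by a 2'-phosphate.
#'
#' @inheritParams digest
#' @return Logical vector of length `nrow(seq) - 1`.
#' @export
cleavage_sites <- function(seq, enzyme = c("T1", "A", "I", "P1"),
                           t1_bases = NULL, a_bases = NULL) {
  enzyme <- match.arg(enzyme)
  seq <- mod_seq(seq)
  n <- nrow(seq)
  if (n < 2) {
    return(logical(0))
  }
  base5 <- seq$base[seq_len(n - 1)]
  sugar5 <- seq$sugar2p[seq_len(n - 1)]
  target <- base5 %in% enzyme_target_codes(enzyme, t1_bases, a_bases)
  blocked <- if (enzyme == "P1") sugar5 == "P" else sugar5 != "OH"
  target & !blocked
}

#' Digest a modified RNA in silico
#'
#' Cleaves 3' of target residues — RNase T1 after guanosine-family bases,
#' RNase A after pyrimidine-family bases, RNase I after every base,
#' nuclease P1 after every linkage — subject to the 2'-sugar-state blocking
#' rules of [cleavage_sites()]. T1/A/I products carry a 3'-phosphate (or
#' 2',3'-cyclic phosphate when `cyclic = TRUE`) and a 5'-OH; P1 products
#' carry a 5'-phosphate and a 3'-OH. With `missed > 0`, fragments spanning
#' up to that many skipped sites are also emitted.
#'
#' @param seq A `mod_seq` (or bracket-dialect string).
#' @param enzyme `"T1"`, `"A"`, `"I"` or `"P1"`.
#' @param missed Maximum number of missed cleavages (default 0, complete
#'   digest).
#' @param cyclic Emit 2',3'-cyclic phosphate 3' ends for T1/A/I products.
#' @param t1_bases,a_bases Optional residue-code vectors overriding the
#'   default guanosine/pyrimidine target families.
#' @return A tibble with one row per fragment: `parent_id`, `start`, `end`,
#'   `length`, `missed`, `seq` (bracket dialect), `mass` (neutral Da) and a
#'   `fragment` list-column of `mod_fragment` objects. Complete-digest
#'   fragments tile the parent without gaps or overlap.
#' @examples
#' digest(mod_seq("AUCGACG"), "T1")
#' @export
digest <- function(seq, enzyme = c("T1", "A", "I", "P1"), missed = 0L,
                   cyclic = FALSE, t1_bases = NULL, a_bases = NULL) {
  enzyme <- match.arg(enzyme)
  if (missed < 0) {
    rlang::abort("`missed` must be a non-negative integer.")
  }
  seq <- mod_seq(seq)
  n <- nrow(seq)
  cut <- which(cleavage_sites(seq, enzyme, t1_bases, a_bases))
  bounds <- c(0L, cut, n) # fragment k runs (bounds[k]+1) .. bounds[k+1]
  term <- seq_termini(seq)
  three_internal <- if (enzyme == "P1") "OH" else if (cyclic) "cycP" else "P"
  five_internal <- if (enzyme == "P1") "P" else "OH"

  pieces <- list()
  nb <- length(bounds)
  for (i in seq_len(nb - 1)) {
    for (j in (i + 1):nb) {
      skipped <- j - i - 1L
      if (skipped > missed) break
      start <- bounds[i] + 1L
      end <- bounds[j]
      frag <- mod_fragment(
        seq, start, end,
        five_prime = if (start == 1) term[["five_prime"]] else five_internal,
        three_prime = if (end == n) term[["three_prime"]] else three_internal,
        missed = skipped
      )
      pieces[[length(pieces) + 1L]] <- frag
    }
  }
  tibble::tibble(
    parent_id = seq_id(seq),
    start = purrr::map_int(pieces, ~ attr(.x, "start")),
    end = purrr::map_int(pieces, ~ attr(.x, "end")),
    length = purrr::map_int(pieces, nrow),
    missed = purrr::map_int(pieces, ~ attr(.x, "missed")),
    seq = purrr::map_chr(pieces, render_mod_string),
    mass = purrr::map_dbl(pieces, oligo_mass),
    fragment = pieces
  )
}

#' Alkaline-phosphatase treatment of a fragment
#'
#' Removes terminal phosphomonoesters: 5'-P, 3'-P and 2',3'-cyclic
#' phosphate termini become OH. Internal 2'-phosphates are retained —
#' bacterial alkaline phosphatase does not reach them — which is exactly
#' what makes a BAP co-digest diagnostic for an internal 2'-phosphate.
#'
#' @param frag A `mod_seq` or `mod_fragment`.
#' @return The dephosphorylated object (same class). Idempotent.
#' @export
apply_phosphatase <- function(frag) {
  attr(frag, "five_prime") <- "OH"
  attr(frag, "three_prime") <- "OH"
  frag
}

#' Cyanoethylate pseudouridine residues
#'
#' Models acrylonitrile treatment: every pseudouridine (code `Y`) gains one
#' cyanoethyl adduct (+C3H3N, +53.02656 Da under the package mass table);
#' all other residues are untouched. This is how the mass-silent
#' pseudouridine is made visible to MS.
#'
#' @param seq A `mod_seq`.
#' @return The derivatized sequence.
#' @export
cyanoethylate <- function(seq) {
  is_psi <- seq$base == "Y"
  seq$adducts[is_psi] <- purrr::map(
    seq$adducts[is_psi], ~ c(.x, "cyanoethyl")
  )
  seq
}

#' Periodate oxidation followed by beta-elimination
#'
#' Removes the 3'-terminal nucleoside of a fragment whose 3' end presents a
#' vicinal diol (free 2'-OH and 3'-OH), leaving the exposed internucleotide
#' phosphate as a 3'-terminal phosphate on the shortened fragment. This is
#' the transform that converts the diagnostic P1 dimer pUp-m5C into the
#' mononucleotide pUp-p (a uridine carrying three phosphate groups).
#'
#' @param frag A `mod_seq` or `mod_fragment` of length at least 2.
#' @return The shortened fragment with a 3'-P terminus.
#' @export
periodate_beta_eliminate <- function(frag) {
  n <- nrow(frag)
  if (n < 2) {
    rlang::abort("Beta-elimination needs a fragment of length >= 2.")
  }
  term <- seq_termini(frag)
  if (term[["three_prime"]] != "OH" || frag$sugar2p[n] != "OH") {
    rlang::abort(paste(
      "Periodate oxidation is blocked: the 3'-terminal residue must carry",
      "a vicinal diol (free 2'-OH and 3'-OH)."
    ))
  }
  out <- frag[seq_len(n - 1), ]
  out <- new_mod_seq(
    tibble::as_tibble(out),
    id = seq_id(frag),
    five_prime = term[["five_prime"]],
    three_prime = "P",
    class = if (inherits(frag, "mod_fragment")) "mod_fragment" else character()
  )
  if (inherits(frag, "mod_fragment")) {
    attr(out, "parent_id") <- attr(frag, "parent_id")
    attr(out, "start") <- attr(frag, "start")
    attr(out, "end") <- attr(frag, "end") - 1L
    attr(out, "missed") <- attr(frag, "missed")
  }
  out
}
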