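# Elemental-composition arithmetic and monoisotopic mass / m/z computation.

# Monoisotopic atomic masses carried at 5 decimal places (10 uDa granularity),
# the precision convention of classic oligonucleotide mass calculators.
# With this table comp_mass(elem_comp("HPO3")) is exactly 79.96632 Da.
ATOMIC_MASSES <- c(
  C = 12.00000,
  H = 1.00783,
  N = 14.00307,
  O = 15.99491,
  P = 30.97376,
  S = 31.97207
)

ELEMENTS <- names(ATOMIC_MASSES)

# Electron-corrected proton mass, used for all charge-state arithmetic.
PROTON_MASS <- 1.00727646

#' Create an elemental composition
#'
#' An `elem_comp` is a named integer vector of element counts over
#' C, H, N, O, P and S, the bookkeeping unit behind every mass in the
#' package. Compositions add and subtract element-wise with `+` and `-`;
#' subtraction that would drive any count negative is an error.
#'
#' @param x A molecular formula string such as `"HPO3"` or `"C9H12N2O6"`,
#'   or a named numeric vector of element counts.
#' @return An `elem_comp` object.
#' @examples
#' elem_comp("HPO3")
#' elem_comp("C3H3N") + elem_comp("H2O")
#' @export
elem_comp <- function(x = character()) {
  if (inherits(x, "elem_comp")) {
    return(x)
  }
  counts <- stats::setNames(integer(length(ELEMENTS)), ELEMENTS)
  if (is.character(x)) {
    if (length(x) > 1) {
      rlang::abort("`x` must be a single formula string.")
    }
    if (length(x) == 1 && nzchar(x)) {
      tokens <- stringr::str_match_all(x, "([A-Z][a-z]?)(\\d*)")[[1]]
      tokens <- tokens[nzchar(tokens[, 1]), , drop = FALSE]
      if (sum(nchar(tokens[, 1])) != nchar(x)) {
        rlang::abort(sprintf("Cannot parse formula '%s'.", x))
      }
      for (i in seq_len(nrow(tokens))) {
        el <- tokens[i, 2]
        n <- if (nzchar(tokens[i, 3])) as.integer(tokens[i, 3]) else 1L
        if (!el %in% ELEMENTS) {
          rlang::abort(sprintf("Unknown element symbol '%s'.", el))
        }
        counts[el] <- counts[el] + n
      }
    }
  } else if (is.numeric(x)) {
    bad <- setdiff(names(x), ELEMENTS)
    if (length(bad) > 0 || is.null(names(x))) {
      rlang::abort(sprintf(
        "Unknown element symbol(s): %s.",
        paste(if (is.null(names(x))) "<unnamed>" else bad, collapse = ", ")
      ))
    }
    if (any(x < 0)) {
      rlang::abort("Element counts must be non-negative.")
    }
    counts[names(x)] <- as.integer(round(x))
  } else {
    rlang::abort("`x` must be a formula string or named count vector.")
  }
  structure(counts, class = "elem_comp")
}

#' @export
Ops.elem_comp <- function(e1, e2) {
  if (!.Generic %in% c("+", "-", "==")) {
    rlang::abort(sprintf("Operation '%s' is not defined for compositions.", .Generic))
  }
  a <- unclass(elem_comp(e1))
  b <- unclass(elem_comp(e2))
  if (.Generic == "==") {
    return(all(a == b))
  }
  out <- if (.Generic == "+") a + b else a - b
  if (any(out < 0)) {
    rlang::abort("Composition subtraction would give a negative element count.")
  }
  structure(out, class = "elem_comp")
}

#' @export
print.elem_comp <- function(x, ...) {
  cat("<elem_comp>", format_formula(x), sprintf("(%.5f Da)\n", comp_mass(x)))
  invisible(x)
}

#' Format a composition as a Hill-style formula string
#'
#' @param x An `elem_comp`.
#' @return A single string such as `"C9H12N2O6"`; the empty composition
#'   formats as `""`.
#' @export
format_formula <- function(x) {
  x <- unclass(elem_comp(x))
  x <- x[x > 0]
  if (length(x) == 0) {
    return("")
  }
  paste0(names(x), ifelse(x == 1, "", x), collapse = "")
}

#' Monoisotopic mass of an elemental composition
#'
#' Sums count times monoisotopic atomic mass over the composition.
#' Deterministic to full floating precision; the atomic masses are
#' IUPAC monoisotopic values carried at 5 decimal places.
#'
#' @param x An `elem_comp`, or anything `elem_comp()` accepts.
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' comp_mass("HPO3") # 79.96632
#' @export
comp_mass <- function(x) {
  counts <- unclass(elem_comp(x))
  sum(counts * ATOMIC_MASSES[names(counts)])
}

#' Convert a neutral mass to m/z and back
#'
#' `mz()` computes the mass-to-charge ratio of a protonated (`"+"`) or
#' deprotonated (`"-"`) species; `mass_from_mz()` is its inverse. The
#' proton mass used is 1.00727646 Da (electron-corrected).
#'
#' @param mass Neutral monoisotopic mass in Da.
#' @param z Positive integer charge.
#' @param polarity `"+"` or `"-"`.
#' @return m/z (or neutral mass) as a double.
#' @examples
#' mz(723.05916, 1, "+") # 724.07, the proton adduct of a pUp-m5C dimer
#' @export
mz <- function(mass, z = 1L, polarity = c("-", "+")) {
  polarity <- match.arg(polarity)
  if (any(z < 1) || any(z != round(z))) {
    rlang::abort("`z` must be a positive integer.")
  }
  sign <- if (polarity == "+") 1 else -1
  (mass + sign * z * PROTON_MASS) / z
}

#' @rdname mz
#' @param x An observed m/z value.
#' @export
mass_from_mz <- function(x, z = 1L, polarity = c("-", "+")) {
  polarity <- match.arg(polarity)
  if (any(z < 1) || any(z != round(z))) {
    rlang::abort("`z` must be a positive integer.")
  }
  sign <- if (polarity == "+") 1 else -1
  x * z - sign * z * PROTON_MASS
}

# Registry -------------------------------------------------------------------

the <- new.env(parent = emptyenv())

#' Modified-nucleoside registry
#'
#' The registry maps short residue codes (U, C, G, A, Y for pseudouridine,
#' s4U, m5C, m2G, m22G, m1A, ac4C, G+ for archaeosine, D, m5s2U, ...) to the
#' elemental composition of the free neutral nucleoside and to a parent-base
#' family used by the digestion rules. It ships as an editable TSV
#' (`system.file("extdata", "modifications.tsv", package = "rnamodms")`);
#' pass `path` to load a custom registry for the session.
#'
#' Pseudouridine (code `Y`) has the same composition as uridine: the
#' isomerization is mass-silent and only becomes visible after
#' cyanoethylation. Entries whose composition comes from standard
#' modification databases rather than first principles carry
#' `source = "modomics"`.
#'
#' @param path Optional path to a registry TSV with columns
#'   `code, name, family, C, H, N, O, P, S, source`.
#' @return A tibble, invisibly when `path` is supplied.
#' @export
mod_registry <- function(path = NULL) {
  if (!is.null(path)) {
    reg <- readr::read_tsv(path, show_col_types = FALSE)
    needed <- c("code", "name", "family", ELEMENTS)
    missing <- setdiff(needed, names(reg))
    if (length(missing) > 0) {
      rlang::abort(sprintf(
        "Registry is missing column(s): %s.", paste(missing, collapse = ", ")
      ))
    }
    if (anyDuplicated(reg$code)) {
      rlang::abort("Registry codes must be unique.")
    }
    the$registry <- reg
    return(invisible(reg))
  }
  if (is.null(the$registry)) {
    mod_registry(system.file("extdata", "modifications.tsv",
      package = "rnamodms",
      mustWork = TRUE
    ))
  }
  the$registry
}

registry_row <- function(code) {
  reg <- mod_registry()
  i <- match(code, reg$code)
  if (anyNA(i)) {
    rlang::abort(sprintf(
      "Unregistered residue code(s): %s. See mod_registry().",
      paste(unique(code[is.na(i)]), collapse = ", ")
    ))
  }
  reg[i, , drop = FALSE]
}

#' Composition and mass of a single residue
#'
#' A residue is a registered nucleoside plus a 2'-sugar state and optional
#' named adducts. The 2'-phosphate state adds exactly one HPO3; the
#' 2'-O-methyl state adds exactly one CH2; the cyanoethyl adduct (from
#' acrylonitrile treatment of pseudouridine) adds C3H3N.
#'
#' @param code Registered residue code.
#' @param sugar2p One of `"OH"`, `"OMe"`, `"P"`.
#' @param adducts Character vector of adduct names (currently `"cyanoethyl"`).
#' @return `residue_comp()` an `elem_comp`; `residue_mass()` a mass in Da.
#' @export
residue_comp <- function(code, sugar2p = "OH", adducts = character()) {
  row <- registry_row(code)
  comp <- elem_comp(stats::setNames(
    as.integer(row[1, ELEMENTS]), ELEMENTS
  ))
  comp <- comp + sugar_state_comp(sugar2p)
  for (a in adducts) {
    comp <- comp + adduct_comp(a)
  }
  comp
}

#' @rdname residue_comp
#' @export
residue_mass <- function(code, sugar2p = "OH", adducts = character()) {
  comp_mass(residue_comp(code, sugar2p, adducts))
}

sugar_state_comp <- function(sugar2p) {
  switch(sugar2p,
    OH = elem_comp(),
    OMe = elem_comp("CH2"),
    P = elem_comp("HPO3"),
    rlang::abort(sprintf("Unknown 2'-sugar state '%s'.", sugar2p))
  )
}

ADDUCTS <- list(cyanoethyl = "C3H3N")

adduct_comp <- function(name) {
  f <- ADDUCTS[[name]]
  if (is.null(f)) {
    rlang::abort(sprintf("Unknown adduct '%s'.", name))
  }
  elem_comp(f)
}
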