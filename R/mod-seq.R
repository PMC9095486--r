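# Modified RNA sequences: tibble-backed residue lists with terminal chemistry.

#' Construct a modified RNA sequence
#'
#' A `mod_seq` is a tibble with one row per residue (columns `pos`, `base`,
#' `sugar2p`, `adducts`) carrying the sequence id and terminal chemistry as
#' attributes. Residues are written in a bracket dialect: plain characters
#' for unmodified single-letter codes (`AUCG`, `Y` for pseudouridine, `D`),
#' bracket tokens for everything else — `[m5C]` a base modification,
#' `[Gm]` 2'-O-methylguanosine, `[Up]` 2'-phosphouridine, `[Y+ce]`
#' cyanoethylated pseudouridine.
#'
#' @param x A sequence string in the bracket dialect, or a tibble with
#'   columns `base`, `sugar2p`, `adducts`.
#' @param id Sequence identifier.
#' @param five_prime 5' terminal chemistry: `"OH"` or `"P"`.
#' @param three_prime 3' terminal chemistry: `"OH"`, `"P"` or `"cycP"`
#'   (2',3'-cyclic phosphate).
#' @return A `mod_seq` tibble.
#' @examples
#' mod_seq("AUC[Gm]AC[s4U]G")
#' mod_seq("[Up]", five_prime = "P")
#' @export
mod_seq <- function(x, id = "seq", five_prime = "OH", three_prime = "OH") {
  if (inherits(x, "mod_seq")) {
    return(x)
  }
  if (is.character(x)) {
    res <- parse_mod_string(x)
  } else if (is.data.frame(x)) {
    res <- tibble::as_tibble(x)
    if (!"sugar2p" %in% names(res)) res$sugar2p <- "OH"
    if (!"adducts" %in% names(res)) res$adducts <- list(character())
    if (!is.list(res$adducts)) res$adducts <- as.list(res$adducts)
  } else {
    rlang::abort("`x` must be a sequence string or residue data frame.")
  }
  new_mod_seq(res, id = id, five_prime = five_prime, three_prime = three_prime)
}

new_mod_seq <- function(residues, id, five_prime, three_prime,
                        class = character()) {
  if (nrow(residues) < 1) {
    rlang::abort("A sequence must contain at least one residue.")
  }
  if (!five_prime %in% c("OH", "P")) {
    rlang::abort("`five_prime` must be 'OH' or 'P'.")
  }
  if (!three_prime %in% c("OH", "P", "cycP")) {
    rlang::abort("`three_prime` must be 'OH', 'P' or 'cycP'.")
  }
  registry_row(unique(residues$base)) # fail loudly on unknown codes
  ok <- residues$sugar2p %in% c("OH", "OMe", "P")
  if (!all(ok)) {
    rlang::abort("`sugar2p` must be one of 'OH', 'OMe', 'P'.")
  }
  residues$pos <- seq_len(nrow(residues))
  residues <- residues[c("pos", "base", "sugar2p", "adducts")]
  tibble::new_tibble(
    residues,
    id = id,
    five_prime = five_prime,
    three_prime = three_prime,
    class = c(class, "mod_seq")
  )
}

parse_mod_string <- function(x) {
  if (length(x) != 1 || !nzchar(x)) {
    rlang::abort("Sequence string must be a single non-empty string.")
  }
  chars <- strsplit(x, "")[[1]]
  tokens <- character()
  i <- 1
  while (i <= length(chars)) {
    if (chars[i] == "[") {
      j <- i + 1
      while (j <= length(chars) && chars[j] != "]") j <- j + 1
      if (j > length(chars)) {
        rlang::abort("Unclosed '[' in sequence string.")
      }
      tokens <- c(tokens, paste(chars[(i + 1):(j - 1)], collapse = ""))
      i <- j + 1
    } else {
      tokens <- c(tokens, chars[i])
      i <- i + 1
    }
  }
  purrr::map_dfr(tokens, parse_residue_token)
}

ADDUCT_ABBREV <- c(ce = "cyanoethyl", cyanoethyl = "cyanoethyl")

parse_residue_token <- function(token) {
  codes <- mod_registry()$code
  parse_core <- function(core) {
    if (core %in% codes) {
      return(list(base = core, sugar = "OH"))
    }
    suffix <- substring(core, nchar(core))
    prefix <- substring(core, 1, nchar(core) - 1)
    if (suffix %in% c("m", "p") && prefix %in% codes) {
      return(list(
        base = prefix,
        sugar = if (suffix == "m") "OMe" else "P"
      ))
    }
    NULL
  }
  # whole token first: registry codes may themselves contain '+' (G+)
  parsed <- parse_core(token)
  adducts <- character()
  if (is.null(parsed)) {
    parts <- strsplit(token, "+", fixed = TRUE)[[1]]
    parsed <- parse_core(parts[1])
    if (is.null(parsed) || length(parts) < 2) {
      rlang::abort(sprintf("Unrecognized residue token '%s'.", token))
    }
    for (a in parts[-1]) {
      full <- ADDUCT_ABBREV[[a]]
      if (is.null(full)) {
        rlang::abort(sprintf("Unknown adduct token '+%s'.", a))
      }
      adducts <- c(adducts, full)
    }
  }
  tibble::tibble(
    pos = NA_integer_, base = parsed$base, sugar2p = parsed$sugar,
    adducts = list(adducts)
  )
}

#' @export
print.mod_seq <- function(x, ...) {
  cat(sprintf(
    "<%s> %s  5'-%s %s 3'-%s  (%d nt, %.5f Da)\n",
    class(x)[1], seq_id(x), seq_termini(x)["five_prime"],
    render_mod_string(x), seq_termini(x)["three_prime"],
    nrow(x), oligo_mass(x)
  ))
  invisible(x)
}

#' Sequence accessors
#'
#' @param x A `mod_seq` or `mod_fragment`.
#' @return `seq_id()` the identifier; `seq_termini()` a named character
#'   vector with elements `five_prime` and `three_prime`.
#' @export
seq_id <- function(x) attr(x, "id")

#' @rdname seq_id
#' @export
seq_termini <- function(x) {
  c(
    five_prime = attr(x, "five_prime"),
    three_prime = attr(x, "three_prime")
  )
}

#' Render a sequence in the bracket dialect
#'
#' @param x A `mod_seq`.
#' @return A single string; inverse of the `mod_seq()` parser.
#' @export
render_mod_string <- function(x) {
  paste(
    purrr::pmap_chr(
      list(x$base, x$sugar2p, x$adducts),
      function(base, sugar, adducts) {
        token <- paste0(
          base,
          switch(sugar, OH = "", OMe = "m", P = "p")
        )
        abbr <- names(ADDUCT_ABBREV)[match(adducts, ADDUCT_ABBREV)]
        if (length(adducts) > 0) {
          token <- paste0(token, paste0("+", abbr, collapse = ""))
        }
        if (nchar(token) > 1) paste0("[", token, "]") else token
      }
    ),
    collapse = ""
  )
}

# Mass and composition -------------------------------------------------------

#' Elemental composition and neutral mass of an oligonucleotide
#'
#' The composition is the sum of the free-nucleoside compositions of all
#' residues (including 2'-sugar-state and adduct increments), plus one
#' phosphodiester linkage (HPO3 minus H2O) per internucleotide bond, plus
#' terminal increments: a terminal phosphate adds HPO3 and a 2',3'-cyclic
#' phosphate adds HPO3 minus H2O.
#'
#' @param x A `mod_seq` or `mod_fragment`.
#' @return `oligo_comp()` an `elem_comp`; `oligo_mass()` the neutral
#'   monoisotopic mass in Da.
#' @examples
#' oligo_mass(mod_seq("U")) # the uridine nucleoside, 244.06956
#' @export
oligo_comp <- function(x) {
  x <- mod_seq(x)
  n <- nrow(x)
  counts <- matrix(0L, nrow = n, ncol = length(ELEMENTS),
    dimnames = list(NULL, ELEMENTS)
  )
  for (i in seq_len(n)) {
    counts[i, ] <- unclass(
      residue_comp(x$base[i], x$sugar2p[i], x$adducts[[i]])
    )
  }
  total <- elem_comp(colSums(counts))
  hpo3 <- elem_comp("HPO3")
  h2o <- elem_comp("H2O")
  for (k in seq_len(n - 1)) total <- total + hpo3
  term <- seq_termini(x)
  if (term["five_prime"] == "P") total <- total + hpo3
  if (term["three_prime"] %in% c("P", "cycP")) total <- total + hpo3
  # remove linkage waters (and the cyclic-phosphate water) at the end so
  # intermediate compositions never go negative
  drop_h2o <- (n - 1) + (term["three_prime"] == "cycP")
  for (k in seq_len(drop_h2o)) total <- total - h2o
  total
}

#' @rdname oligo_comp
#' @export
oligo_mass <- function(x) {
  comp_mass(oligo_comp(x))
}

#' @rdname oligo_comp
#' @param z Charge state.
#' @param polarity `"+"` or `"-"`.
#' @export
oligo_mz <- function(x, z = 1L, polarity = c("-", "+")) {
  mz(oligo_mass(x), z, match.arg(polarity))
}

# FASTA-dialect IO -----------------------------------------------------------

#' Read and write modified sequences in the bracket FASTA dialect
#'
#' Records are ordinary FASTA records whose sequence lines use the bracket
#' dialect of [mod_seq()]. The header may carry terminal chemistry as
#' `5p=OH 3p=P` key-value pairs after the identifier. An optional side-car
#' TSV (columns `id, position, base, sugar2p, adducts`) overrides inline
#' annotations per position; adducts are `;`-separated.
#'
#' @param path File path.
#' @param sidecar Optional path to a side-car annotation TSV.
#' @return A list of `mod_seq` objects, named by id.
#' @export
read_mod_fasta <- function(path, sidecar = NULL) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (!any(hdr) || !hdr[1]) {
    rlang::abort("Not a FASTA file: no '>' header found.")
  }
  idx <- cumsum(hdr)
  seqs <- purrr::map(split(lines, idx), function(block) {
    header <- sub("^>", "", block[1])
    fields <- strsplit(trimws(header), "\\s+")[[1]]
    id <- fields[1]
    kv <- fields[-1][grepl("=", fields[-1])]
    opts <- stats::setNames(
      sub(".*=", "", kv), sub("=.*", "", kv)
    )
    mod_seq(
      paste(block[-1], collapse = ""),
      id = id,
      five_prime = if ("5p" %in% names(opts)) opts[["5p"]] else "OH",
      three_prime = if ("3p" %in% names(opts)) opts[["3p"]] else "OH"
    )
  })
  names(seqs) <- purrr::map_chr(seqs, seq_id)
  if (!is.null(sidecar)) {
    ann <- readr::read_tsv(sidecar, show_col_types = FALSE)
    for (i in seq_len(nrow(ann))) {
      id <- as.character(ann$id[i])
      if (!id %in% names(seqs)) next
      s <- seqs[[id]]
      p <- ann$position[i]
      if (p < 1 || p > nrow(s)) {
        rlang::abort(sprintf("Side-car position %d out of range for '%s'.", p, id))
      }
      if (!is.na(ann$base[i])) s$base[p] <- ann$base[i]
      if (!is.na(ann$sugar2p[i])) s$sugar2p[p] <- ann$sugar2p[i]
      if ("adducts" %in% names(ann) && !is.na(ann$adducts[i])) {
        s$adducts[[p]] <- strsplit(ann$adducts[i], ";")[[1]]
      }
      seqs[[id]] <- new_mod_seq(
        s, id = id,
        five_prime = seq_termini(s)[["five_prime"]],
        three_prime = seq_termini(s)[["three_prime"]]
      )
    }
  }
  seqs
}

#' @rdname read_mod_fasta
#' @param seqs A `mod_seq` or list of them.
#' @export
write_mod_fasta <- function(seqs, path) {
  if (inherits(seqs, "mod_seq")) seqs <- list(seqs)
  lines <- purrr::map(seqs, function(s) {
    term <- seq_termini(s)
    c(
      sprintf(">%s 5p=%s 3p=%s", seq_id(s), term["five_prime"], term["three_prime"]),
      render_mod_string(s)
    )
  })
  readr::write_lines(unlist(lines), path)
  invisible(path)
}
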