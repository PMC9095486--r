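# Readers and writers for peak lists (TSV and MGF-style blocks), XIC
# tables and biophysics tables. All tabular formats are plain TSV with
# mandatory headers.

#' Read and write peak lists as TSV
#'
#' @param path File path; two columns `mz`, `intensity`.
#' @param polarity Spectrum polarity to attach on read.
#' @return `read_peaks_tsv()` a `spectrum`.
#' @export
read_peaks_tsv <- function(path, polarity = "-") {
  spectrum(readr::read_tsv(path, show_col_types = FALSE), polarity = polarity)
}

#' @rdname read_peaks_tsv
#' @param spec A `spectrum`.
#' @export
write_peaks_tsv <- function(spec, path) {
  readr::write_tsv(tibble::as_tibble(spec), path)
  invisible(path)
}

#' Read and write MGF-style spectra
#'
#' Spectra are stored as `BEGIN IONS`/`END IONS` blocks with `TITLE`,
#' `PEPMASS` and `CHARGE` headers (charge written as e.g. `2-`) followed
#' by `m/z intensity` pairs.
#'
#' @param path File path.
#' @return `read_mgf()` a named list of `spectrum` objects with precursor
#'   attributes set.
#' @export
read_mgf <- function(path) {
  lines <- trimws(readr::read_lines(path))
  starts <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(starts) != length(ends)) {
    rlang::abort("Malformed MGF: unbalanced BEGIN IONS/END IONS.")
  }
  out <- purrr::map2(starts, ends, function(s, e) {
    block <- lines[(s + 1):(e - 1)]
    kv <- block[grepl("=", block, fixed = TRUE)]
    keys <- sub("=.*", "", kv)
    vals <- sub("^[^=]*=", "", kv)
    title <- if ("TITLE" %in% keys) vals[keys == "TITLE"][1] else NA_character_
    pepmass <- if ("PEPMASS" %in% keys) {
      as.numeric(strsplit(vals[keys == "PEPMASS"][1], "\\s+")[[1]][1])
    } else {
      NULL
    }
    z <- NULL
    polarity <- "-"
    if ("CHARGE" %in% keys) {
      ch <- vals[keys == "CHARGE"][1]
      polarity <- if (grepl("-", ch, fixed = TRUE)) "-" else "+"
      z <- as.integer(gsub("[^0-9]", "", ch))
    }
    rows <- block[!grepl("=", block, fixed = TRUE) & nzchar(block)]
    mat <- do.call(rbind, strsplit(rows, "\\s+"))
    peaks <- tibble::tibble(
      mz = as.numeric(mat[, 1]),
      intensity = as.numeric(mat[, 2])
    )
    s <- spectrum(peaks,
      polarity = polarity,
      precursor_mz = pepmass, precursor_z = z
    )
    attr(s, "title") <- title
    s
  })
  names(out) <- purrr::map_chr(
    out, ~ attr(.x, "title") %||% NA_character_
  )
  out
}

#' @rdname read_mgf
#' @param spectra A `spectrum` or (optionally named) list of them.
#' @export
write_mgf <- function(spectra, path) {
  if (inherits(spectra, "spectrum")) spectra <- list(spectra)
  if (is.null(names(spectra))) {
    names(spectra) <- sprintf("spectrum_%03d", seq_along(spectra))
  }
  lines <- purrr::imap(spectra, function(s, title) {
    hdr <- c("BEGIN IONS", sprintf("TITLE=%s", title))
    if (!is.null(attr(s, "precursor_mz"))) {
      hdr <- c(hdr, sprintf("PEPMASS=%.5f", attr(s, "precursor_mz")))
    }
    if (!is.null(attr(s, "precursor_z"))) {
      hdr <- c(hdr, sprintf(
        "CHARGE=%d%s", attr(s, "precursor_z"),
        if (spec_polarity(s) == "-") "-" else "+"
      ))
    }
    c(hdr, sprintf("%.6f %.2f", s$mz, s$intensity), "END IONS", "")
  })
  readr::write_lines(unlist(lines), path)
  invisible(path)
}

#' Read pipeline tables from TSV
#'
#' Thin validated readers: XIC tables (`site, species, condition,
#' replicate, area`), melting curves (`temperature, absorbance`),
#' kinetics tables (`conc, conc_unit, vi, vi_unit, replicate`) and decay
#' series (`time, fraction`).
#'
#' @param path File path.
#' @return A tibble in the layout the corresponding fitter expects.
#' @export
read_xic_tsv <- function(path) {
  check_xic(readr::read_tsv(path, show_col_types = FALSE))
}

#' @rdname read_xic_tsv
#' @export
read_melting_tsv <- function(path) {
  t <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("temperature", "absorbance") %in% names(t)))
  t
}

#' @rdname read_xic_tsv
#' @export
read_kinetics_tsv <- function(path) {
  t <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("conc", "vi") %in% names(t)))
  t
}

#' @rdname read_xic_tsv
#' @export
read_decay_tsv <- function(path) {
  t <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("time", "fraction") %in% names(t)))
  t
}
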