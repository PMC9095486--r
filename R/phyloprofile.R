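# Phenotype-constrained phylogenetic profiling: which genes are present in
# every genome showing a phenotype and absent from every genome lacking it.

#' Construct an ortholog presence/absence matrix
#'
#' An `ortholog_matrix` is a tibble with one row per gene: a `gene` id
#' column, an `annotation` column (`"characterized"` or
#' `"uncharacterized"`), and one 0/1 column per genome. The per-genome
#' phenotype labels (`"positive"`, `"negative"`, `"unlabeled"`) are carried
#' as an attribute and retrieved with `phenotype_labels()`.
#'
#' @param presence A genes-by-genomes 0/1 matrix with row and column names,
#'   or a tibble in the layout above.
#' @param phenotype Named character vector mapping genome id to
#'   `"positive"`, `"negative"` or `"unlabeled"`; at least one positive.
#' @param annotation Named character vector mapping gene id to
#'   `"characterized"`/`"uncharacterized"`; defaults to characterized.
#' @return An `ortholog_matrix` tibble.
#' @export
ortholog_matrix <- function(presence, phenotype, annotation = NULL) {
  if (is.matrix(presence)) {
    if (is.null(rownames(presence)) || is.null(colnames(presence))) {
      rlang::abort("`presence` must have gene rownames and genome colnames.")
    }
    tb <- tibble::as_tibble(presence, rownames = "gene")
  } else {
    tb <- tibble::as_tibble(presence)
  }
  genomes <- setdiff(names(tb), c("gene", "annotation"))
  if (anyDuplicated(tb$gene) || anyDuplicated(genomes)) {
    rlang::abort("Gene and genome ids must be unique.")
  }
  vals <- unlist(tb[genomes])
  if (!all(vals %in% c(0L, 1L))) {
    rlang::abort("Presence entries must be 0 or 1.")
  }
  if (!"annotation" %in% names(tb)) {
    tb$annotation <- "characterized"
    if (!is.null(annotation)) {
      tb$annotation <- unname(annotation[tb$gene])
    }
  }
  bad <- setdiff(names(phenotype), genomes)
  if (length(bad) > 0) {
    rlang::abort(sprintf(
      "Phenotype labels for unknown genome(s): %s.", paste(bad, collapse = ", ")
    ))
  }
  labels <- stats::setNames(rep("unlabeled", length(genomes)), genomes)
  labels[names(phenotype)] <- phenotype
  if (!all(labels %in% c("positive", "negative", "unlabeled"))) {
    rlang::abort("Phenotype labels must be positive/negative/unlabeled.")
  }
  if (!any(labels == "positive")) {
    rlang::abort("At least one genome must be labeled positive.")
  }
  tb <- tb[c("gene", "annotation", genomes)]
  tibble::new_tibble(tb, phenotype = labels, class = "ortholog_matrix")
}

#' @rdname ortholog_matrix
#' @param x An `ortholog_matrix`.
#' @export
phenotype_labels <- function(x) attr(x, "phenotype")

#' Screen for genes matching a phenotype profile
#'
#' Returns the genes present in at least `|positives| - max_pos_misses`
#' phenotype-positive genomes and at most `max_neg_hits` phenotype-negative
#' genomes. With the defaults (0/0) this is the strict Venn intersection:
#' present in every positive genome, absent from every negative one.
#' Unlabeled genomes are ignored. Gene order is preserved.
#'
#' @param m An `ortholog_matrix`.
#' @param max_pos_misses Positive genomes a candidate may be absent from.
#' @param max_neg_hits Negative genomes a candidate may be present in.
#' @return Character vector of gene ids, in matrix order.
#' @export
profile_candidates <- function(m, max_pos_misses = 0L, max_neg_hits = 0L) {
  labels <- phenotype_labels(m)
  if (is.null(labels) || !any(labels == "positive")) {
    rlang::abort("`m` must carry phenotype labels with >= 1 positive genome.")
  }
  pos <- names(labels)[labels == "positive"]
  neg <- names(labels)[labels == "negative"]
  pos_count <- if (length(pos) > 0) {
    rowSums(as.matrix(m[pos]))
  } else {
    rep(0, nrow(m))
  }
  neg_count <- if (length(neg) > 0) {
    rowSums(as.matrix(m[neg]))
  } else {
    rep(0, nrow(m))
  }
  keep <- pos_count >= length(pos) - max_pos_misses & neg_count <= max_neg_hits
  m$gene[keep]
}

#' Filter candidate genes by functional annotation
#'
#' @param genes Character vector of gene ids (order preserved).
#' @param m The `ortholog_matrix` carrying annotations.
#' @param keep Annotation classes to retain (default uncharacterized —
#'   the screen for novel enzymes).
#' @return The subset of `genes` with annotation in `keep`. Genes missing
#'   from the matrix raise a warning and are excluded.
#' @export
annotation_filter <- function(genes, m, keep = "uncharacterized") {
  i <- match(genes, m$gene)
  if (anyNA(i)) {
    rlang::warn(sprintf(
      "Gene(s) without annotation excluded: %s.",
      paste(genes[is.na(i)], collapse = ", ")
    ))
    genes <- genes[!is.na(i)]
    i <- i[!is.na(i)]
  }
  genes[m$annotation[i] %in% keep]
}

#' Read and write ortholog matrices as TSV
#'
#' Layout: a header row `gene  <genome ids...>  annotation`, a phenotype
#' row with gene id `#phenotype` holding `+` / `-` / `.` per genome, then
#' one row per gene with 0/1 entries.
#'
#' @param path File path.
#' @return An `ortholog_matrix`.
#' @export
read_ortholog_tsv <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(names(raw)[1] == "gene")
  ph_row <- which(raw$gene == "#phenotype")
  if (length(ph_row) != 1) {
    rlang::abort("Expected exactly one '#phenotype' row.")
  }
  genomes <- setdiff(names(raw), c("gene", "annotation"))
  map <- c("+" = "positive", "-" = "negative", "." = "unlabeled")
  phenotype <- map[unlist(raw[ph_row, genomes])]
  names(phenotype) <- genomes
  genes <- raw[-ph_row, ]
  genes[genomes] <- lapply(genes[genomes], as.integer)
  ortholog_matrix(genes, phenotype)
}

#' @rdname read_ortholog_tsv
#' @param m An `ortholog_matrix`.
#' @export
write_ortholog_tsv <- function(m, path) {
  labels <- phenotype_labels(m)
  genomes <- setdiff(names(m), c("gene", "annotation"))
  map <- c(positive = "+", negative = "-", unlabeled = ".")
  ph <- tibble::as_tibble(as.list(stats::setNames(
    map[labels[genomes]], genomes
  )))
  ph$gene <- "#phenotype"
  ph$annotation <- ""
  body <- tibble::as_tibble(m)
  body[genomes] <- lapply(body[genomes], as.character)
  readr::write_tsv(
    dplyr::bind_rows(
      ph[c("gene", genomes, "annotation")],
      body[c("gene", genomes, "annotation")]
    ),
    path
  )
  invisible(path)
}
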