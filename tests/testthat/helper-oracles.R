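# Independent brute-force oracles used to cross-check the implementation.
# These deliberately re-derive specificity tables and mass bookkeeping with
# plain loops rather than calling into the code paths they check.

ORACLE_ATOMIC <- c(C = 12, H = 1.00783, N = 14.00307, O = 15.99491,
                   P = 30.97376, S = 31.97207)

oracle_registry <- function() {
  read.delim(
    system.file("extdata", "modifications.tsv", package = "rnamodms"),
    check.names = FALSE
  )
}

# element counts of one residue (nucleoside + sugar state + adducts)
oracle_residue_counts <- function(base, sugar2p, adducts) {
  reg <- oracle_registry()
  row <- reg[reg$code == base, ]
  stopifnot(nrow(row) == 1)
  counts <- c(C = row$C, H = row$H, N = row$N, O = row$O, P = row$P, S = row$S)
  if (sugar2p == "P") counts <- counts + c(C = 0, H = 1, N = 0, O = 3, P = 1, S = 0)
  if (sugar2p == "OMe") counts <- counts + c(C = 1, H = 2, N = 0, O = 0, P = 0, S = 0)
  for (a in adducts) {
    stopifnot(a == "cyanoethyl")
    counts <- counts + c(C = 3, H = 3, N = 1, O = 0, P = 0, S = 0)
  }
  counts
}

# neutral oligo mass by element-by-element summation
oracle_oligo_mass <- function(s) {
  term <- seq_termini(s)
  n <- nrow(s)
  counts <- c(C = 0, H = 0, N = 0, O = 0, P = 0, S = 0)
  for (i in seq_len(n)) {
    counts <- counts + oracle_residue_counts(
      s$base[i], s$sugar2p[i], s$adducts[[i]]
    )
  }
  hpo3 <- c(C = 0, H = 1, N = 0, O = 3, P = 1, S = 0)
  h2o <- c(C = 0, H = 2, N = 0, O = 1, P = 0, S = 0)
  counts <- counts + (n - 1) * hpo3 - (n - 1) * h2o
  if (term[["five_prime"]] == "P") counts <- counts + hpo3
  if (term[["three_prime"]] == "P") counts <- counts + hpo3
  if (term[["three_prime"]] == "cycP") counts <- counts + hpo3 - h2o
  sum(counts * ORACLE_ATOMIC[names(counts)])
}

# per-bond digestion oracle: tests every internucleotide bond independently
# against its own copy of the specificity rules, then splits.
oracle_digest_coords <- function(s, enzyme) {
  g_fam <- c("G", "m2G", "m22G", "m7G", "G+")
  pyr <- c("U", "C", "Y", "D", "s4U", "m5C", "m5U", "m5s2U", "ac4C", "acp3U")
  n <- nrow(s)
  cut <- logical(if (n > 1) n - 1 else 0)
  for (i in seq_along(cut)) {
    hit <- switch(enzyme,
      T1 = s$base[i] %in% g_fam,
      A = s$base[i] %in% pyr,
      I = TRUE,
      P1 = TRUE
    )
    blocked <- if (enzyme == "P1") {
      s$sugar2p[i] == "P"
    } else {
      s$sugar2p[i] != "OH"
    }
    cut[i] <- hit && !blocked
  }
  data.frame(
    start = c(1L, which(cut) + 1L),
    end = c(which(cut), n)
  )
}

# random modified sequence for property tests
random_mod_seq <- function(n = NULL, id = "rand", max_len = 40) {
  if (is.null(n)) n <- sample(2:max_len, 1)
  codes <- c(
    "A", "C", "G", "U", "Y", "D", "s4U", "m5C", "m5U", "m1A",
    "m2G", "m22G", "G+", "ac4C", "m5s2U"
  )
  probs <- c(rep(0.2, 4), rep(0.02, 11))
  mod_seq(
    tibble::tibble(
      base = sample(codes, n, replace = TRUE, prob = probs / sum(probs)),
      sugar2p = sample(c("OH", "OMe", "P"), n,
        replace = TRUE, prob = c(0.85, 0.08, 0.07)
      ),
      adducts = replicate(n, character(), simplify = FALSE)
    ),
    id = id
  )
}

# localization oracle for a phosphate-sized delta: physically install the
# 2'-phosphate at each candidate position, rebuild the ladder from the
# modified fragment, and score matches from scratch.
oracle_localize_2p <- function(frag, spec, tol_ppm = 20, charges = 1L) {
  n <- nrow(frag)
  term <- seq_termini(frag)
  scores <- data.frame(position = seq_len(n), n_matched = NA_integer_)
  for (p in seq_len(n)) {
    res <- tibble::as_tibble(frag)
    res$sugar2p[p] <- "P"
    modded <- mod_seq(res,
      id = "oracle",
      five_prime = term[["five_prime"]], three_prime = term[["three_prime"]]
    )
    rep <- match_peaks(
      cid_ladder(modded), spec,
      tol_ppm = tol_ppm, charges = charges
    )
    scores$n_matched[p] <- sum(rep$matched)
  }
  scores
}

# phylo-profiling oracle: naive per-gene row scan
oracle_profile <- function(m, max_pos_misses = 0, max_neg_hits = 0) {
  labels <- phenotype_labels(m)
  pos <- names(labels)[labels == "positive"]
  neg <- names(labels)[labels == "negative"]
  keep <- character()
  for (i in seq_len(nrow(m))) {
    np <- sum(unlist(m[i, pos]))
    nn <- if (length(neg) > 0) sum(unlist(m[i, neg])) else 0
    if (np >= length(pos) - max_pos_misses && nn <= max_neg_hits) {
      keep <- c(keep, m$gene[i])
    }
  }
  keep
}
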