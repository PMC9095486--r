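test_that("c/y ladders satisfy the complementarity identity", {
  set.seed(202)
  h2o <- comp_mass("H2O")
  for (i in 1:200) {
    frag <- random_mod_seq(sample(2:12, 1))
    lad <- cid_ladder(frag)
    n <- nrow(frag)
    total <- oligo_mass(frag) + h2o
    for (k in seq_len(n - 1)) {
      ci <- lad$neutral_mass[lad$series == "c" & lad$index == k]
      ynk <- lad$neutral_mass[lad$series == "y" & lad$index == n - k]
      expect_lt(abs(ci + ynk - total), 1e-9)
    }
  }
  expect_error(cid_ladder(mod_seq("A")), "length")
})

test_that("c1 of a UC dinucleotide is uridine 3'-monophosphate", {
  lad <- cid_ladder(mod_seq("UC", three_prime = "P"))
  c1 <- lad$neutral_mass[lad$ion == "c1"]
  expect_equal(c1, 324.03588, tolerance = 1e-9)
  expect_equal(c1, residue_mass("U") + comp_mass("HPO3"), tolerance = 1e-9)
})

test_that("an internal 2'-phosphate shifts exactly the bracketing ions", {
  plain <- mod_seq("ACUGA", three_prime = "P")
  res <- tibble::as_tibble(plain)
  res$sugar2p[3] <- "P"
  modded <- mod_seq(res, three_prime = "P")
  lp <- cid_ladder(plain)
  lm <- cid_ladder(modded)
  diff <- lm$neutral_mass - lp$neutral_mass
  hpo3 <- comp_mass("HPO3")
  n <- 5
  for (r in seq_len(nrow(lp))) {
    covers <- if (lp$series[r] == "c") {
      lp$index[r] >= 3
    } else {
      lp$index[r] >= n - 3 + 1
    }
    expect_equal(diff[r], if (covers) hpo3 else 0, tolerance = 1e-9)
  }
})

test_that("match_peaks recovers exact, thinned and jittered ladders", {
  frag <- mod_fragment(mod_seq("AUCGACGA", id = "p"), 1, 8, three_prime = "P")
  lad <- cid_ladder(frag)
  exact <- spectrum(
    tibble::tibble(mz = mz(lad$neutral_mass, 1, "-"), intensity = 100)
  )
  rep <- match_peaks(lad, exact, tol_ppm = 10)
  expect_equal(coverage(rep), 1.0)
  expect_true(all(abs(rep$error_ppm) < 1e-9))

  # every second predicted ion removed; this fragment has no isobaric
  # c/y coincidences, so coverage drops to exactly one half
  frag2 <- mod_seq("UUCGAC", three_prime = "P")
  lad2 <- cid_ladder(frag2)
  stopifnot(min(dist(lad2$neutral_mass)) > 0.1) # no isobaric pairs
  half <- spectrum(tibble::tibble(
    mz = mz(sort(lad2$neutral_mass)[seq(1, nrow(lad2), by = 2)], 1, "-"),
    intensity = 100
  ))
  expect_equal(coverage(match_peaks(lad2, half, tol_ppm = 10)), 0.5)

  # 5 ppm jitter cannot be matched at 0.1 ppm
  set.seed(5)
  jit <- spectrum(tibble::tibble(
    mz = mz(lad$neutral_mass, 1, "-") * (1 + rnorm(nrow(lad), 0, 5e-6)),
    intensity = 100
  ))
  expect_lt(coverage(match_peaks(lad, jit, tol_ppm = 0.1)), 0.1)
  expect_error(match_peaks(lad, exact, tol_ppm = 0), "positive")
  expect_error(
    match_peaks(lad, spectrum(tibble::tibble(
      mz = double(), intensity = double()
    ))),
    "empty"
  )
})

test_that("match_peaks is invariant to peak-list order", {
  frag <- mod_seq("AUCGAC", three_prime = "P")
  lad <- cid_ladder(frag)
  peaks <- tibble::tibble(
    mz = mz(lad$neutral_mass, 1, "-"), intensity = seq_len(nrow(lad))
  )
  set.seed(3)
  shuffled <- peaks[sample(nrow(peaks)), ]
  a <- match_peaks(lad, spectrum(peaks), 10)
  b <- match_peaks(lad, spectrum(shuffled), 10)
  expect_equal(as.data.frame(a), as.data.frame(b))
})

test_that("localize_delta recovers an implanted 2'-phosphate site", {
  set.seed(404)
  hpo3 <- comp_mass("HPO3")
  for (i in 1:50) {
    frag <- random_mod_seq(sample(4:10, 1))
    frag$sugar2p[] <- "OH" # clean background
    frag <- mod_seq(tibble::as_tibble(frag), three_prime = "P")
    k <- sample(nrow(frag), 1)
    res <- tibble::as_tibble(frag)
    res$sugar2p[k] <- "P"
    modded <- mod_seq(res, three_prime = "P")
    spec <- spectrum(tibble::tibble(
      mz = mz(cid_ladder(modded)$neutral_mass, 1, "-"), intensity = 100
    ))
    got <- localize_delta(frag, spec, hpo3, tol_ppm = 5)
    want <- oracle_localize_2p(frag, spec, tol_ppm = 5)
    # agreement with the exhaustive-placement oracle
    best_oracle <- want$position[want$n_matched == max(want$n_matched)]
    expect_setequal(got$position[got$top], best_oracle)
    expect_true(k %in% got$position[got$top])
  }
})

test_that("degenerate localizations are reported as ties, not resolved", {
  frag <- mod_seq("AUCGA", three_prime = "P")
  spec <- spectrum(tibble::tibble(
    mz = mz(cid_ladder(frag)$neutral_mass, 1, "-"), intensity = 100
  ))
  # delta = 0: every placement explains the spectrum equally
  got <- localize_delta(frag, spec, 0, tol_ppm = 5)
  expect_true(all(got$top))
  # ions that cannot bracket the site leave a tied set
  hpo3 <- comp_mass("HPO3")
  res <- tibble::as_tibble(frag)
  res$sugar2p[2] <- "P"
  modded <- mod_seq(res, three_prime = "P")
  lad <- cid_ladder(modded)
  keep <- lad[lad$series == "c" & lad$index >= 3, ] # no ion separates 1..3
  trunc <- spectrum(tibble::tibble(
    mz = mz(keep$neutral_mass, 1, "-"), intensity = 100
  ))
  # c3/c4 cannot separate positions 2 and 3 (y4, isobaric with c4,
  # separates position 1): the tie is reported as a set
  got <- localize_delta(frag, trunc, hpo3, tol_ppm = 5)
  expect_setequal(got$position[got$top], c(2, 3))
})

test_that("shotgun identification recovers generated precursors", {
  seqs <- list(
    gen_modified_trna(1, phospho = TRUE, id = "t1"),
    gen_modified_trna(2, phospho = FALSE, id = "t2"),
    mod_seq("AUCGAUUG", id = "t3"),
    mod_seq("CCGGAAGAC", id = "t4")
  )
  truth <- purrr::map_dfr(seqs, function(s) {
    d <- digest(s, "T1")
    tibble::tibble(sequence = seq_id(s), fragment = d$seq, mass = d$mass)
  })
  prec <- tibble::tibble(
    mz = mz(truth$mass, 2, "-"), z = 2L, polarity = "-"
  )
  hits <- identify_fragments(prec, seqs, "T1",
    tol_ppm = 5,
    add_2p_variants = FALSE
  )
  found <- unique(paste(hits$sequence, hits$fragment))
  expect_true(all(paste(truth$sequence, truth$fragment) %in% found))
  expect_true(all(abs(hits$ppm) < 5))

  # empty precursor list -> empty table
  none <- identify_fragments(prec[0, ], seqs, "T1")
  expect_equal(nrow(none), 0)

  # isomeric fragments are both reported for one precursor
  iso <- list(mod_seq("AUCG", id = "i1"), mod_seq("UACG", id = "i2"))
  m <- digest(iso[[1]], "T1")$mass[1]
  one <- tibble::tibble(mz = mz(m, 1, "-"), z = 1L, polarity = "-")
  both <- identify_fragments(one, iso, "T1", add_2p_variants = FALSE)
  expect_setequal(both$sequence, c("i1", "i2"))
})

test_that("the 2'-phosphate hypothesis flags the V-loop fragment", {
  ref <- gen_modified_trna(1, phospho = FALSE) # reference without the mark
  mod <- gen_modified_trna(1, phospho = TRUE) # what the cell actually has
  dmod <- digest(mod, "T1")
  vloop <- dmod[dmod$start <= 47 & dmod$end >= 47, ]
  prec <- tibble::tibble(mz = mz(vloop$mass, 2, "-"), z = 2L, polarity = "-")
  hits <- identify_fragments(prec, list(ref), "T1", tol_ppm = 5)
  expect_true(any(hits$variant_2p))
  hit <- hits[hits$variant_2p, ]
  expect_true(any(hit$start <= 47 & hit$end >= 47))
})
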