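test_that("RNase T1 cuts after guanosines with free 2'-OH", {
  d <- digest(mod_seq("AUCGACG"), "T1")
  expect_equal(d$seq, c("AUCG", "ACG"))
  expect_equal(
    unname(seq_termini(d$fragment[[1]])), c("OH", "P")
  )
  expect_equal(
    unname(seq_termini(d$fragment[[2]])), c("OH", "OH")
  )
  # 2'-O-methyl blocks the transesterification; the terminal G has no bond
  blocked <- digest(mod_seq("AUC[Gm]ACG"), "T1")
  expect_equal(nrow(blocked), 1)
  expect_equal(blocked$seq, "AUC[Gm]ACG")
  # cyclic-phosphate option
  cyc <- digest(mod_seq("AUCGACG"), "T1", cyclic = TRUE)
  expect_equal(unname(seq_termini(cyc$fragment[[1]]))[2], "cycP")
})

test_that("nuclease P1 leaves a dinucleotide 3' of a 2'-phosphate", {
  s <- mod_seq("AC[Up][m5C]G")
  d <- digest(s, "P1")
  expect_equal(d$seq, c("A", "C", "[Up][m5C]", "G"))
  dimer <- d$fragment[[3]]
  expect_equal(unname(seq_termini(dimer)), c("P", "OH"))
  # the dimer's proton adduct is the diagnostic m/z 724.1 species
  expect_equal(round(oligo_mz(dimer, 1, "+"), 1), 724.1)
  # all products carry 5'-P except the parent 5' end
  expect_equal(unname(seq_termini(d$fragment[[1]]))[1], "OH")
  expect_equal(unname(seq_termini(d$fragment[[2]]))[1], "P")
})

test_that("complete digests match the per-bond brute-force oracle", {
  set.seed(101)
  for (i in 1:200) {
    s <- random_mod_seq()
    enzyme <- sample(c("T1", "A", "I", "P1"), 1)
    got <- digest(s, enzyme)
    want <- oracle_digest_coords(s, enzyme)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    # tiling: fragments reproduce the parent residue list
    expect_identical(
      paste(got$seq, collapse = ""), render_mod_string(s)
    )
    # no fragment retains an internal cleavable site
    for (f in got$fragment) {
      internal <- cleavage_sites(f, enzyme)
      expect_false(any(internal))
    }
  }
})

test_that("each hydrolyzed bond adds one water to the fragment mass sum", {
  set.seed(13)
  for (i in 1:50) {
    s <- random_mod_seq()
    for (enzyme in c("T1", "A", "I", "P1")) {
      d <- digest(s, enzyme)
      k <- nrow(d) - 1
      expect_equal(
        sum(d$mass), oligo_mass(s) + k * comp_mass("H2O"),
        tolerance = 1e-8
      )
    }
  }
})

test_that("missed cleavages emit spanning fragments", {
  s <- mod_seq("AUCGACGUG")
  d0 <- digest(s, "T1", missed = 0)
  d1 <- digest(s, "T1", missed = 1)
  expect_true(all(d0$seq %in% d1$seq))
  expect_setequal(d1$seq[d1$missed == 1], c("AUCGACG", "ACGUG"))
  d2 <- digest(s, "T1", missed = 2)
  expect_true("AUCGACGUG" %in% d2$seq)
  expect_error(digest(s, "T1", missed = -1), "non-negative")
})

test_that("alkaline phosphatase strips terminal but not internal phosphates", {
  d <- digest(mod_seq("AUCGACG"), "T1")
  frag <- d$fragment[[1]] # AUCG with 3'-P
  bald <- apply_phosphatase(frag)
  expect_equal(unname(seq_termini(bald)), c("OH", "OH"))
  expect_equal(oligo_mass(frag) - oligo_mass(bald), comp_mass("HPO3"))
  expect_equal(oligo_mass(apply_phosphatase(bald)), oligo_mass(bald))
  # internal 2'-phosphate survives
  up <- mod_fragment(mod_seq("A[Up]CG"), 1, 4, three_prime = "P")
  stripped <- apply_phosphatase(up)
  expect_equal(stripped$sugar2p[2], "P")
  expect_equal(
    oligo_mass(up) - oligo_mass(stripped), comp_mass("HPO3")
  )
})

test_that("cyanoethylation touches only pseudouridine", {
  s <- mod_seq("AUYGU")
  ce <- cyanoethylate(s)
  expect_equal(
    oligo_mass(ce) - oligo_mass(s), comp_mass("C3H3N"),
    tolerance = 1e-9
  )
  none <- mod_seq("AUCG")
  expect_equal(oligo_mass(cyanoethylate(none)), oligo_mass(none))
})

test_that("periodate/beta-elimination removes the 3'-terminal nucleoside", {
  # the pN-p preparation: P1 dimer -> mononucleotide with three phosphates
  dimer <- mod_seq("[Up][m5C]", five_prime = "P")
  mono <- periodate_beta_eliminate(dimer)
  expect_equal(nrow(mono), 1)
  expect_equal(unname(seq_termini(mono)), c("P", "P"))
  expect_equal(
    oligo_mass(mono), residue_mass("U") + 3 * comp_mass("HPO3"),
    tolerance = 1e-9
  )
  # blocked when the 3'-terminal residue lacks the vicinal diol
  expect_error(periodate_beta_eliminate(mod_seq("A[Gm]")), "diol")
  expect_error(
    periodate_beta_eliminate(mod_seq("AUCG", three_prime = "P")), "diol"
  )
  # trinucleotide: mass delta checked against composition bookkeeping
  tri <- mod_seq("ACG")
  di <- periodate_beta_eliminate(tri)
  expect_identical(render_mod_string(di), "AC")
  expect_equal(oligo_mass(di), oracle_oligo_mass(di), tolerance = 1e-9)
  expect_equal(
    oligo_mass(tri) - oligo_mass(di),
    residue_mass("G") - comp_mass("H2O"),
    tolerance = 1e-9
  )
})
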