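test_that("comp_mass reproduces reference masses", {
  # a phosphate group, the key neutral-loss/gain unit of the workflow
  expect_equal(round(comp_mass("HPO3"), 5), 79.96632)
  expect_equal(comp_mass(elem_comp()), 0)
  expect_equal(comp_mass("H2O"), 18.01057, tolerance = 1e-10)
  expect_equal(comp_mass("CH2"), 14.01566, tolerance = 1e-10)
  expect_error(elem_comp("Xq2"), "parse|Unknown")
})

test_that("composition arithmetic is element-wise and guarded", {
  a <- elem_comp("C2H5")
  b <- elem_comp("H2O")
  expect_true((a + b) == elem_comp("C2H7O"))
  expect_true((a + b) - b == a)
  expect_error(b - a, "negative")
  # additivity of mass under composition addition
  set.seed(11)
  for (i in 1:50) {
    x <- elem_comp(c(
      C = sample(0:10, 1), H = sample(0:20, 1), N = sample(0:5, 1),
      O = sample(0:10, 1), P = sample(0:2, 1), S = sample(0:2, 1)
    ))
    y <- elem_comp(c(C = sample(0:10, 1), H = sample(0:20, 1)))
    expect_equal(comp_mass(x + y), comp_mass(x) + comp_mass(y))
  }
})

test_that("formula formatting round-trips in Hill order", {
  f <- c("C9H12N2O6", "HO3P", "C3H3N") # carbon first, then alphabetical
  for (x in f) {
    expect_identical(format_formula(elem_comp(x)), x)
  }
  expect_true(elem_comp("HPO3") == elem_comp("HO3P"))
  expect_identical(format_formula(elem_comp()), "")
})

test_that("oligo_mass agrees with element-by-element composition summation", {
  # uridine alone: no linkage terms
  expect_equal(oligo_mass(mod_seq("U")), 244.06956, tolerance = 1e-9)
  # dinucleotide with a base modification
  dinuc <- mod_seq("U[m5C]")
  expect_equal(oligo_mass(dinuc), 563.12652, tolerance = 1e-9)
  expect_equal(oligo_mass(dinuc), oracle_oligo_mass(dinuc), tolerance = 1e-9)
  # the diagnostic P1 dimer: 5'-P, internal 2'-P, two extra phosphates
  dimer <- mod_seq("[Up][m5C]", five_prime = "P")
  expect_equal(oligo_mass(dimer), 723.05916, tolerance = 1e-9)
  expect_equal(
    oligo_mass(dimer),
    oligo_mass(mod_seq("U[m5C]")) + 2 * comp_mass("HPO3"),
    tolerance = 1e-9
  )
  set.seed(42)
  for (i in 1:100) {
    s <- random_mod_seq()
    expect_equal(oligo_mass(s), oracle_oligo_mass(s), tolerance = 1e-9)
  }
  expect_error(mod_seq("Zq"), "Unrecognized|Unregistered")
})

test_that("concatenation adds one phosphodiester linkage", {
  set.seed(7)
  link <- comp_mass("HPO3") - comp_mass("H2O")
  for (i in 1:100) {
    a <- random_mod_seq(max_len = 15)
    b <- random_mod_seq(max_len = 15)
    joined <- mod_seq(paste0(render_mod_string(a), render_mod_string(b)))
    expect_equal(
      oligo_mass(joined), oligo_mass(a) + oligo_mass(b) + link,
      tolerance = 1e-9
    )
  }
})

test_that("pseudouridine is mass-silent until cyanoethylated", {
  withU <- mod_seq("AUCGU")
  withY <- mod_seq("AYCGY")
  expect_equal(oligo_mass(withU), oligo_mass(withY))
  ce <- cyanoethylate(withY)
  expect_equal(
    oligo_mass(ce) - oligo_mass(withY), 2 * comp_mass("C3H3N"),
    tolerance = 1e-9
  )
})

test_that("sugar-state increments are exactly HPO3 and CH2", {
  expect_equal(
    residue_mass("U", "P") - residue_mass("U"), comp_mass("HPO3")
  )
  expect_equal(
    residue_mass("G", "OMe") - residue_mass("G"), comp_mass("CH2")
  )
  expect_error(residue_mass("U", "wat"), "sugar")
})

test_that("m/z arithmetic uses the electron-corrected proton and inverts", {
  expect_equal(mz(723.05916, 1, "+"), 724.06644, tolerance = 1e-7)
  expect_equal(round(mz(723.05916, 1, "+"), 1), 724.1)
  expect_equal(mz(1000, 2, "-"), 498.99272354, tolerance = 1e-8)
  for (z in 1:3) {
    for (p in c("+", "-")) {
      expect_equal(mass_from_mz(mz(1234.567, z, p), z, p), 1234.567)
    }
  }
  expect_error(mz(100, 0), "positive integer")
})

test_that("registry loads, enforces uniqueness, fails loudly on unknowns", {
  reg <- mod_registry()
  expect_false(anyDuplicated(reg$code) > 0)
  # pseudouridine shares uridine's composition
  expect_equal(residue_mass("Y"), residue_mass("U"))
  expect_error(residue_mass("nope"), "Unregistered")
  # external-source entries are flagged
  expect_true(all(c("modomics", "canonical") %in% reg$source))
})
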