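test_that("noiseless melting curves are recovered exactly", {
  curve <- gen_melting(seed = 1, tm = 85.8, width = 2, noise_sd = 0)
  fit <- fit_melting(curve)
  expect_equal(fit$tm, 85.8, tolerance = 1e-6)
  expect_equal(fit$width, 2, tolerance = 1e-4)
  # sigmoid and derivative estimators agree on clean curves
  expect_lt(abs(fit$tm - fit$tm_derivative), 0.2)
  # the modified-vs-unmodified comparison
  lo <- fit_melting(gen_melting(seed = 2, tm = 79.2, noise_sd = 0))
  expect_equal(fit$tm - lo$tm, 6.6, tolerance = 1e-6)
  expect_equal(delta_tm(curve, gen_melting(seed = 2, tm = 79.2)), 6.6,
    tolerance = 1e-6
  )
})

test_that("melting Tm is robust to absorbance noise", {
  # noise sd = 0.5% of the ~0.25 transition amplitude
  ok <- 0
  for (s in 1:100) {
    curve <- gen_melting(seed = s, tm = 85.8, noise_sd = 0.005 * 0.25)
    fit <- fit_melting(curve)
    if (abs(fit$tm - 85.8) < 0.3) ok <- ok + 1
  }
  expect_gte(ok, 95)
})

test_that("flat curves are rejected as transition-free", {
  flat <- tibble::tibble(
    temperature = seq(40, 105, 0.5),
    absorbance = rep(1, 131)
  )
  expect_error(fit_melting(flat), "transition")
  expect_error(
    fit_melting(tibble::tibble(
      temperature = 1:10, absorbance = rnorm(10)
    )),
    "20 points"
  )
})

test_that("broom-style accessors expose melting fits", {
  fit <- fit_melting(gen_melting(seed = 3, noise_sd = 1e-3))
  td <- tidy(fit)
  expect_true(all(c("tm", "width") %in% td$term))
  gl <- glance(fit)
  expect_true(gl$converged)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})

test_that("noiseless Michaelis-Menten data are recovered to solver tolerance", {
  d <- gen_kinetics(seed = 1, km = 97.3, vmax = 9.9, noise_cv = 0)
  # the titration starts at 100 nM, a hair above the true Km, so the
  # one-sided-grid warning legitimately fires
  expect_warning(fit <- fit_mm(d), "outside")
  expect_equal(fit$km, 97.3, tolerance = 1e-6)
  expect_equal(fit$vmax, 9.9, tolerance = 1e-6)
  # random parameters over three orders of magnitude
  set.seed(31)
  for (i in 1:20) {
    km <- 10^runif(1, 1, 4)
    vmax <- 10^runif(1, 0, 2)
    grid <- exp(seq(log(km / 20), log(km * 20), length.out = 8))
    d <- tibble::tibble(conc = grid, vi = vmax * grid / (km + grid))
    fit <- fit_mm(d)
    expect_equal(fit$km, km, tolerance = 1e-6)
    expect_equal(fit$vmax, vmax, tolerance = 1e-6)
  }
})

test_that("Km bias stays small under multiplicative noise", {
  bias <- vapply(1:100, function(s) {
    d <- gen_kinetics(seed = s, km = 97.3, vmax = 9.9, noise_cv = 0.05,
      n_rep = 3
    )
    (suppressWarnings(fit_mm(d))$km - 97.3) / 97.3
  }, numeric(1))
  expect_lt(abs(stats::median(bias)), 0.05)
})

test_that("units are converted, never assumed", {
  d_nM <- gen_kinetics(seed = 5, km = 200, vmax = 12)
  d_uM <- dplyr::mutate(d_nM, conc = conc / 1e3, conc_unit = "uM")
  expect_equal(fit_mm(d_uM)$km, fit_mm(d_nM)$km, tolerance = 1e-9)
  d_s <- dplyr::mutate(d_nM, vi = vi / 60, vi_unit = "nM_s")
  expect_equal(fit_mm(d_s)$vmax, fit_mm(d_nM)$vmax, tolerance = 1e-9)
  bad <- dplyr::mutate(d_nM, conc_unit = "furlongs")
  expect_error(fit_mm(bad), "unit")
})

test_that("a grid far below Km warns that Km is unbounded", {
  km <- 5e4
  grid <- c(10, 20, 40, 80, 160)
  d <- tibble::tibble(conc = grid, vi = 10 * grid / (km + grid))
  expect_warning(fit_mm(d), "outside|unbounded")
  expect_error(
    fit_mm(tibble::tibble(conc = c(1, 1, 2, 2), vi = 1:4)),
    "4 distinct"
  )
})

test_that("decay fits recover rates, constants and ratios", {
  d <- gen_decay(seed = 1, k = 0.1, noise_cv = 0)
  fit <- fit_decay(d)
  expect_equal(fit$rate, 0.1, tolerance = 1e-8)
  expect_equal(fit$half_life, log(2) / 0.1, tolerance = 1e-6)

  const <- tibble::tibble(time = c(0, 5, 10, 20), fraction = 1)
  cf <- fit_decay(const)
  expect_equal(cf$rate, 0)
  expect_equal(cf$half_life, Inf)

  # nuclease-protection comparison: threefold rate difference
  ratios <- vapply(1:50, function(s) {
    a <- fit_decay(gen_decay(seed = s, k = 0.3, noise_cv = 0.03))
    b <- fit_decay(gen_decay(seed = s + 1000, k = 0.1, noise_cv = 0.03))
    decay_ratio(a, b)
  }, numeric(1))
  expect_equal(stats::median(ratios), 3, tolerance = 0.15)

  expect_error(
    fit_decay(tibble::tibble(time = 0:3, fraction = c(1, 0.5, 0, -1))),
    "positive"
  )
  expect_error(
    fit_decay(tibble::tibble(time = 0:1, fraction = c(1, 0.5))),
    "3 time points"
  )
})

test_that("kinetics and decay fits expose tidy/glance/autoplot", {
  mmf <- suppressWarnings(fit_mm(gen_kinetics(seed = 2)))
  expect_identical(tidy(mmf)$term, c("km", "vmax"))
  expect_true(glance(mmf)$converged)
  expect_s3_class(autoplot(mmf), "ggplot")
  dcf <- fit_decay(gen_decay(seed = 2, noise_cv = 0.01))
  expect_identical(tidy(dcf)$term, "k")
  expect_s3_class(autoplot(dcf), "ggplot")
})
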