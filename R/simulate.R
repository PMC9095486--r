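# Seeded generators emulating every input the pipeline consumes: a
# modified tRNA-like sequence, CID spectra, XIC area tables, melting
# curves, kinetics tables, decay series and ortholog matrices. Each
# generator records its generating truth as a "truth" attribute so
# recovery tests are self-contained, and is bit-reproducible under a
# fixed seed.

#' Generating truth of a synthetic object
#'
#' @param x An object produced by one of the `gen_*()` generators.
#' @return The list of generating parameters recorded by the generator.
#' @export
sim_truth <- function(x) attr(x, "truth")

# 76-nt cloverleaf-like template, bracket dialect, modelled on a heavily
# modified archaeal class I tRNA: archaeosine at 15, Gm18, D20, m22G26,
# pseudouridines at 39/55, a 5-nt V-loop at 45-49 whose U47 can carry the
# 2'-phosphate, m5C48, m5U54, m1A58.
TRNA_TOKENS <- c(
  "G", "C", "G", "G", "C", "C", "A", "U", "A", "G", # 1-10
  "C", "U", "C", "A", "G+", "U", "A", "Gm", "G", "D", # 11-20
  "A", "G", "A", "G", "C", "m22G", "C", "C", "G", "G", # 21-30
  "C", "C", "U", "A", "A", "C", "A", "A", "Y", "G", # 31-40
  "C", "C", "G", "G", "A", "G", "U", "m5C", "C", "A", # 41-50
  "A", "U", "G", "m5U", "Y", "C", "G", "m1A", "U", "U", # 51-60
  "C", "G", "A", "U", "C", "C", "G", "G", "C", "U", # 61-70
  "C", "G", "A", "C", "C", "A" # 71-76
)

#' Generate a modified tRNA-like sequence
#'
#' Builds a 76-nt cloverleaf-like sequence with a realistic complement of
#' archaeal modifications and a 5-nt variable loop (positions 45-49). When
#' `phospho = TRUE` the V-loop uridine at position 47 carries the
#' 2'-phosphate sugar state. The anticodon triplet (34-36) is drawn at
#' random under the seed; everything else is fixed.
#'
#' @param seed Integer seed.
#' @param phospho Install the 2'-phosphate at position 47.
#' @param id Sequence id.
#' @return A `mod_seq`; `sim_truth()` holds `site` (47) and `vloop`
#'   (45:49).
#' @export
gen_modified_trna <- function(seed = 1L, phospho = TRUE, id = "tRNA-synth") {
  tokens <- TRNA_TOKENS
  withr::with_seed(seed, {
    tokens[34:36] <- sample(c("A", "C", "U"), 3, replace = TRUE)
  })
  if (phospho) tokens[47] <- "Up"
  s <- mod_seq(
    paste(ifelse(nchar(tokens) > 1, paste0("[", tokens, "]"), tokens),
      collapse = ""
    ),
    id = id
  )
  attr(s, "truth") <- list(site = 47L, vloop = 45:49, phospho = phospho)
  s
}

#' Generate a CID spectrum from a fragment
#'
#' Predicts the c/y ladder of `frag`, perturbs each m/z by Gaussian noise
#' in ppm, thins peaks by a dropout probability and assigns lognormal
#' intensities.
#'
#' @param frag A `mod_fragment` of length >= 2.
#' @param seed Integer seed.
#' @param noise_ppm Gaussian m/z noise sd in ppm.
#' @param dropout Per-peak dropout probability.
#' @param charges Product-ion charge states to emit.
#' @param polarity Spectrum polarity (negative by default).
#' @return A `spectrum`; `sim_truth()` holds the generating ladder and
#'   noise settings.
#' @export
gen_spectrum <- function(frag, seed = 1L, noise_ppm = 0, dropout = 0,
                         charges = 1L, polarity = "-") {
  stopifnot(dropout >= 0, dropout <= 1, noise_ppm >= 0)
  ladder <- cid_ladder(frag)
  pred <- tidyr::crossing(
    tibble::as_tibble(ladder),
    charge = as.integer(charges)
  )
  pred$mz <- mz(pred$neutral_mass, pred$charge, polarity)
  peaks <- withr::with_seed(seed, {
    keep <- stats::runif(nrow(pred)) >= dropout
    tibble::tibble(
      mz = pred$mz[keep] *
        (1 + stats::rnorm(sum(keep), 0, noise_ppm * 1e-6)),
      intensity = stats::rlnorm(sum(keep), meanlog = log(1e4), sdlog = 0.5)
    )
  })
  out <- spectrum(peaks, polarity = polarity)
  attr(out, "truth") <- list(
    ladder = ladder, noise_ppm = noise_ppm, dropout = dropout,
    charges = charges
  )
  out
}

#' Generate an XIC area table
#'
#' Emits modified/unmodified area pairs for one site across conditions and
#' replicates, with lognormal multiplicative noise around a stated
#' modified fraction.
#'
#' @param seed Integer seed.
#' @param fraction True modified fraction(s), one per condition (recycled).
#' @param conditions Condition ids.
#' @param n_rep Replicates per condition.
#' @param sdlog Lognormal sd of the area noise (0 = noiseless).
#' @param total Mean total area per replicate.
#' @param site Site id.
#' @return An XIC tibble for [stoichiometry()]; `sim_truth()` holds the
#'   generating fractions.
#' @export
gen_xic <- function(seed = 1L, fraction = 0.968, conditions = "wt",
                    n_rep = 3L, sdlog = 0, total = 1e6, site = "U47") {
  fraction <- rep_len(fraction, length(conditions))
  grid <- tidyr::crossing(
    condition = conditions,
    replicate = seq_len(n_rep)
  )
  grid$f <- fraction[match(grid$condition, conditions)]
  out <- withr::with_seed(seed, {
    purrr::pmap_dfr(grid, function(condition, replicate, f) {
      noise <- stats::rlnorm(2, meanlog = -sdlog^2 / 2, sdlog = sdlog)
      tibble::tibble(
        site = site,
        species = c("modified", "unmodified"),
        condition = condition,
        replicate = replicate,
        area = total * c(f, 1 - f) * noise
      )
    })
  })
  attr(out, "truth") <- list(fraction = stats::setNames(fraction, conditions))
  out
}

#' Generate a melting curve
#'
#' Boltzmann sigmoid with linear baselines on a temperature grid (default
#' 40-105 degrees C in 0.5-degree steps, the ramp of a UV melting
#' experiment), plus Gaussian absorbance noise.
#'
#' @param seed Integer seed.
#' @param tm Melting temperature (degrees C).
#' @param width Transition width (degrees C).
#' @param baselines Numeric `c(aL, bL, aU, bU)` for the folded/unfolded
#'   linear baselines (relative A260; the defaults give ~25%
#'   hyperchromicity).
#' @param noise_sd Gaussian absorbance noise sd (absolute units).
#' @param temperatures Temperature grid.
#' @return A tibble `temperature`, `absorbance`; `sim_truth()` holds the
#'   generating parameters.
#' @export
gen_melting <- function(seed = 1L, tm = 85.8, width = 2,
                        baselines = c(aL = 1.00, bL = 2e-4, aU = 1.23, bU = 2e-4),
                        noise_sd = 0,
                        temperatures = seq(40, 105, by = 0.5)) {
  a <- boltzmann_melt(
    temperatures, baselines[["aL"]], baselines[["bL"]],
    baselines[["aU"]], baselines[["bU"]], tm, width
  )
  a <- withr::with_seed(seed, a + stats::rnorm(length(a), 0, noise_sd))
  out <- tibble::tibble(temperature = temperatures, absorbance = a)
  attr(out, "truth") <- list(
    tm = tm, width = width, baselines = baselines, noise_sd = noise_sd
  )
  out
}

#' Generate a Michaelis-Menten kinetics table
#'
#' Initial velocities on a substrate grid (default 0.1-5.0 uM, the span of
#' a tRNA titration) with multiplicative Gaussian noise.
#'
#' @param seed Integer seed.
#' @param km True Km in nM.
#' @param vmax True Vmax in nM min^-1.
#' @param conc_nM Substrate grid in nM.
#' @param n_rep Replicates per concentration.
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @return A tibble `conc`, `conc_unit`, `vi`, `vi_unit`, `replicate`;
#'   `sim_truth()` holds `km` and `vmax`.
#' @export
gen_kinetics <- function(seed = 1L, km = 97.3, vmax = 9.9,
                         conc_nM = c(100, 200, 400, 800, 1500, 2500, 3800, 5000),
                         n_rep = 1L, noise_cv = 0) {
  grid <- tidyr::crossing(conc = conc_nM, replicate = seq_len(n_rep))
  v <- vmax * grid$conc / (km + grid$conc)
  v <- withr::with_seed(
    seed,
    v * (1 + stats::rnorm(length(v), 0, noise_cv))
  )
  out <- tibble::tibble(
    conc = grid$conc, conc_unit = "nM",
    vi = v, vi_unit = "nM_min",
    replicate = grid$replicate
  )
  attr(out, "truth") <- list(km = km, vmax = vmax)
  out
}

#' Generate a nuclease decay series
#'
#' Exponential intact-fraction decay sampled at the probing time points,
#' with multiplicative Gaussian noise; the t = 0 point is fixed at 1.
#'
#' @param seed Integer seed.
#' @param k True decay rate (min^-1).
#' @param times Sampling times in minutes.
#' @param noise_cv Coefficient of variation of the noise.
#' @return A tibble `time`, `fraction`; `sim_truth()` holds `k`.
#' @export
gen_decay <- function(seed = 1L, k = 0.1, times = c(0, 1, 3, 5, 10, 15, 30),
                      noise_cv = 0) {
  f <- exp(-k * times)
  f <- withr::with_seed(
    seed,
    pmax(1e-6, f * (1 + stats::rnorm(length(f), 0, noise_cv)))
  )
  f[times == 0] <- 1
  out <- tibble::tibble(time = times, fraction = f)
  attr(out, "truth") <- list(k = k)
  out
}

#' Generate an ortholog presence/absence matrix with implanted candidates
#'
#' Emulates a comparative-genomics screen: background genes get random
#' presence calls, a set of candidate genes is implanted with the perfect
#' phenotype profile (present in every positive genome, absent from every
#' negative one), and any background gene that matches the perfect profile
#' by chance is nudged off it so the implanted set is exactly recoverable.
#' Optional bit flips model orthology-call noise.
#'
#' @param seed Integer seed.
#' @param n_genes Total gene count.
#' @param n_pos,n_neg Phenotype-positive and -negative genome counts.
#' @param n_unlabeled Additional unlabeled genomes.
#' @param n_candidates Implanted perfect-profile genes.
#' @param n_uncharacterized How many implanted candidates are annotated
#'   uncharacterized.
#' @param bg_prob Background presence probability.
#' @param flip_rate Post-hoc bit-flip rate (0 = clean matrix).
#' @return An `ortholog_matrix`; `sim_truth()` holds the implanted ids.
#' @export
gen_ortholog_matrix <- function(seed = 1L, n_genes = 2826, n_pos = 7,
                                n_neg = 2, n_unlabeled = 0,
                                n_candidates = 9, n_uncharacterized = 5,
                                bg_prob = 0.5, flip_rate = 0) {
  stopifnot(n_candidates <= n_genes, n_uncharacterized <= n_candidates)
  genomes <- c(
    sprintf("pos%02d", seq_len(n_pos)),
    sprintf("neg%02d", seq_len(n_neg)),
    if (n_unlabeled > 0) sprintf("unl%02d", seq_len(n_unlabeled))
  )
  phenotype <- stats::setNames(
    rep(c("positive", "negative", "unlabeled"), c(n_pos, n_neg, n_unlabeled)),
    genomes
  )
  genes <- sprintf("gene%04d", seq_len(n_genes))
  withr::with_seed(seed, {
    pres <- matrix(
      as.integer(stats::runif(n_genes * length(genomes)) < bg_prob),
      nrow = n_genes, dimnames = list(genes, genomes)
    )
    cand_idx <- sort(sample(n_genes, n_candidates))
    pos_cols <- seq_len(n_pos)
    neg_cols <- n_pos + seq_len(n_neg)
    pres[cand_idx, pos_cols] <- 1L
    pres[cand_idx, neg_cols] <- 0L
    # background genes must not match the perfect profile by accident
    bg <- setdiff(seq_len(n_genes), cand_idx)
    perfect <- rowSums(pres[bg, pos_cols, drop = FALSE]) == n_pos &
      rowSums(pres[bg, neg_cols, drop = FALSE]) == 0
    for (g in bg[perfect]) {
      pres[g, sample(pos_cols, 1)] <- 0L
    }
    if (flip_rate > 0) {
      flip <- stats::runif(length(pres)) < flip_rate
      pres[flip] <- 1L - pres[flip]
    }
    annotation <- stats::setNames(
      sample(
        c("characterized", "uncharacterized"), n_genes,
        replace = TRUE, prob = c(0.7, 0.3)
      ),
      genes
    )
    cand_ids <- genes[cand_idx]
    unchar <- sample(cand_ids, n_uncharacterized)
    annotation[cand_ids] <- "characterized"
    annotation[unchar] <- "uncharacterized"
    m <- ortholog_matrix(pres, phenotype, annotation)
    attr(m, "truth") <- list(
      candidates = cand_ids,
      uncharacterized = sort(unchar)
    )
    m
  })
}
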