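---
title: "Methods: discovering a 2'-phosphate on tRNA by mass spectrometry"
author: "rnamodms"
output: rmarkdown::html_vignette
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the models and procedures it
implements, the parameters that matter, the design choices that were
genuinely open, and what the synthetic-data tests do and do not show.

## The problem

Thermophilic archaeal tRNAs carry a dense complement of
post-transcriptional modifications. One of them — a phosphate monoester on
the ribose 2′-OH of the variable-loop uridine (2′-phosphouridine, Uᵖ47) —
is invisible to nucleoside-level analysis (it is lost during nucleoside
preparation) and announces itself only as an unexplained +80 Da shift on
ribonuclease digestion fragments. The workflow that finds and
characterizes such a modification is entirely computational once the
spectra exist: predict fragment masses, notice the shift, identify its
elemental composition, localize it within the fragment from CID product
ions, quantify its stoichiometry from extracted-ion chromatograms, and
screen genomes for candidate enzymes whose presence tracks the
modification's phenotype. `rnamodms` implements each of those stages as a
tested, seedable function.

## Mass conventions

All masses are neutral monoisotopic masses assembled from an atomic-mass
table carried at **5 decimal places** (H 1.00783, C 12, N 14.00307,
O 15.99491, P 30.97376, S 31.97207), the precision convention of the
classic oligonucleotide mass calculators this workflow descends from.
Under this table the phosphate group HPO₃ weighs exactly 79.96632 Da and
a water 18.01057 Da. The 10-µDa granularity is three orders of magnitude
below the ppm-level tolerances used for matching (10 ppm ≈ 0.015 Da at
m/z 1500), so it never affects an assignment; it does fix the 5th decimal
of printed reference masses, which is why the table is part of the
package's documented contract rather than an implementation detail.
Charge-state arithmetic uses the electron-corrected proton mass
1.00727646 Da; only ±proton adducts are modeled.

A residue's mass is the free neutral nucleoside (from the editable
registry in `inst/extdata/modifications.tsv`) plus its 2′-sugar state
(+HPO₃ for 2′-phosphate, +CH₂ for 2′-O-methyl) plus named adducts
(+C₃H₃N for cyanoethyl). Pseudouridine deliberately shares uridine's
composition — the isomerization is mass-silent, and only cyanoethylation
makes it visible. Unknown codes fail loudly; nothing defaults to a parent
base. Registry entries sourced from standard modification databases
rather than first principles are flagged `source = "modomics"`.

## Digestion chemistry

The four nucleases differ in two orthogonal ways — what they cut after,
and which 2′-sugar states block them:

| enzyme | cuts 3′ of | blocked by | products |
|---|---|---|---|
| RNase T1 | guanosine family | any non-OH 2′ state | 5′-OH / 3′-P (or cyclic) |
| RNase A | pyrimidine family | any non-OH 2′ state | 5′-OH / 3′-P (or cyclic) |
| RNase I | every base | any non-OH 2′ state | 5′-OH / 3′-P (or cyclic) |
| nuclease P1 | every linkage | 2′-phosphate only | 5′-P / 3′-OH |

The transesterifying RNases proceed through the 2′-OH, so both
2′-O-methyl and 2′-phosphate block them; P1 is a hydrolase and stalls
only at the 2′-phosphate. That asymmetry is the workflow's diagnostic
lever: a P1 digest of modified tRNA collapses to mononucleotides
*except* for one dinucleotide spanning the 2′-phosphorylated residue
(pUᵖ–m⁵C, [M+H]⁺ 724.07, printed 724.1 at report precision). The
guanosine family for T1 defaults to all base-modified guanosines
(m²G, m²₂G, m⁷G, archaeosine) and the RNase A family to all pyrimidine
derivatives in the registry; both are overridable per call
(`t1_bases`, `a_bases`) because cleavage of heavily modified bases is an
empirical question the defaults should not hide. Whether T1 cleaves 3′
of archaeosine is one such open point; the default assumes yes.

Missed cleavages default to 0 (complete digest); fragments tile the
parent exactly, and each hydrolyzed bond adds one water to the summed
fragment mass — both properties are enforced by tests against a
per-bond brute-force oracle.

Chemical treatments are composition edits with their preconditions:
alkaline phosphatase removes terminal phosphomonoesters but never the
internal 2′-phosphate (its experimental BAP resistance is the point);
whether BAP would remove a 2′-phosphate sitting on a 3′-terminal residue
is not determinable from the underlying experiments, and the package
retains it. Periodate/β-elimination requires a vicinal diol on the
3′-terminal residue and converts the dinucleotide to the
triple-phosphorylated mononucleotide pUᵖp.

## CID ladders, matching, localization

For a fragment of length n the c series (5′ side, 3′-phosphate) and y
series (3′ side, 5′-OH) satisfy M(cᵢ) + M(y₍n−i₎) = M(fragment) + M(H₂O)
identically; the tests require this to hold below 1 nDa on random
fragments. Only c and y ions are predicted — the series this workflow
assigns — with the ladder stored as an ordinary tibble so further series
are an extension, not a rewrite.

Matching assigns every predicted ion (each charge in `charges`, spectrum
polarity) to the nearest observed peak within a ppm tolerance; one peak
may satisfy several ions and all assignments are reported, because c/y
isobars (same residue multiset, same termini) are common and silently
collapsing them biases coverage. Defaults are 10 ppm for precursors and
20 ppm for product ions, Orbitrap-class figures.

Localization places the unexplained mass on each candidate residue in
turn, rebuilds the ladder, and scores placements by matched-ion count
(ties: summed |ppm|, then lower position). All positions within a margin
of the best score are flagged `top`. Ties are **reported as sets** —
positional ambiguity in this workflow is resolved chemically
(phosphatase co-digestion, periodate chemistry), not computationally, so
the software must not pretend otherwise. A zero delta degenerates to an
all-positions tie and is reported as such.

## Characterizing the shift

`formula_search()` enumerates all compositions within element-count
bounds (default C ≤ 10, H ≤ 20, N ≤ 5, O ≤ 10, P ≤ 2, S ≤ 2 — sized for
single-residue modifications) and returns every candidate within the mmu
tolerance, sorted by absolute error then atom count. The search is
complete by construction: any in-bounds composition is found when its
exact mass is queried, and a property test checks this over random
compositions.

Completeness has a consequence worth stating plainly: rank 1 is not an
assignment. For the canonical observed shift 79.97067 Da at a 10 mmu
tolerance, C₄S (−1.40 mmu), H₃NPS (−1.72) and O₅ (−3.88) all sit closer
than HO₃P (+4.35 mmu), and a complete error-sorted search must say so.
Chemically implausible candidates are left to the analyst (or to the
discovery pipeline, which works with measured deltas at sub-mmu error,
where the phosphate ranks first outright). RDBE/valence or
isotope-pattern filtering is deliberately out of scope. Errors are
reported in millimass units (10⁻³ Da) and printed at 1 d.p. with
half-away-from-zero rounding, so +4.35 mmu prints as 4.4.

## Stoichiometry and dose response

The modified fraction of a site is area(mod)/(area(mod)+area(unmod)) per
replicate, averaged, assuming equal ionization efficiency of the two
co-eluting species — the standard working assumption for fragment pairs
differing by a small neutral group, recorded in the output attributes.
Area, not apex intensity, is the basis. A missing species row warns and
counts as zero; a zero total is undefined and reported missing, never
0 or 1. Dose–response tables divide each modified fragment's intensity
by a control fragment in the same condition (cancelling per-condition
loading and ionization scale), anchor the first condition at 1.0, and
flag strict monotone decreases — the expected signature when an eraser
enzyme is titrated up.

## Phylogenetic profiling

The screen consumes a precomputed ortholog presence/absence matrix —
orthology inference itself is out of scope, since the discovery logic is
the intersection, not the clustering. With defaults
(`max_pos_misses = 0`, `max_neg_hits = 0`) it is the strict Venn:
present in all phenotype-positive genomes, absent from all negatives,
unlabeled genomes ignored. Both tolerances are exposed for noisy
matrices, and relaxing them can only grow the candidate set (tested).
The genome-scale fixture (2,826 genes, 7 positives, 2 negatives, 9
implanted perfect profiles of which 5 uncharacterized) reproduces the
shape of the real screen; background genes that match the perfect
profile by chance are nudged off it so the implanted set is exactly
recoverable — with ~2,800 genes and 9 informative genomes, roughly five
such collisions are expected at random, so without the nudge the count
"9" would not be a generator invariant.

## Biophysical fits

**Melting.** A(T) = bl(T) + (bu(T) − bl(T))/(1 + exp((Tm − T)/w)) with
linear folded/unfolded baselines, fitted by Levenberg–Marquardt
(`minpack.lm::nlsLM`); Tm is the sigmoid's inflection. The underlying
experiments report only "the inflection point", so the sigmoid is a
package choice; to keep it auditable a model-free estimate (maximum of
the smoothed-spline dA/dT) is always returned alongside, and the two
must agree within 0.2 °C on clean model curves. Curves must span the
transition (≥ 20 points, an absorbance increase present); flat curves
are an error, not a Tm of convenience.

**Michaelis–Menten.** Unweighted nonlinear least squares of
Vᵢ = Vmax·S/(Km + S), initialized at Vmax₀ = max Vᵢ and Km₀ = S nearest
half-max. Unweighted because the reference analyses used a commercial
fitter with no stated weighting. Units are carried explicitly (nM/µM/mM,
nM min⁻¹/nM s⁻¹) and converted, never assumed. A fitted Km outside the
concentration grid triggers a warning that the estimate is effectively
unbounded on that side — note this fires legitimately for the canonical
tRNA titration, whose grid floor (100 nM) sits a hair above the true Km
(97.3 nM).

**Decay.** I(t) = exp(−k·t) with k ≥ 0, initialized from a log-linear
regression; half-life ln 2/k; a ratio utility compares two series (e.g.
±modification under the same nuclease). A constant series fits k = 0
with infinite half-life.

All three fits are deterministic given the data — no random restarts.

## Synthetic data: what it emulates, what it does not

The generators produce a 76-nt cloverleaf-like tRNA with a realistic
archaeal modification complement and the 2′-phosphouridine at V-loop
position 47; CID spectra with Gaussian m/z noise **in ppm**, peak
dropout, and lognormal intensities; XIC areas with lognormal
multiplicative noise; melting curves with Gaussian absorbance noise;
velocities with multiplicative Gaussian noise. These noise shapes are
standard instrument-error models chosen once (the source experiments
state none); defaults are 5 ppm m/z noise (Orbitrap-class), 10% dropout
for the localization study, and the study-condition values elsewhere
(stoichiometry 0.968; Tm 85.8/79.2 °C on a 40–105 °C, 0.5 °C grid;
Km 97.3 nM / Vmax 9.9 nM min⁻¹ on a 0.1–5.0 µM grid; decay sampling at
0/1/3/5/10/15/30 min; the 2,826 × 9 ortholog matrix). Every generator
records its truth as an attribute (`sim_truth()`) and is bit-identical
under a fixed seed.

What passing these tests shows: the pipeline's inference is correct when
its error model holds. What it does not show: robustness to co-eluting
isobaric fragments, isotope envelopes, retention-time effects, uneven
ionization between modified and unmodified species, or orthology-call
biases — none of which the generators simulate. Results on real data
inherit those caveats.

Problem sizes used by the test suite and the acceptance script —
1000-sequence digestion oracle sweeps, 1000-fragment ladder identities,
100-seed Monte-Carlo loops for localization, stoichiometry, Tm and Km —
were chosen to give stable pass/fail statistics on a single CPU.

## Known limitations

- Average (non-monoisotopic) masses, isotope envelopes and non-proton
  adducts are out of scope; vendor raw files and mzML are not parsed
  (peak lists come in as TSV or MGF-style blocks).
- `discover()` assigns each precursor to the candidate fragment with the
  smallest residual shift below `max_delta`; with very dense digests or
  multiple co-occurring unknowns the assignment should be reviewed
  against the listed alternatives rather than trusted blindly.
- The formula search ranks by mass error alone (see above); chemical
  plausibility is the analyst's judgement.
- Digestion is all-or-none per the 2′-state rules; partial cleavage
  kinetics and sequence-context preferences are not modeled.
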