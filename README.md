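# rnamodms

An R toolkit for discovering and characterizing post-transcriptional RNA
modifications from LC–MS/MS data, built around the computational workflow
that identifies **2′-phosphouridine (Uᵖ)** — a phosphate monoester on the
ribose 2′-OH of an internal residue — in the 5-nt variable loop of
thermophilic archaeal tRNA, together with the comparative-genomics screen
for its writer enzyme (an archaeal RNA kinase) and the biophysical fits
that characterize the modification and its writer/eraser pair.

It is written for RNA mass-spectrometrists and tRNA-modification labs who
want the in-silico half of such a study as reusable, tested, scriptable
functions: tibbles in, tibbles out, pipe-friendly, with `autoplot()` and
broom-style `tidy()`/`glance()` on every fitted object.

## What it computes

**Mass prediction.** Elemental-composition arithmetic over C/H/N/O/P/S and
monoisotopic mass/m-z for modified oligonucleotides. A residue is a
registered nucleoside (U, C, G, A, Ψ, s⁴U, m⁵C, m²G, m²₂G, m¹A, ac⁴C,
archaeosine, D, …) plus a 2′-sugar state — OH, 2′-*O*-methyl (+CH₂) or
2′-phosphate (+HPO₃) — plus optional adducts (cyanoethyl, +C₃H₃N). An
oligo of n residues weighs

    M = Σ M(nucleoside_i) + (n−1)·(M_HPO3 − M_H2O) + terminal increments

and ionizes at m/z = (M ± z·1.00727646)/z.

**In-silico digestion.** RNase T1 (3′ of guanosines), RNase A (3′ of
pyrimidines), RNase I (3′ of every base) and nuclease P1 (every linkage),
with the 2′-sugar-state chemistry that makes the workflow diagnostic: the
transesterifying RNases require a free 2′-OH, so 2′-O-methyl or
2′-phosphate blocks them, while P1 stalls only 3′ of a 2′-phosphate —
leaving a signature pUᵖ–m⁵C dinucleotide ([M+H]⁺ at m/z 724.1) where
everything else collapses to mononucleotides. Alkaline-phosphatase,
cyanoethylation and periodate/β-elimination transforms are modeled as
composition edits.

**CID spectra.** Complementary c/y product-ion ladders
(M(cᵢ) + M(y₍n−i₎) = M(fragment) + M(H₂O)), peak matching at ppm
tolerance, mass-shift localization by exhaustive placement (ties reported
as sets, never silently resolved) and shotgun precursor-to-fragment
identification across a sequence set, including a hypothesized
2′-phosphate variant per U-containing fragment.

**Mass-shift characterization.** Bounded exhaustive
elemental-composition search: every composition within element bounds
whose mass lies within a mmu tolerance of the observed shift, with signed
errors (79.96632 Da, the phosphate, is recovered at +4.4 mmu from the
canonical observed shift of 79.97067 Da).

**Quantification.** Modification stoichiometry from extracted-ion
chromatogram areas, fraction = area(mod)/(area(mod)+area(unmod)), and
dose–response tables normalized to a control fragment with a
monotone-decrease flag (the eraser-titration signature).

**Phylogenetic profiling.** The strict Venn screen: genes present in
every phenotype-positive genome and absent from every negative one, with
relaxable mismatch tolerances, then an annotation filter for
uncharacterized candidates.

**Biophysics.** Boltzmann two-state melting fits (Tm = inflection point,
with an independent smoothed-derivative estimate), first-order
nuclease-decay fits, and Michaelis–Menten fits (Vᵢ = Vmax·S/(Km+S)) with
explicit unit handling.

**Synthetic data.** Seeded generators for every input — a 76-nt modified
tRNA with the V-loop 2′-phosphouridine at position 47, noisy CID spectra,
XIC tables, melting curves, kinetics tables, decay series and
ortholog matrices with implanted candidates — so the whole pipeline is
testable without instrument data.

## Worked example

Discover the modification from synthetic data: the pipeline sees CID
spectra of the truly modified tRNA but only the unmodified reference
sequence.

```r
library(rnamodms)

mod <- gen_modified_trna(1, phospho = TRUE)   # what the cell has
ref <- gen_modified_trna(1, phospho = FALSE)  # what the pipeline knows

d     <- digest(mod, "T1")
vloop <- d$fragment[[which(d$start == 47)]]
vloop
#> <mod_fragment> tRNA-synth:47-53  5'-OH [Up][m5C]CAAUG 3'-P  (7 nt, 2337.27827 Da)

spec <- gen_spectrum(vloop, seed = 1, noise_ppm = 3, dropout = 0.05)
attr(spec, "precursor_mz") <- oligo_mz(vloop, 2, "-")
attr(spec, "precursor_z")  <- 2L
xic <- gen_xic(seed = 1, fraction = 0.968, sdlog = 0.05)

discover(ref, list(vloop = spec), xic = xic)
#> == Modification discovery report ==
#> 1 spectra analyzed; 1 carry an unexplained mass shift
#>   vloop: fragment U[m5C]CAAUG (47-53), delta 79.96632 Da -> HO3P (0.0 mmu), site 47 (U)
#>   stoichiometry U47 [wt]: 96.7%
```

The report reads: the observed precursor is 79.96632 Da heavier than the
predicted V-loop fragment; the only composition explaining the shift at
sub-mmu error is HO₃P (a phosphate); the c/y ions place it uniquely on
the uridine at position 47; and the modified species accounts for 96.7%
of the XIC area (generating truth 96.8%).

A thin command-line wrapper over the same functions ships in
`inst/cli/rnamodms.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","rnamodms.R",package="rnamodms"))')" \
  mz --mass 723.05916 --z 1 --polarity +
#> 724.07
```

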