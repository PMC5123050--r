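---
title: "Models and design choices in clamplock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in clamplock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clamplock)
```

clamplock implements the four quantitative analyses used to establish that a
small viral protein binds inside the DNA-binding channel of the archaeal RNA
polymerase (RNAP) and immobilises its clamp: equilibrium binding affinity,
crosslink-derived distance restraints, single-molecule FRET population
structure, and promoter-motif organisation of the viral genome. This
vignette explains each model, its assumptions and tunable parameters, what
the synthetic-data generators do and do not emulate, and the numerical
choices made where the design was genuinely open.

## Tight-binding (Morrison) Kd estimation

**Model.** For a 1:1 equilibrium R + L ⇌ RL with dissociation constant
$K_d$, mass action in *total* concentrations $R_T$, $L_T$ gives the
fraction of ligand bound as

$$f = \frac{(K_d + R_T + L_T) - \sqrt{(K_d + R_T + L_T)^2 - 4 R_T L_T}}{2 L_T}.$$

This closed form is required — rather than the hyperbolic Langmuir
isotherm — whenever $L_T$ is comparable to $K_d$, as in a gel-shift
titration of 1 nM labelled ligand against 1–100 nM polymerase, because the
free-receptor ≈ total-receptor approximation then fails. The discriminant is
analytically non-negative; the implementation clamps tiny negative
floating-point residues to zero before the square root. The closed form is
verified in the test suite against an independent bisection solve of the
mass-action equation to $|\Delta| < 10^{-9}$ across three decades of all
three parameters.

**Fitting.** `fitKd()` minimises $\sum_i (f_i^{obs} - f(K_d))^2$ by
Levenberg–Marquardt (minpack.lm) with a single free parameter. Choices:

* *Initial value*: the receptor concentration at which the observed fraction
  crosses 0.5 (linearly interpolated), or the geometric mean of the receptor
  range if it never crosses — parameter-free and robust.
* *Bounds*: $K_d \in [10^{-4}, 10^{6}]$ nM keeps the optimiser in the
  physically meaningful regime; the model degenerates only at $K_d \le 0$.
* *Weights*: none. Band densitometry provides no per-point variances, so
  replicates enter as independent equally weighted points.
* *Uncertainty*: the report carries both the Jacobian-based standard error
  of the fit and, when ≥ 2 replicates are present, the between-replicate
  standard deviation of per-replicate estimates — a printed "±" can mean
  either, so both are exposed.
* Fitting operates on fraction bound in [0, 1]; percentages are an I/O
  formatting concern.

Non-convergence and degenerate inputs (constant or non-finite fractions,
fewer than 3 points, < 2-fold receptor range) are reported as errors or an
honest `converged = FALSE`, never as a silent number.

`normalizeDoseResponse()` covers the companion transcription-repression
readout: raw transcript signals measured at increasing inhibitor:RNAP
stoichiometry are divided by the zero-stoichiometry reference, so activity 1
means uninhibited.

## Crosslink-MS distance validation

**Model.** An amine-reactive crosslinker of fixed arm length constrains the
Cα–Cα distance of a linked residue pair; for BS3 the accepted maximum is
27.4 Å. Claimed pairs are mapped onto a Cα-only model
(`readStructure()`: PDB or mmCIF, first model, highest-occupancy altloc with
ties to "A", residues without Cα dropped with a warning) and each mappable
pair is scored `satisfied = distance ≤ limit`. Pairs with an end missing
from the model are reported `mappable = FALSE`, and all three counts
(satisfied / mappable / total) are always printed because published
denominators ("observable residue pairs") vary.

**Null distribution.** Observed distances are compared with random residue
pairs drawn from the structure (`sampleNull()`), by default lysines only —
the crosslinker's dominant reactivity — with serine/threonine/tyrosine
available via `residueClasses`, and with an optional chain restriction so
the null can be confined to the polymerase while excluding the ligand.
Sampling is uniform over unordered pairs; `exhaustive = TRUE` enumerates all
pairs deterministically, and the test suite requires the sampled mode to
match enumeration (KS < 0.05 at n = 10⁴). `compareDistributions()` reports
shared-edge histograms and the two-sample Kolmogorov–Smirnov statistic.

**Interface calling.** For inter-protein links between the ligand chain and
the complex, the structure-side anchors should be mutually consistent: a
link is flagged as an outlier when its anchor lies farther than
`clusterLimit` from the leave-one-out centroid of the remaining anchors.
The default limit, 2 × 27.4 + 20 ≈ 75 Å (two crosslinker reaches plus the
~20 Å width of the ligand), is exposed as an argument since no standard
value exists. Upstream search scores/FDRs are treated purely as an input
filter (`filterCrosslinks()`), applied before any statistic, and are never
recomputed.

All statistics are functions of inter-atomic distances only, and the suite
checks invariance under rigid-body rotation plus translation to
$|\Delta d| < 10^{-6}$ Å.

## smFRET population analysis

**Histogramming.** `buildHistogram()` uses half-open bins `[edge, next)` —
a sample exactly on an edge falls in the right-hand bin — with bin width
0.05 over (−0.2, 1.2) by default. Apparent efficiencies legitimately fall
outside [0, 1] through shot noise, so samples are never clipped;
out-of-range samples are folded into the boundary bins and reported. The
bin width and range are conventions (field practice varies); counts are
conserved under any choice.

**Mixture fitting.** `fitMixture()` performs least squares of a sum of one
or two Gaussian curves on the bin counts at bin centres — the convention
under which single-molecule population means and their standard errors are
usually quoted — rather than maximum likelihood on raw samples. Component
*weights are areas* (amplitude × sd, normalised), matching the usual
"% population" labels; whether published percentages are areas or
amplitudes is often unstated, and the area convention is what this package
reports. Start values are data-driven (top bin; for two components, the
best bin at least three bin widths away); bounds keep means inside the
histogram and sds above a quarter bin width.

**Model-order selection.** `selectModel()` compares the one- and
two-component fits by BIC with a decision margin of 10, ties and small
improvements going to the simpler model. The BIC is computed from the
*Poisson* likelihood of the bin counts under each fitted curve,
$-2\sum_i (y_i \log \mu_i - \mu_i) + 3k \log m$. A Gaussian-iid BIC on the
raw least-squares residuals was evaluated first and rejected: bin counts
are strongly heteroscedastic, and in simulation at the study conditions
(n = 5000, sd = 0.08) that criterion selected a spurious second component in
~40% of genuinely one-component datasets, while the Poisson form made no
selection errors in either direction over 60 seeds. The fit itself remains
least-squares; only the selection score uses the Poisson likelihood. A
candidate fit that failed to converge is never selected — the degenerate
two-component fit on one-component data frequently cannot converge, which is
itself evidence for the simpler model.

**Distance conversion.** `forsterDistance()` implements
$R = R_0 (1/E - 1)^{1/6}$, defined for $E \in (0, 1)$, with the exact
inverse `forsterEfficiency()` (round-trip identity to $10^{-9}$ relative).
The default $R_0 = 52$ Å is a calibration constant: it is the value under
which the three published mean efficiencies of the clamp dye pair
(0.67, 0.40, 0.58) round to the three published distances (46, 56, 49 Å).
Dye photophysics is outside the package's scope; supply your own $R_0$ for
other pairs.

## Promoter-motif analysis

**Transcription units.** Archaeal mRNAs here are leaderless — the
transcription start site lies within a few bases of the start codon — so
the promoter TATA element sits a short fixed distance upstream of the start
codon, and only the first gene of each co-transcribed run has a promoter.
`callTranscriptionUnits()` merges consecutive same-strand genes whose
intergenic gap is ≤ `maxGap`; a strand flip always splits. The published
gene-to-unit reduction for this genome does not state its gap threshold, so
`maxGap` has no hidden default semantics: 50 bp is a conventional operon
gap, and reproducing a specific published unit count on a real annotation
may require tuning it. Each unit's lead gene is its 5′-most member in gene
orientation.

**Windows and scanning.** `extractWindows()` returns the −100..+50 window
around the lead gene's start codon (+1 = first codon base, no position 0),
reverse-complemented for minus-strand genes, clipped and flagged at contig
ends, never padded. `iupacScan()` matches a degenerate IUPAC pattern
(default `TTTWWAA`, the archaeal TATA consensus; W = A/T) at every offset on
the window strand, overlapping hits included, via Biostrings' fixed = FALSE
matching; the test suite holds it equal to a position-by-position
brute-force oracle on random sequences. Scanning is restricted to the coding
strand because promoters are directional. Spacing is measured from the motif
3′ end to the base immediately before the start codon.
`summarizeHits()` reduces to the nearest hit per unit (by absolute spacing)
for the spacing mean ± sd, and counts units with any hit and with a hit in
the expected 20–30 bp window. De-novo motif discovery is out of scope; the
scanner tests a stated consensus.

## Synthetic data: what it does and does not emulate

Every generator is a pure function of its parameters and seed, its output
re-parses through the package's own readers losslessly, and its truth slot
records all parameters a recovery test needs.

* `genTitration()` evaluates the Morrison model at the published titration
  design and adds i.i.d. Gaussian noise on fraction bound, clipped to
  [0, 1] — the conventional densitometry noise assumption, since gel
  quantification reports no noise model. Replicate counts and noise
  magnitudes are conventions, not measured values.
* `genFretSamples()` draws from the stated Gaussian mixture without
  clipping. It emulates population structure only — no photobleaching,
  blinking, dye anisotropy or burst-size effects, so passing recovery tests
  demonstrate correctness of the fitting machinery, not robustness to
  photophysical artefacts.
* `genToyComplex()` places Cα atoms on a rigid lattice (3.8 Å along each
  chain, 10 Å between chains, all lysines, occupancy 1.00) and plants
  exactly the requested numbers of satisfied and violated links, verified
  by brute-force distance recomputation. It is a correctness fixture, not a
  protein-like decoy.
* `genGenome()` builds genes alternately on both strands, each spaced to
  lead its own unit, and plants a concrete instantiation of the motif at a
  spacing drawn from N(25, 5²) bp for the chosen fraction of genes; the
  remainder of every −100..+50 window is kept motif-free by rejection
  (background is uniform A/C/G/T). Recovery is therefore exact by
  construction. Real genomes have compositional bias, overlapping genes and
  spurious motif matches; the generator deliberately excludes these so that
  recovery failures always indicate pipeline defects.

## Problem sizes and numerical conventions

The simulations used in the tests and the acceptance script are: 200
titrations of 7 points each for the Kd recovery; 5,000 efficiency samples
per histogram with 20 seeds for the FRET recovery; a 40-residue toy complex
with 10⁴ null draws for the crosslink calibration; and a 46-gene synthetic
genome for the promoter scan. These sizes match the published designs where
stated (titration series, 5,000-sample histograms, 46 units) and are
otherwise the package's choices. Degenerate inputs follow one rule
throughout: impossible requests error with a named cause; fits that run but
fail report `converged = FALSE`.

## Running on real data (optional recipes)

The crosslink pipeline reproduces the published satisfaction statistics when
given the real inputs: download the polymerase–DNA complex structure
(PDB 4B1O) as mmCIF, export the published crosslinked residue-pair table as
the five-column TSV (`Chain1, Residue1, Chain2, Residue2, Score`), supply a
two-column chain map reconciling subunit names with chain IDs, and run
`clamplock xl-validate --structure 4b1o.cif --links links.tsv --limit 27.4
--null-n 10000`. Likewise the promoter pipeline runs on the real viral
genome and annotation (NCBI) via `clamplock promoter-scan`; note the
published unit count depends on the unstated intergenic gap threshold, so
`--max-gap` should be varied. Neither recipe is exercised by the tests,
which are fully offline.

## Known limitations

* Single-site binding only: no Hill/cooperative or two-site models, no
  global fits across buffer conditions.
* Distances are Cα–Cα; no side-chain, solvent-accessible-surface or
  through-space path metrics for crosslinks.
* Mixture fitting is binned least squares with at most two components; no
  EM on raw samples, no dwell-time kinetics.
* The scanner matches a single consensus; no PWM scoring or motif
  discovery.
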