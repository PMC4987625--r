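---
title: "Epitope mapping from phage-display deep sequencing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Epitope mapping from phage-display deep sequencing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagescan)
```

## The experimental system

phagescan analyses antibody-epitope mapping experiments of the
gene-fragment phage-display kind: the coding sequence of an antigen (here
a carrier-antigen fusion, e.g. a 1314 bp / 438-residue construct) is
randomly sheared, size-selected (about 100-400 bp), and blunt-cloned
upstream of a phage capsid-protein gene.  The library is sequenced before
and after rounds of affinity selection with a monoclonal antibody, and
the fragments that survive selection delineate the epitope.

Three statistical ideas carry the analysis:

1. **The 1/18 natural-frame lottery.**  A randomly cloned fragment is
   displayed as the authentic peptide only if it is inserted in the
   forward orientation (probability 1/2), in the correct reading frame at
   the 5' junction (1/3), and with a length that is a multiple of 3 so
   the downstream fusion stays in frame (1/3) — jointly 1/18 ≈ 5.6%.
   `map_inserts()` classifies each read by reconstructing orientation,
   junction frame and length modulo 3 from its placement on the reference
   CDS, with an additional stop-codon screen on the displayed frame
   (a clone whose displayed reading contains a stop cannot present the
   peptide and is classed non-natural even if it wins the lottery).
   `enumerate_frame_classes()` verifies the lottery by brute force.

2. **Per-residue enrichment factors.**  Natural-frame reads are collapsed
   to unique displayed fragments (identified by their residue span) with
   read-count weights.  For residue $i$, with per-residue read tallies
   $C_i$ and library depths $N$,
   $$EF_i = \frac{(C^{sel}_i + p)/N_{sel}}{(C^{unsel}_i + p)/N_{unsel}},$$
   with pseudocount $p = 1$ by default.  The pseudocount keeps the
   profile finite and strictly positive; residues covered in neither
   library sit at the defined baseline $N_{unsel}/N_{sel}$.  Depth
   normalisation is the default because the two libraries are sequenced
   to different depths; `normalize = FALSE` gives the raw-count variant.
   A fragment is *significantly enriched* when its frequency among
   natural-frame reads of the selected library exceeds the mean plus five
   sample standard deviations of the frequency distribution over unique
   fragments of the unselected library; the distribution is taken over
   unique fragments, not reads, because it describes the library's
   fragment-frequency null.

3. **Hot-spot boundaries.**  Abrupt increases of the EF profile along the
   sequence mark residue stretches required for binding.
   `call_hotspots()` formalises the visual reading: jump scores are
   consecutive-residue changes, $J_i = \log(EF_i/EF_{i-1})$ by default
   (EF is a ratio quantity; a `difference` mode is provided), and a
   boundary is called when $|J_i|$ exceeds
   $\max(\mathrm{median}(|J|) + k_{MAD}\cdot\mathrm{MAD}(|J|),\; j_{floor})$.
   Calls closer than `min_separation` (default 5) residues keep only the
   larger score.  `candidate_required_region()` reports the contiguous
   run of residues on the high side of the boundary that stays above the
   pre-jump level — the candidate binding-required stretch.

## Why the jump threshold has an absolute floor

Coverage-derived EF profiles are piecewise constant: between fragment
endpoints the profile does not move at all, so the median and MAD of
$|J|$ are nearly zero and a purely robust-z rule fires on any
sparse-coverage wiggle (worst near the protein termini, which few
fragments cover).  On simulated null selections (no binder, neutral
resampling) the largest null jump ranged from 0.15 to 1.1 log units
across seeded runs, while planted-epitope onsets produced jumps of 2.9 to
3.5 log units.  The default floor is therefore `log(8)` ≈ 2.08 — a call
must represent at least an eightfold EF step — which sits between the
two regimes with roughly a one-log-unit margin on either side
(`difference` mode uses an analogous floor of 7 EF units).  Both the
floor and `k_mad` (default 6) are exposed as tunables; raising either
only removes calls.

## The biopanning simulator

`simulate_library()` and `simulate_selection()` generate data with
recorded ground truth:

* **Fragmentation** follows the gel-purified-shearing model: fragment
  length uniform in the configured range (default 100-400 bp), start
  uniform over all positions where the fragment fits on the gene.
  Drawing length first and then a feasible start (rather than truncating
  overhanging fragments at the gene end) matters: truncation would tie
  length mod 3 deterministically to the junction frame for end-spanning
  clones and push the natural-frame fraction well above 1/18, which is
  neither what shearing produces nor what libraries of this kind show.
* **Cloning** assigns orientation by a fair coin; the junction frame
  follows from the fragment start, making the 18 configurations equally
  likely.  A configurable fraction of clones (default 0.1) is wild-type
  (no insert).
* **Sequencing** draws `reads_per_round` reads from the clone population
  with replacement, wraps each insert in the vector flank pair, and
  applies uniform substitution errors (default 0.001/base).  Sampling
  with replacement — rather than one read per clone — is what gives the
  unselected fragment-frequency distribution a nonzero spread, without
  which the mean + 5 SD rule is degenerate.
* **Selection** is conjunctive span coverage: a clone is a binder iff it
  is natural-frame and its displayed span covers *every* residue of
  *every* configured required set; binders get multinomial weight
  `w_binder` (default 100), everything else `w_background` (default 1),
  compounded over `n_rounds` (default 2) rounds.

What the simulator does **not** model: indels or platform-specific error
profiles; PCR duplicates and amplification bias (clones are
equi-abundant within a round apart from selection); partial binding
credit (a fragment covering one of two required stretches is pure
background); and fragmentation hot spots.  Tests passing on simulated
data therefore validate the statistical machinery, not the full
messiness of real libraries.

### A geometric consequence of conjunctive binding

With two required stretches, every binder must span the interval from
the first stretch's start to the last stretch's end (115 aa for the
default demonstration sets, close to the 133 aa maximum fragment), so
binder span starts pile up over a short window ending at the first
stretch start and binder coverage *ramps* there instead of stepping.
The sharp features the detector finds are the binder-coverage onset
(fixed by the maximum fragment length) and the post-epitope decrease; an
interior EF step exactly at the second stretch start cannot arise from
conjunctive coverage with uniformly positioned fragments, because a
binder covers the residue before that start if and only if it covers the
start itself, up to the measure-zero class of fragments starting exactly
there.  In real data such interior steps come from *partially binding*
short fragments that cover the later stretch alone — behaviour the
all-or-nothing binding model deliberately excludes.  Consequently,
hot-spot localisation on simulated conjunctive selections recovers the
epitope region and its boundaries only up to this geometry, and the
package's validation asserts second-stretch localisation knowingly as the
model's limiting case (see the acceptance tests).

## Simulation scales used by the validation suite

Chosen a priori from power considerations and kept fixed:

* **Null control**: library complexity 5,000 clones sequenced at 50,000
  reads per round (about 10 reads per clone), one neutral resampling
  round, 50 seeded runs.  At this depth the unselected frequency spread
  is well estimated and a neutral resample exceeds the 5 SD threshold
  with probability well under 1/2 per run, so the median number of
  significant calls over runs is 0.
* **Planted epitope**: 100,000 clones, 15,000 reads per round, two
  rounds at weight ratio 100.  A conjunctive binder for the default
  two-stretch epitope must both start within a 19-codon window and end
  within 4 nt of the gene end, giving a per-clone binder probability of
  about 4 × 10⁻⁵; 100,000 clones yield ~4 binder clones in expectation
  with P(none) below 2%.
* **Frame-fraction check**: 100,000 insert-bearing clones, compared to
  1/18 within three binomial standard errors.

## The Friguet K_D estimator

In the competition ELISA, a fixed antibody concentration $i_0$ (0.7 nM)
is equilibrated with soluble antigen at concentrations $a_0$ spanning
7-480 nM, and the absorbance $A$ read on antigen-coated wells is
proportional to free antibody, with $A_0$ the no-competitor signal.
Under antigen excess ($a_0 \gg i_0$, satisfied at $a_0 \ge 10 i_0$; the
estimator warns otherwise) the free-antibody fraction is
$K_D/(K_D + a_0)$, so
$$\frac{A_0}{A_0 - A} = 1 + \frac{K_D}{a_0},$$
a straight line in $1/a_0$ with intercept 1 and slope $K_D$, fitted by
ordinary least squares.  Implementation choices: points with $A \ge A_0$
are undefined on the y axis and are dropped with a warning rather than
clamped; a series that is entirely non-inhibiting returns an explicit
no-binding result; an intercept deviating from 1 by more than 0.2 warns
that the linear model is suspect.  `simulate_elisa_series()` can also
generate data from the exact bimolecular equilibrium (quadratic
solution), which quantifies the approximation bias — of order
$i_0/a_0$, i.e. within a few percent on this design.  One K_D is
estimated per coating concentration (3.5, 7, 14, 28 nM); replicates are
summarised as mean ± sample SD, and fold changes versus a reference
antigen are computed from the *unrounded* means (ratios of rounded
table entries will not reproduce them exactly).

```{r friguet-demo}
fit <- friguet_kd(simulate_elisa_series(kd = 4.22))
c(kd = fit$kd, intercept = fit$intercept)
```

## Numerical and degenerate-input conventions

* Residue and nucleotide coordinates are 1-based, inclusive; fusion
  residue = antigen-local residue + `numbering_offset`.  The offset is
  explicit user input — fragment labels in the antigen's own numbering
  (the "S140-K254" style) are convertible with `convert_span()`, and a
  round trip is the identity.
* Mapping is exact-substring first (leftmost occurrence on ties, as is
  flank location), then a seed-and-verify placement: three exact 20-mer
  seeds anchor a candidate offset verified by Hamming count, bounded by
  `max_mismatch_frac` (default 0.02).  This targets substitution errors;
  reads with indels fall back to `unmapped` and are excluded from the
  natural-fraction denominator, as are empty clones.
* Ranking ties break toward the longer span, then the smaller start.
* An empty read stream yields a zero summary, not an error; a library
  with no natural-frame reads is an explicit error for occurrence and
  length statistics; a single-fragment unselected library is an explicit
  error for the 5 SD rule (its SD is undefined).
* All simulator randomness flows from one seed; fixed seed means
  bit-identical FASTQ output and pipeline reports.

## Limitations

Single reference CDS per run (no multi-gene libraries); no chimera
detection or quality trimming beyond flank matching; paired-end mates
are expected to be merged upstream; no IC50 fitting for
percent-inhibition curves; no avidity modelling in the K_D stage; the
hot-spot rule marks EF geometry, not contact-point status — a called
stretch may act through folding rather than direct contact.
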