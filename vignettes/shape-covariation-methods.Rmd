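---
title: "Methods: protein-sequence / DNA-shape covariation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: protein-sequence / DNA-shape covariation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ShapeCovar)
```

## The scientific question

Transcription factors recognise their DNA binding sites through two
complementary mechanisms: *base readout* — direct contacts to the chemical
signatures of base pairs, chiefly in the major groove — and *shape readout* —
recognition of the sequence-dependent 3D structure of the double helix, in
particular minor-groove geometry, whose narrowing focuses negative
electrostatic potential and attracts positively charged side chains
(arginine, lysine, and histidine when protonated).  Homeodomains are the
canonical test case: the ~60-residue domain inserts its third helix
(residues 47–55, the recognition helix) into the major groove and its
flexible N-terminal tail (residues 1–9) into the minor groove.

`ShapeCovar` quantifies, over a family of such proteins with high-throughput
binding data (protein-binding-microarray 8-mer E-scores, or pre-aligned
bacterial one-hybrid sites), how the amino-acid sequence covaries with

1. the *nucleotide sequence* of the preferred binding sites (via position
   frequency matrices), and
2. the *3D shape* of those sites (via pentamer-model structural features),

at the level of whole similarity matrices and of individual
(protein position, DNA position) pairs.

## Shape prediction from a pentamer table

Structural features are assigned with a sliding-pentamer model: a lookup
table maps each of the 512 strand-distinct pentamers to the minor groove
width (MGW, Å) and propeller twist (ProT, degrees) of its central base pair
and to the roll and helix twist (degrees) of its two central base-pair
steps.  For a sequence of length $L$:

* MGW and ProT at position $i$ come from the pentamer centred at $i$,
  defined for $i \in [3, L-2]$; the outermost two positions on each side are
  reported as missing, never imputed.
* Roll and HelT at step $j$ (between bases $j$ and $j+1$) average the
  contributions of the pentamers whose central steps cover $j$ — two
  contributors for interior steps, one at the edges of coverage.  The
  published pentamer model does not prescribe how overlapping step values
  combine; averaging was chosen because it is continuous in the sequence and
  exactly reverse-complement symmetric, and it is flagged here as a package
  convention rather than an upstream fact.

Reverse-complement queries resolve through canonicalization: base-pair
parameters are strand-symmetric, step parameters swap their two values.  The
loader accepts either a canonical-512 or a raw-1024 table and verifies
completeness, finiteness, and reverse-complement consistency.

Per protein, the *average shape profile* is the unweighted per-position mean
over its aligned sites, computed only over sites with a defined value at the
position (coverage counts are retained).  Pairwise shape similarity between
proteins is $-\lVert v_a - v_b \rVert_2$ per structural parameter: 0 for
identical profiles, increasingly negative with divergence, so that high
values mean high similarity for every metric in the package.  Positions
missing in any profile are dropped from all profiles for that comparison
rather than imputed.

## Motif alignment and sequence similarity

PBM-style input is reduced to the 8-mers with E-score ≥ 0.45 (the
conventional "bound" cutoff; reverse-complement pairs collapse to one
representative).  Each selected 8-mer is placed on an 8-wide binding-site
frame so that a 5-base window matching the degenerate homeodomain core
NNA(Y/K)N sits at frame positions 3–7, scanning both strands.  Ambiguous
placements are resolved by PFM log-likelihood.  The original procedure
disambiguated against previously published PFMs, which is an external
dependency; by default this package instead uses a self-contained two-pass
scheme — unambiguous k-mers build a provisional PFM, against which variant
choice (NNAYN vs NNAKN, by total log-likelihood) and the remaining
placements are resolved — and `referencePfm` restores the original
behaviour when a reference is available.  This stand-in is deterministic:
remaining ties prefer the strand-canonical orientation (the
lexicographically smaller of the two oriented sequences), then the leftmost
frame placement.  A plus-strand preference would be just as deterministic
but would break strand consistency — a reverse-complemented input list must
align identically, and it does under the canonical rule.

PFMs are column-normalised base counts with per-column effective coverage
(sites need not span the whole frame); DNA sequence similarity between two
proteins is the Pearson correlation of their flattened PFMs.  Protein
similarity is the raw BLOSUM45 sum over MSA columns, skipping columns where
either row is gapped; no length normalisation is applied because the
downstream correlation is scale-invariant, and whether the original
analysis normalised is not stated.  Region-restricted variants score only
the N-terminal-tail or recognition-helix windows.

## Covariation statistics

**Matrix level.**  The Pearson correlation between two similarity matrices
is computed over the strict upper triangle.  Its significance is assessed
two ways: a *t*-approximation p-value, and an empirical shuffle null —
protein identities are randomly reassigned 1000 times and the correlation
recomputed.  Reassigning identities permutes the rows and columns of the
protein similarity matrix by one permutation, so the implementation permutes
the precomputed matrix; a test verifies this equals recomputing from the
shuffled cohort.  The empirical p is $(r+1)/(n+1)$, which cannot be zero.  A
binning control reruns the correlation after sampling an equal number of
pairs from each DNA-similarity bin (edges 0, 0.4, 0.5, …, 0.9, 1), guarding
against distributional artefacts.  The binning procedure is described in
terms of "binding sites" upstream; it is implemented here as subsampling of
pairwise score entries, recorded as an interpretation.

**Position level.**  A protein's profile position is called *narrow* when
its average MGW is ≤ 5.12 Å (inclusive), the average observed over a large
homeodomain binding-site compendium; 4.9–5.2 Å sensitivity reruns are built
in.  The call is made on the per-protein average profile, not per site,
matching the feature-vector construction.  For every protein alignment
column and frame position:

* the **hypergeometric map** tests co-occurrence of basic residues
  ({R, K, H}) with narrow calls: with $N$ proteins, $s$ basic, $m$ narrow
  and overlap $k$, $p = P(K \ge k)$ under the hypergeometric distribution;
  vacuous cells ($s=0$ or $m=0$) record $p=1$ with a flag.  Raw p-values
  are reported (with an optional Benjamini–Hochberg overlay left to the
  caller via `p.adjust`), since the heat-map convention in this literature
  is raw $-\log_{10} p$.
* the **MI map** is the plug-in mutual information (bits) between the full
  residue alphabet (gap included; a binary basic/non-basic recoding is
  optional) and the binary narrow call.  The full alphabet is the default
  because covariation may act through residues that are not themselves
  basic (conformational positioning rather than direct insertion).

Residue-grouped MGW curves (R / K / H / other at a chosen column) are
compared position-wise with the two-sided Wilcoxon rank-sum test (exact for
small groups, normal approximation with tie correction otherwise), flagged
at $p < 5\times10^{-5}$.

## Shape-augmented affinity models

Per protein, per-8-mer E-scores are predicted by multiple linear regression
under 10-fold cross-validation repeated 50 times (fold assignment
re-randomised per repeat; every 8-mer is predicted exactly once per
repeat).  Three variants are compared: sequence one-hot features alone;
sequence plus the four shape parameters of the placed, flank-extended
sites; and sequence plus row-shuffled shape features (shuffle redrawn per
repeat) as an overfitting control, plus single-parameter ablations.  Frame
positions not covered by an 8-mer are filled with a randomly drawn
nucleotide (once per run, not per repeat, so that cross-validation
variation isolates fold assignment) and carry the table-average value of
each shape parameter, as do edge positions whose pentamer is undefined.

Reported $R^2$ is the *squared Pearson correlation between predicted and
observed E-scores*, not the in-sample coefficient of determination — the
two differ under cross-validation, and the squared-correlation convention
is what this analysis tradition reports.  Both mean and median across
repeats are available (it is not stated upstream which aggregation was
used; the mean is the default reading of "average").  Bound/unbound
classification (E-score ≥ 0.45) is summarised by the ROC AUC computed by
the midrank Mann–Whitney method, identical to the trapezoidal area.
Rank-deficient designs (one-hot blocks are collinear with the intercept)
are handled by QR pivoting, which still yields valid least-squares
predictions.

## The synthetic study conditions

The generator exists so that every statistic above can be exercised on data
whose ground truth is known.  Its defaults are the package's fixed study
conditions:

* **Shape table** (`simulateShapeTable`): MGW $= 5.8 - 0.8\,\mathrm{atFrac}
  + U(-0.12, 0.12)$ Å — the B-DNA reference narrowed in proportion to AT
  content, reflecting AT-tract minor-groove narrowing; ProT decreases with
  AT content; Roll ~ N(2°, 1.2°), HelT ~ N(34.5°, 1°) per central step;
  revcomp-consistent by construction.  The closed-form table mean is
  $5.8 - 0.4$ Å.  Real pentamer tables reach further down (A-tracts near
  3 Å); the compressed range is deliberate — it keeps every narrow call in
  the regime where the 5.12 Å threshold is discriminative rather than
  saturated.
* **Cohort** (`simulateCohort`): 60 proteins on a gapless 60-column
  homeodomain-like alignment.  Half carry the planted residue (arginine) at
  tail column 5; non-carriers never carry R/K/H there.  Carrier status
  aligns with a two-subfamily background (12 non-basic marker columns
  followed with probability 0.8 over sparse random substitutions), as in
  real TF families where tail composition tracks subfamily — this is what
  makes the *matrix-level* correlation detectable, while the marker columns
  stay non-basic and only partially informative so they cannot out-score
  the planted column in either map.
* **E-scores**: every strand-collapsed 8-mer receives a latent affinity
  $-d$ (mismatches to the degenerate core NNAYN at its best placement over
  4 offsets × 2 strands), plus, for carriers, $8 \times$ the negative mean
  squared deviation of the site's table MGW at each affected position
  (frame 4 and 5) from that position's target — the core-match average
  minus 0.5 Å — plus N(0, 0.25) noise.  Ranks are mapped onto
  $\mathrm{Beta}(2,2) - 0.5$, a symmetric PBM-like E-score scale on
  $[-0.5, 0.5]$ under which about 240 8-mers per protein clear the 0.45
  threshold (within the 100–1000 sites a real PBM experiment yields).
  E-scores are rank statistics, which is why the generator rank-transforms
  latent affinities rather than emitting them directly.

Because the core is degenerate at the affected positions, the planted shape
preference flows *only* through the pentamer table (sequence and shape
channels stay separable); carriers' selected sites settle ≈ 0.3–0.4 Å below
non-carriers' (the full −0.5 Å is not realised because pentamer
availability thins toward the narrow extreme and the latent noise keeps
selection soft).  The quadratic (target-seeking) shape term and the weight
of 8 were fixed once so that carrier and non-carrier profile levels
straddle the 5.12 Å call threshold — non-carriers sit near 5.35 Å, carriers
near 5.0 Å, and the cohort average lands near the threshold itself, which
is exactly how that threshold was originally derived (a cohort-average
MGW).  A null specification (`mgwShift = 0, shapeEffectWeight = 0`)
removes the planted term entirely; narrow calls then essentially vanish
and both maps stay flat, which the acceptance suite verifies across seeds.

**What the generator does not emulate:** probe-level PBM intensities and
their normalisation; selection dynamics of one-hybrid assays; phylogenetic
non-independence of the proteins; indels in the domain alignment;
dinucleotide or longer-range sequence preferences beyond the planted
channel; and realistic A-tract shape extremes.  Passing on these
conditions therefore demonstrates correctness of the statistics and
end-to-end recoverability of a planted signal — not biological performance
on real PBM data.

## Numerical and design choices

* Coordinates are 1-based and inclusive throughout, in code and reports;
  the binding-site frame is 8 wide with the consensus window at positions
  3–7, so frame numbering matches the conventional 1–8 site numbering.
* Similarity matrices validate their invariants on construction (symmetry;
  unit diagonal and $[-1,1]$ range for PFM correlation; zero diagonal and
  non-positive off-diagonal for shape metrics).
* Placement ties (equal log-likelihood) break to the strand-canonical
  orientation, then the leftmost frame placement — deterministic and
  strand-consistent among exact ties.
* PFM log-likelihoods floor frequencies at $10^{-3}$ so zero columns never
  veto a placement.
* The empirical shuffle p-value uses $(r+1)/(n+1)$; extreme observations
  report $1/1001$ at the default 1000 shuffles, never 0.
* Degenerate inputs error loudly and early: empty site sets, zero-coverage
  PFM columns, uniform PFMs under correlation, single-class ROC input,
  sub-pentamer sequences, ambiguity codes.
* Problem sizes in the test and acceptance runs — 60-protein cohorts,
  1000-shuffle nulls, 20-seed null/ordering sweeps, 1024-8-mer × 10-repeat
  regression fits — were chosen as the smallest sizes at which the planted
  effects and their controls are stable, and are stated in the tests
  themselves.

## Known limitations

* Interdependencies between protein positions are not modelled: a column
  correlated with a truly causal column inherits its covariation signal,
  so the maps identify candidate positions, not causal residues.
* In homeodomains, minor-groove shape at the core is determined by the same
  base pairs read in the major groove, so sequence and shape readout cannot
  be fully separated on real data; the generator's separable channels are
  an idealisation.
* Raw p-values across the position × position grid are reported by
  default (heat-map convention); apply `p.adjust` for formal error-rate
  control.
* The 8-wide frame drops flank context; the affinity module's randomized
  flank extension (with table-average shape) is the only flank handling.
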