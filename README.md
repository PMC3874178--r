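# ShapeCovar

Covariation analysis between the amino-acid sequences of a transcription
factor family and the nucleotide sequence *and 3D shape* of their DNA
binding sites.

Transcription factors achieve specificity through **base readout** (direct
contacts to base-pair chemistry, mostly in the major groove) and **shape
readout** (recognition of sequence-dependent helix geometry — in
particular, a narrow minor groove concentrates negative electrostatic
potential and attracts basic side chains R, K and protonated H).
Homeodomains are the archetype: the recognition helix (residues 47–55)
reads bases in the major groove while the N-terminal tail (residues 1–9)
probes minor-groove shape.  `ShapeCovar` asks, for a cohort of such
proteins with high-throughput binding data: *which protein positions
covary with the sequence of the preferred sites, and which with their
shape?*

## What the package computes

Given an aligned protein cohort, per-protein 8-mer E-score tables
(protein-binding-microarray convention, scores in [−0.5, 0.5], "bound"
at ≥ 0.45) and a pentamer→shape lookup table:

1. **Shape profiling** — per-position MGW, ProT, Roll, HelT predicted by a
   sliding pentamer window (base-pair parameters from the centred
   pentamer; step parameters as the mean of the overlapping central-step
   contributions); per-protein average profiles over all selected sites.
2. **Motif building** — 8-mers with E ≥ 0.45 are aligned (both strands) to
   the degenerate homeodomain core NNA(Y/K)N on an 8-wide frame, ambiguous
   placements resolved by PFM likelihood via a self-contained two-pass
   scheme (or a supplied reference PFM); column-normalised PFMs and their
   pairwise Pearson similarity.
3. **Similarity matrices** — BLOSUM45 protein similarity (full domain or a
   region window: N-terminal tail, recognition helix); DNA sequence
   similarity (PFM correlation); four DNA shape similarities
   (−|Euclidean distance| between shape profiles, 0 = identical).
4. **Covariation** — matrix-level Pearson correlation with a 1000-shuffle
   empirical null and a score-binning control; position-level maps of the
   cumulative hypergeometric test (basic residue × narrow minor groove,
   narrow = MGW ≤ 5.12 Å) and of mutual information (residue identity ×
   narrow/not-narrow call); residue-grouped MGW curves with Wilcoxon
   rank-sum flags.
5. **Affinity models** — per-protein multiple linear regression of E-scores
   on sequence one-hot features, with and without the four shape
   parameters (plus a shuffled-shape control and per-parameter ablations),
   under 10-fold cross-validation with repeats; R² is the squared Pearson
   correlation between predicted and observed E-scores; ROC AUC at the
   0.45 bound/unbound threshold.
6. **Synthetic cohorts** — a generator that plants a known covariation: a
   chosen residue (default arginine at tail column 5) whose carriers
   prefer binding sites with a narrower minor groove (default −0.5 Å at
   site positions 4–5), used to validate every statistic end to end.

## Worked example

```r
library(ShapeCovar)

## a 60-protein cohort with planted shape covariation
sim <- simulateCohort(covariationSpec(seed = 42))

sites <- lapply(names(sim$cohort@msa), function(id)
  alignToConsensus(selectKmers(sim$escores[, id]), proteinId = id))
profiles <- lapply(sites, averageShapeProfile, table = sim$shapeTable)
profiles[[1]]
#> ShapeProfile 'HD001': 8 positions, 238 sites
#>   MGW:   NA 5.21 5.12 5.02 5.02 5.10 5.18 5.26

protSim <- proteinSimilarity(sim$cohort)          # BLOSUM45 pairwise sums
mgwSim  <- shapeSimilarity(profiles, "MGW")       # -|Euclidean distance|
matrixPCC(protSim, mgwSim)
#> $pcc
#> [1] 0.5993648
#> $p
#> [1] 4.167447e-173
#> $nPairs
#> [1] 1770

nl <- shuffleNull(protSim, mgwSim, nShuffles = 1000, seed = 7)
round(c(observed = nl$observed, null_mean = nl$mean, p = nl$p), 4)
#>  observed null_mean         p
#>    0.5994    0.0001    0.0010

calls <- callNarrowGroove(profiles)               # narrow = MGW <= 5.12 A
covariationMaps(sim$cohort, calls)
#> CovariationMaps: 60 protein columns x 8 DNA positions (narrow MGW <= 5.12 A)
#>   min hypergeometric p = 8.46e-18 at (column 5, position 4)
```

Protein HD001 is a carrier: its 238 selected sites average ~5.0 Å at site
positions 4–5, below the 5.12 Å narrow cutoff, while non-carriers sit near
5.35 Å.  The protein/shape similarity correlation (0.60) towers over its
shuffle null (mean ≈ 0, empirical p = 1/1001), and both covariation maps
peak exactly at the planted cell — protein column 5 (the arginine
position) × site position 4.

`runPipeline(runConfig(...))` runs all stages on files (aligned FASTA,
E-score TSVs, shape-table TSV) or on a simulated cohort, and writes the
similarity matrices, covariation maps, PFMs (MEME minimal format), shape
profiles and a JSON manifest to an output directory.

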