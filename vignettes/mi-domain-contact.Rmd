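---
title: "Mutual-information coevolution scores for domain-domain contact prediction"
author: "micontact"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mutual-information coevolution scores for domain-domain contact prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micontact)
```

## The problem and the model

Residues that are in physical contact across a protein-protein (or
domain-domain) interface tend to mutate in a correlated way: a change in
size, shape or chemistry on one side must be compensated on the other if
the contact is to remain favourable.  Mutual information (MI) between
two columns $J$ and $K$ of a multiple sequence alignment (MSA) is the
canonical measure of such covariation:

$$MI(J;K) = H(J) + H(K) - H(J;K), \qquad
  H(J) = -\sum_j p_j \log_e p_j ,$$

with plug-in (empirical frequency) probabilities, natural logarithms
throughout, and $0 \log 0 := 0$.  `micontact` works on *paired-domain*
MSAs -- alignments of two-domain proteins in which each domain is
treated as one interaction partner -- and computes MI for every
inter-domain column pair, together with the corrected variants:

* **MIp**: $MI - APC$, where the average product correction
  $APC(J;K) = \overline{MI}(J)\,\overline{MI}(K)/\overline{MI}$
  estimates the entropic and phylogenetic background shared by the two
  columns (means over the surviving inter-domain pairs).
* **MIc**: $MI - NCPS$, where the coevolutionary pattern similarity
  $CPS(J;K)$ is the mean product of the two columns' MI profiles
  against third columns $L$, and
  $NCPS = CPS/\sqrt{\overline{CPS}}$.
* **MI3D / MIp3D**: the total correlation
  $H(J)+H(K)+H(L)-H(J,K,L)$ of one column of one domain with a spatial
  *patch* $(K, L)$ of the other domain (reference-structure residues of
  $K$ and $L$ strictly closer than 4.5 Å), with the product-of-means
  correction $APC3D = \overline{MI3D}(J)\,\overline{MI3D}(K)\,
  \overline{MI3D}(L)/\overline{MI3D}$.
* **RA variants**: any of the above computed after mapping the 20 amino
  acids onto seven physiochemical categories (Small; Hydrophobic;
  Negatively charged; Aromatic; Polar; Favoured positive = R, H;
  Disfavoured positive = K), which trades alphabet resolution for
  noise reduction.

Three filtering rules apply everywhere: columns containing any gap are
ineligible; columns with zero entropy are ineligible; and pairs (or
triples) whose raw score is exactly 0 are excluded before any mean,
correction or standardisation is computed.  All surviving scores are
standardised to z-scores over the alignment's own surviving set, using
the sample (n-1) standard deviation, so that scores from different
alignments are comparable.

Residues are scored by the **maximum** standardised score their column
achieves in any surviving pair or triple (mean aggregation is available
but known to perform worse).  Evaluation uses precision-recall curves
over percentile cutoffs, the precision at 20% recall as the headline
number, MCC curves as a complement, subsampling stability (70% of
sequences, repeated), and a binomial test on the top-k predictions for
single test cases.

## A worked example

```{r example}
spec <- synthetic_spec(
  n_sequences = 300, len1 = 12, len2 = 12,
  coupled_pairs = data.frame(col1 = c(2, 7), col2 = c(15, 20),
                             coupling = 0.9),
  conserved_cols = 5, gapped_cols = 10, seed = 7)
msa <- generate_msa(spec)
ann <- generate_annotations(spec, msa)

art <- run_pipeline(run_config(
  msa, annotations = ann$annotations, coordinates = ann$coords,
  variants = c("MI", "MIp", "MIc")))

str(art$summary$variants, max.level = 2)
```

The planted covarying pairs are also the planted contacts, so every
variant reaches precision 1 at 20% recall here; the baseline field is
the contact prevalence a random predictor would achieve.

## Tunable parameters and their defaults

| Parameter | Default | Meaning |
|---|---|---|
| surface threshold | 7 % | relative accessibility (1.4 Å probe, domain alone) above which a residue is "surface" (strict) |
| contact / patch distance | 4.5 Å | strict minimum inter-atomic distance criterion |
| accessibility-change tolerance | 0.5 points | criterion 3 of the contact definition: isolated vs in-complex accessibility must differ by more than this |
| subsample fraction | 0.7 | stability analysis; gated to MSAs with ≥ 200 sequences so subsamples keep ≥ ~125 sequences |
| replicates | 100 | stability analysis |
| percentile grid | 0–100 | P-ROC / MCC cutoffs; the 0th (all-inclusive) point pins precision = prevalence, recall = 1 |
| target recall | 0.2 | headline precision read-out |
| `cps_l_scope` | `"all"` | see below |
| aggregation | `"max"` | residue score over its column's surviving entries |

Domain ranges are 1-based inclusive residue numbers on the ungapped
reference sequence; alignment columns are 1-based (the natural R
convention).

## Design choices where the design was open

**Standard deviation.** Every standardisation ("estimated standard
deviation") uses the sample (n-1) form.  No pseudocounts are applied
anywhere: probabilities are plain empirical frequencies.

**CPS third-column scope.** $CPS(J;K)$ sums $MI(J;L)\,MI(K;L)$ over
third columns $L$.  For an inter-domain pair no choice of $L$ makes both
factors inter-domain, so the default (`cps_l_scope = "all"`) computes
the full MI matrix over all eligible columns of both domains and lets
$L$ range over them (divisor = number of admissible $L$); the
normalising mean of $CPS$ is taken over the surviving *inter-domain*
pairs only.  `cps_l_scope = "opposite"` restricts $L$ to the second
domain's eligible columns.

**Zero-score exclusion order.** Zero-MI pairs are removed *before* the
APC/CPS means and before standardisation; the same rule applies to
MI3D.  Tiny negative raw values from floating point are clamped to 0
and then excluded as zeros (tolerance 1e-12).

**Degenerate standardisation.** A table with fewer than two survivors,
or with zero spread, cannot be z-scored and raises a dedicated error
rather than returning NAs.  A consequence worth knowing: when every
surviving pair shares one common column, MIp is identically 0 and is
reported through that error.

**Subsampling.** `subsample_msa()` draws `floor(fraction * (n-1))` of
the non-reference rows and always retains the reference row, so
structure-derived annotations remain mappable (a 200-row MSA at 0.7
yields 140 rows).  Each stability replicate derives its own seed from
the master seed; results are bit-identical across runs.

**Top-k ties.** Candidates tied at the k-th score are all included
(with a warning, enlarging k); a deterministic truncation by column
index is available.  The binomial model uses the effective k.

**Precision at recall.** The conservative step convention: the
precision at the highest percentile cutoff whose recall still reaches
the target, with no interpolation.

**Annotation inputs.** Relative accessibilities are an input table
(isolated and in-complex, percent), not computed internally; any
SASA tool's output can be supplied in the documented TSV format.
Distances use all atoms present in the coordinate file; alternate
locations resolve to the highest occupancy.  Whether the distance
criterion should look only at *surface* residues of the partner domain
is ambiguous in the field; it is implemented literally as "a residue".

**Non-standard residues.** B, Z, X, `*`, `?` -- and, extending the same
logic, U and O -- become gaps during sanitisation; lowercase is folded
to uppercase first, and `.` gaps are normalised to `-`.

## What the synthetic generator emulates -- and what it does not

`synthetic_spec()` / `generate_msa()` draw background columns
independently and uniformly over a configurable alphabet and plant
covariation as **bijection mixtures**: with probability equal to the
coupling strength, a row's domain-2 symbol is the image of its domain-1
symbol under a fixed random bijection.  This isolates exactly the
statistical signal MI measures.  Planted triples use a **pure
three-body linkage** (the third symbol is a bijective function of the
first two symbols' index sum): every pairwise margin stays independent
while the triple is strongly dependent.  The two-bijection alternative
(K and L both images of J) was rejected because it inflates the
pairwise K-L score, which propagates to *every* triple sharing the
patch and is then cancelled wholesale by APC3D -- under that
construction a planted triple is unrecoverable by MIp3D at any
realistic size.

An optional `shared_ancestry` background mutates all sequences away
from a common ancestral sequence with **per-sequence** substitution
rates drawn from Uniform(0, 2p).  The rate heterogeneity couples all
columns through their shared divergence and produces the
phylogenetic-style background MI that APC and CPS are designed to
remove (the package's tests verify both the excess over a
margin-preserving shuffle control and its suppression by MIp).  A star
phylogeny with iid per-site mutations would *not* work: with mutations
independent across sites, columns remain independent and carry no
excess MI.

`generate_annotations()` places one atom per residue such that exactly
the planted contact pairs are closer than 4.5 Å across the interface
and exactly the planted patch pairs are closer than 4.5 Å within the
domain; surface residues get 30% isolated accessibility (buried 3%),
and planted contacts lose 15 points in the complex.  Surface membership
is sampled at `surface_fraction` (default 0.7, roughly the surface
prevalence of real two-domain proteins), with planted contacts always
surface.

What passing tests on this generator do **not** show: real MSAs have
tree-structured (not exchangeable-row) phylogeny, non-uniform column
compositions, alignment errors and gap structure correlated with
structure, and contact definitions inherited from real geometry.
Recovery rates and precision figures on synthetic data are therefore
statements about the correctness and power of the *scores*, not
performance claims about real proteins.

## Numerical behaviour worth knowing

* **Plug-in bias.** The empirical MI of two independent columns is
  positive in expectation, roughly $(k_J-1)(k_K-1)/(2n)$ nats for
  alphabet sizes $k$ and $n$ sequences.  For triples the bias is far
  larger: with 20 symbols and a few hundred sequences
  $H(J,K,L) \approx \log n$ for *every* triple, so raw MI3D sits
  around $3\bar H - \log n$ regardless of signal, and APC3D -- which
  has the units of a squared score (a product of three means over one
  mean, implemented exactly as defined) -- can dwarf the raw values.
  This is the mechanism behind the known underperformance of the 3D
  variants on real data; the package's triple-recovery tests use a
  4-letter alphabet where the bias is negligible and the planted
  three-body signal dominates.
* **Problem sizes.** The test suite's simulation checks use, e.g.,
  100 generator seeds at 500 sequences x 50 columns for planted-pair
  recovery, 400 seeds for the null binomial goodness-of-fit (80
  candidates, k = 5, where the hypergeometric truth and the binomial
  model are indistinguishable), a 20-step sweep for the zero-entropy
  diagnostic, and 8 subsample replicates for the stability rank-order
  check -- sizes at which each property is comfortably powered.
* **Determinism.** Every source of randomness flows through an explicit
  seed argument; the caller's RNG state is saved and restored.

## Known limitations

* Only two-domain (pairwise) interfaces are modelled; a domain
  interacting with several partners confounds the signal.
* No sequence weighting or phylogenetic downweighting is applied --
  deliberately, as the scores are defined on raw frequencies.
* SASA computation and MSA construction are out of scope; both are
  inputs.
* The consensus/resampling pipelines built around other MI variants
  (e.g. ZNMI) are not reimplemented.
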