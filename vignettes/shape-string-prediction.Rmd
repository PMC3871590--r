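---
title: "Shape-string prediction from NMR chemical shifts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape-string prediction from NMR chemical shifts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shapecrf)
```

## The problem

Backbone conformation of a protein chain can be coarse-grained into a
*shape string*: one letter per residue naming the region of the
Ramachandran plane occupied by its (φ, ψ) torsion pair. Eight letters
are used — A (α-helix), S (β-extended), R (polyproline II), U and V
(bridge regions), K (helix caps / 3₁₀), T (turn), and G (the
positive-φ region essentially reserved for glycine) — plus X for
residues with no structural data. This alphabet is finer than
three-state secondary structure and correspondingly more informative
about local geometry.

Chemical shifts of the six routinely assigned backbone nuclei (HA, H,
N, CA, CB, C) depend strongly on local conformation, so a chain whose
shifts are assigned carries substantial structural signal even before
any structure is solved. `shapecrf` treats shape-string prediction as
supervised sequence labeling: per-residue categorical features derived
from shifts and from sequence similarity are consumed by a linear-chain
conditional random field (CRF) over the eight states.

## Preprocessing: normalization and alphabetization

Raw shifts from different nuclei live on very different ppm scales, and
their typical ranges also differ by amino-acid type. Both effects are
removed by a per-(amino acid, atom) min/max transform: for each of the
20 × 6 = 120 combinations the training corpus supplies a range
$[x_{\min}, x_{\max}]$, and a value $x$ becomes
$x' = (x - x_{\min}) / (x_{\max} - x_{\min})$. Query values outside
the training range are clipped to the boundary first, which doubles as
a cheap guard against referencing errors and outliers. Vacant cells
(unassigned shifts) are tagged rather than imputed.

Normalized values are then discretized into ten equal bins labeled
L, A, D, C, Q, M, V, W, P, G in ascending order; discretization
deliberately absorbs the small shift perturbations caused by pH,
temperature and referencing differences. With the vacancy letter "N"
each of the six shift features takes one of 11 letters. Two
conventions here are the package's own (the source definitions leave
them open): bins are half-open $[k/10, (k+1)/10)$ with the last bin
closed at 1, and the listed letter order maps to ascending bins. At
prediction time an (aa, atom) combination that is absent or degenerate
(a single training observation) emits "N" with a warning rather than
aborting, so sparse corpora remain usable; `fit_scale_table()` flags
such entries.

## Shape assignment and the torsion-region table

`assign_shape()` maps (φ, ψ, amino acid) to a letter using a table of
axis-aligned rectangles matched first-to-last (lower-inclusive,
upper-exclusive, final catch-all row), with glycine-only rows checked
first so that G is reserved for glycine and a non-glycine residue in
the same region receives the underlying base letter. The published
boundaries of the original shape-string assignment are not available,
so the shipped table (`inst/extdata/torsion_regions.tsv`) is a
documented approximation shipped as *data*: tests treat the table
itself as ground truth (coverage, first-match semantics, round-trips),
and users with the authoritative boundaries can drop them in without
touching code.

`align_records()` reconciles shift records with structure-derived
shape strings for the same chain, which routinely disagree in coverage
(disordered tails, crystal-contact breaks). The two amino-acid
sequences are aligned globally with identity scoring and affine gaps
(match +1, mismatch −10, gap open 5, gap extend 1, via
`Biostrings::pairwiseAlignment`); the mismatch-hostile scoring means
only insertions/deletions are tolerated. Chains whose best alignment
still contains a substitution are flagged unalignable rather than
silently trusted — zero substitution tolerance is a deliberate choice,
since a mismatched residue pair usually indicates an entry mix-up
rather than a sequencing variant.

## Profiles: hallmark patterns and the eight boxes

Sequence similarity to structure-annotated chains is the second
evidence channel. At full scale this would be a similarity search
against a structure database; the package's reference hit source is an
exact k-mer matcher (default k = 6) against the training corpus, with
an adapter (`read_external_hits()`) for hits produced by external
search tools. Each matched position contributes the subject residue's
shape letter as one hit; the `top_n` (default 10) subjects with the
most matches are kept.

Query stretches with no primary hit are scanned against a library of
*hallmark patterns*: length 2–4 amino-acid substrings whose corpus
occurrences show a statistically conserved shape letter at one or more
positions. Mining enumerates every substring with support at least
`min_support` (default 100) and tests each position's modal letter
with a one-sided upper-tail binomial test against the corpus
background frequency of that letter; patterns with any position at
`p ≤ max_p` (default 0.01; the original cutoff is unpublished) are
kept. Occurrences with X at a position are excluded from that
position's test, since X is missing data rather than a state. For an
uncovered query match, corpus occurrences of the pattern are ranked by
sequence identity of their ±`flank` (default 5) residue context to the
query's context, and the best `top_n` occurrences each contribute one
count of the conserved letter — all hits are weighted equally, the
simplest defensible reading of an unspecified original weighting.

Per residue the evidence is stored as eight non-negative counts (box
order S, R, U, V, K, A, T, G), converted to fractions of the position
total, and discretized with the same ten-letter alphabet as the shifts
(uniformity being the point; the original discretization scheme for
profiles is unstated). No-evidence positions emit "N" for all eight
boxes.

## The CRF

Each residue thus carries 14 categorical features (6 shift letters + 8
profile letters). `crf_featurize()` emits every base feature at every
offset in a ±`window` context (default ±3, a configurable stand-in for
an unpublished feature template), with a boundary token beyond chain
ends, giving $14(2w+1)$ indicator features per position over a fixed
12-letter id space; one label-bigram family models transitions.
Training maximizes the L2-penalized conditional log-likelihood
(`l2` default 1.0) with L-BFGS (default cap 200 iterations) from a
zero start, making fits deterministic; the objective trace is stored
and plotted by `autoplot()`. Chains are split at X runs — X is absence
of data, not a learnable class — and every position receives one of
the eight letters at prediction time. Decoding uses Viterbi for the
predicted string and forward–backward for per-residue posteriors; both
recursions are compiled and are tested against exhaustive path
enumeration on short sequences, which is feasible because
$8^L \le 262{,}144$ for $L \le 6$.

## Evaluation

S8 is residue-level accuracy over the eight states, per class
$100\,n_i/m_i$ and in total residue-weighted; S3 is the same after the
collapse [S,R,U,V]→S, [A,K]→H, [T,G]→T, and is never below S8 because
the collapse is many-to-one. SOV is the segment-overlap measure: for
overlapping reference/predicted segment pairs in a state the
contribution is $\mathrm{len}(s_1)\,(minov+\delta)/maxov$ with
$\delta = \min(maxov-minov,\; minov,\; \lfloor \mathrm{len}(s_1)/2
\rfloor,\; \lfloor \mathrm{len}(s_2)/2 \rfloor)$ — the 1999 convention
with integer floors, chosen because the source rendering of the
formulas is ambiguous about the variant. X positions split segments
and never enter the normalizer. Uncertainty is reported by target
bootstrap: 80% of chains drawn without replacement, 1000 replicates,
mean and replicate standard deviation quoted as the standard error;
sampling without replacement matches the stated procedure more closely
than a with-replacement bootstrap would, and the distinction is
immaterial at these sizes.

The ablation harness (`ablate_features()`) reruns chain-level k-fold
cross-validation (default 5 folds; folds split at chain level because
residue-level splits would leak sequence context through the window
and transitions) for each of the six leave-one-shift-feature-out
conditions plus the all-six row, optionally adding
shift-only/profile-only/combined rows.

## The synthetic generator

`generate_corpus()` emulates the joint structure the predictor
assumes, not protein physics. Shape strings follow a first-order
Markov chain with self-transition bias 0.82 (mean segment length about
5–6 residues, the scale of real secondary-structure runs) and a
stationary distribution of A 40%, S 20%, R 12% and 5.6% for each of
U, V, K, T, G — the qualitative imbalance of real shape-string corpora
(helix dominant, bridge and glycine states rare), which is what makes
the eight-class problem hard. Amino acids are uniform except that G
states force glycine. Shifts are Gaussian around a per-(aa, atom) base
mean (realistic ppm centers and widths per atom, with a deterministic
per-amino-acid spread so all 120 ranges differ), plus a shape-state
offset: state codes are eight ±1 sign patterns over the six atoms with
minimum pairwise Hamming distance 3, scaled by the separation
parameter `s` in units of each atom's SD. `s = 2` (the default) gives
a well-separated but noisy problem; `s = 0` is an exact null in which
shifts are independent of shape. A Student-t option (df 3) stresses
the clipping path. Torsions are drawn uniformly inside the sampled
letter's region (area-weighted across rectangles, with rejection to
respect first-match and glycine-override semantics), so
`assign_shape()` reproduces the generated labels exactly — a
round-trip the tests rely on.

What passing tests on such corpora do show: the pipeline's plumbing,
estimators and decoder are correct, and the CRF recovers structure
when the assumed signal exists (held-out S8 ≥ 90% at `s = 2` with 10%
vacancies, versus collapse to the majority-class rate on the null).
What they do not show: performance on real BMRB/PDB data, where shift
distributions are non-Gaussian and overlapping, missingness is
systematic rather than independent, and sequence similarity carries
real evolutionary signal; the absolute accuracies reported here
therefore characterize the generator, not proteins.

## Numerical and design choices

* Problem sizes: the test suite and the acceptance script train on 200
  chains of 50–150 residues (about 20,000 positions) and hold out 50
  chains — large enough for stable scores, small enough to run
  routinely on one CPU; smoke tests use 8–20 chains.
* Optimization: zero initialization and a fixed iteration cap make
  training bit-reproducible; identical seeds yield identical model
  files.
* Ties and boundaries: bin boundaries are lower-inclusive; region rows
  match first-to-last; the modal letter in mining breaks ties by box
  order. Degenerate scale entries and all-vacant rows degrade to "N"
  features rather than errors.
* Serialization is plain text throughout (TSV tables, JSON models) so
  trained artifacts diff and version cleanly.

## Limitations

* The torsion-region table is an approximation; swap in authoritative
  boundaries where available.
* The exact k-mer hit source is a desk-scale stand-in for a real
  similarity search; on low-identity queries profiles are mostly
  empty and prediction rests on the shift features.
* No chemical-shift re-referencing or outlier handling beyond range
  clipping is attempted; badly referenced inputs will degrade quietly.
* The CRF is strictly linear-chain with categorical features; no
  semi-Markov segments, continuous emissions, or neural encoders.
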