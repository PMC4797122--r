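---
title: "SMILES similarity kernels and WNN-GIP: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SMILES similarity kernels and WNN-GIP: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smilesim)
```

This vignette explains what `smilesim` computes, why its defaults are what
they are, and where genuine design choices were made. The package has three
layers: string preprocessing and similarity kernels over SMILES, a
drug–target interaction predictor consuming kernel matrices, and an
evaluation/synthetic-data layer that makes the whole pipeline testable
without any external download.

## Preprocessing: what the kernels actually see

SMILES strings are compared character by character, so two distortions must
be removed first.

**Two-character atoms.** `Cl` and `Br` (and, by default, `Si` and `Se`) are
collapsed to single replacement characters (`L`, `R`, `A`, `Z`) so that a
chlorine atom contributes one symbol, not a spurious `C` plus an `l`. Only
the two halogens are universally agreed on; the rest of the table is this
package's choice, and `normalize_atoms()` accepts any user table. The
replacement characters were picked because they are not legal SMILES
organic-subset symbols, and the function refuses tables that collide with
real symbols. Whitespace is stripped before anything else — printed SMILES
sometimes carry typesetting spaces that are not tokens.

**Ring numbers.** Ring-closure digits are arbitrary labels: `C1CCC1` and
`C4CCC4` denote the same ring. The LINGO-family kernels therefore operate on
strings whose digits outside `[...]` atom blocks have been set to `0`
(`zero_ring_numbers()`). Digits inside brackets are isotopes, charges or
hydrogen counts and are left alone; `%nn` two-digit closures become `%00`.
Both operations are idempotent, and ring zeroing preserves length.

Canonicalization is deliberately **not** performed. The kernels assume the
input SMILES are already canonical and unique (benchmark sets typically
are); feeding the same molecule in two different valid spellings will
produce a similarity below 1. This keeps the package free of a chemistry
toolkit dependency and makes the preprocessing fully transparent.

## The kernel family

Three groups of similarity functions are provided, all symmetric and (except
the raw substring inner product) bounded in [0, 1].

**Whole-string kernels.** Edit similarity normalizes Levenshtein distance by
the longer string. NLCS squares the longest-common-subsequence length over
the length product, which rewards pairs whose common subsequence covers both
strings. The combined CLCS adds two consecutive variants: NMCLCS₁ (longest
prefix of the shorter string found contiguously in the longer) and NMCLCSₙ
(longest common contiguous substring), weighted `0.33/0.33/0.33`. The
weights are the *literal* value 0.33, not 1/3 — identical strings score
0.99 — because that is how the combination is conventionally specified, and
the components enter unrounded. For equal-length strings NMCLCS₁ takes the
better of the two prefix directions so symmetry is preserved (the original
formulation speaks only of "the shorter string" and leaves this case open).
The substring kernel is the inner product of all-substring (length ≥ 2)
frequency profiles; its raw value is the reference behavior, while the
cosine-normalized variant is what `pairwise_similarity()` uses by default
inside matrices, since raw inner products grow with molecule size and are
not comparable across compounds.

**Fingerprint kernels (SMIfp).** A SMILES string is mapped to a vector of
symbol counts — 34 symbols classically, 38 in the extended variant that
drops `%` and adds `@`, `@@`, `.`, `\` and `/` (chirality and directional
bonds, which turn out to be frequent in drug-like SMILES). The historical
34-symbol list is not reprinted in any source shipped here, so the built-in
`smifp34` alphabet is a synthetic reconstruction (also shipped as
`inst/extdata/smifp34_synthetic.txt` and clearly labelled as such); the 38D
set is derived from it exactly as published, and any alphabet can be
supplied as a plain text file. Tokenization is greedy, so `@@` never counts
as two `@`. Fingerprints are computed on the *raw* SMILES, before atom
collapsing, so the stereo tokens survive. Distances are City Block (CBD)
and count Tanimoto; because the downstream kernel machinery needs
similarities in [0, 1], CBD is exposed as `1/(1+CBD)` — a package choice,
monotone in the distance, so AUC-style rank metrics are unaffected by the
specific transform.

**LINGO and corpus-weighted kernels.** A LINGO is a q-character substring of
the ring-zeroed SMILES; a string of length n has n−(q−1) of them, counted
with multiplicity. `lingosim` is the per-LINGO count Tanimoto averaged over
the union of the pair's unique LINGOs. The TF and TF-IDF kernels borrow the
vector-space model of information retrieval: each compound is a "document",
its LINGOs are "terms", TF weight is sublinear (`1 + log10(count)`), IDF is
`log10(N/df)` with no smoothing, and similarity is the cosine of the
weighted vectors. Low-IDF LINGOs behave like stop words — carbonyls and
aromatic-ring runs appear in most drug-like compounds — and
`lingo_report()` ranks them the way a corpus linguist would.

Default `q = 4`, with `q` ∈ {3, 4, 5} worth sweeping per data set; the
kernel matrices expose `q` directly. The TF/TF-IDF vocabulary defaults to
the *full* compound set of a data set (matching how such corpus statistics
are usually quoted), with `vocab_corpus` available to restrict weighting to
a training fold; out-of-vocabulary LINGOs of unseen compounds are dropped
and counted. Term order is first-appearance over the corpus, making vectors
and reports byte-reproducible for a fixed corpus order.

One worked-example subtlety: reference arithmetic for the TF-IDF cosine of
the toy pair uses weight vectors already rounded to one or two decimals
(0.61/8.2 ≈ 0.07), whereas full-precision IDFs give ≈ 0.084. The package
always computes at full precision; the test suite checks both paths
separately so the distinction stays visible.

## From similarities to kernels

`pairwise_similarity()` computes the upper triangle once and mirrors it, so
matrices are bit-exactly symmetric; the diagonal is computed, not assumed
(degenerate compounds, e.g. SMILES shorter than q, really do score 0
against themselves and trigger a warning). Similarity matrices are not
automatically positive semidefinite, which regularized least squares
requires. `make_kernel()` symmetrizes and, if the smallest eigenvalue is
below ε = 1e-9, shifts the whole diagonal up by the deficit. The minimal
diagonal shift was chosen over eigenvalue clipping because it leaves every
off-diagonal similarity untouched — the quantity the kernels were designed
to produce. Composite kernels (`composite_kernel()`) mix a precomputed 2D
matrix with a SMILES kernel as `λ·S₂D + (1−λ)·S_f`, default λ = 0.5; mixing
happens on raw similarities *before* PSD repair, since both inputs are
similarities and the repair is a property of the final kernel (the ordering
is not dictated by the method's description, so it is fixed and documented
here).

## The WNN-GIP predictor

The interaction network is a binary drugs × targets adjacency; its rows and
columns are interaction profiles. The Gaussian interaction profile kernel
is `exp(−γ‖yᵢ−yⱼ‖²)` with `γ = gamma_scale / mean(‖y‖²)`, the mean taken
over nonzero profiles so that empty rows (hidden test drugs) cannot
collapse the bandwidth. For a *new* drug, whose profile is unknown, the
weighted-nearest-neighbor step builds one: training drugs are ranked by
chemical similarity and their profiles summed with geometric weights
`decay^(rank−1)`, clipped to [0, 1]. Ties in similarity are broken by the
training drugs' identifiers (stable under reordering of the inputs), or by
training order when no identifiers exist.

Drug and target kernels are then blended with the GIP kernels
(`α·K_chem + (1−α)·K_GIP`), PSD-repaired, and passed to Kronecker RLS:
`scores = K (K + σI)⁻¹ vec(Y)` with `K = K_target ⊗ K_drug`. The solver
uses the eigendecomposition identity — with `K_drug = UΛUᵀ` and
`K_target = VMVᵀ`, the smoother factors into
`U [ (ΛᵢMⱼ/(ΛᵢMⱼ+σ)) ∘ (UᵀYV) ] Vᵀ` — which costs O(n³+m³) instead of
O(n³m³) and never materializes the Kronecker product. The brute-force
Kronecker solve exists only as a test oracle, and the two agree to 1e-8 on
random instances. Non-PSD inputs are refused with a pointer to
`make_kernel()` rather than silently regularized.

Hyperparameter defaults — `gamma_scale = 1`, `alpha = 0.5`, `sigma = 1`,
`wnn_decay = 0.7` — are the conventional values for this predictor family;
no setting here is asserted to be what any particular published comparison
used, and all are exposed in `gip_config()` and echoed into run metadata.

## Evaluation

Cross-validation is performed over *drugs*: each fold's drugs are treated
as new compounds (adjacency rows hidden, profiles imputed), and all their
hidden drug-target pairs are pooled per fold. Defaults are 5 folds × 5
repeats = 25 fold scores; `glance()` reports standard deviations both over
the 25 folds and over the 5 repeat means, because summary tables in the
literature rarely say which convention they use. Fold partitions are drawn
from a seed-derived stream (`seed + repeat`), restore the caller's RNG
state, and are identical across kernels evaluated with the same seed — the
prerequisite for the paired t-test. AUC-ROC is the Mann-Whitney statistic
computed from mid-ranks (exact under ties). AUC-PR is step-interpolated
average precision; linear PR interpolation is optimistic and was ruled out,
and the choice is recorded here because either convention appears in
practice. `paired_ttest()` is a two-sided paired t-test on per-fold
differences; the zero-variance degenerate case is reported as significant
with a warning rather than erroring mid-pipeline.

## The synthetic benchmark

`generate_dti_benchmark()` plants recoverable structure: drugs belong to
clusters, each cluster has a private random motif (over `C/c/N/O`) spliced
into every member's SMILES between legal grammar fragments (balanced
branches, paired ring digits, optional stereo tokens to exercise the 38D
alphabet), and drug-target edges are drawn with probability `p_within`
(default 0.35) inside matching clusters versus `p_background` (0.05)
elsewhere. Target similarity is 0.9 within / 0.2 across clusters plus small
symmetric noise. Defaults are 60 drugs, 30 targets, 3 clusters — large
enough that repeated CV is stable, small enough that the whole pipeline
runs in well under a second. The within/background probabilities were
chosen once as values giving a realistic sparse network (~15 % density)
with strong community contrast, and motif length 6 guarantees three planted
4-grams per cluster.

What passing tests on this generator do and do not show: they demonstrate
that the kernels detect shared substrings, that the predictor converts
chemical similarity into interaction ranking (planted-signal AUC-ROC well
above 0.5), and that every contract (symmetry, determinism, fold
structure) holds. They do *not* show chemical realism — the grammar is
deliberately tiny, molecules are not valid chemistry, and absolute AUC
values on real benchmark sets depend on external data (2D similarity
matrices, Smith-Waterman target similarities) and on predictor
hyperparameters this package does not fix. `scripts/benchmark_protocol.R`
documents how to run the identical protocol when such files are supplied.

## Numerical choices and degenerate inputs

* Printed reference decimals for the worked toy pair are truncated rather
  than rounded (e.g. 1/77 appearing as 0.012); the acceptance script
  reports those quantities truncated to the printed precision for
  comparability, while the package itself always returns full precision.
* Empty strings: edit similarity of two empty strings is 1 (identity
  convention); the LCS family returns 0 with a warning; profiles shorter
  than `q` are empty, and empty-vs-empty LINGO profiles score 0 with a
  warning rather than NaN.
* Zero-norm weight vectors (possible under TF-IDF when every term has
  IDF 0, e.g. a single-document corpus) give cosine 0 with a warning.
* The substring profile is O(n²) in string length; a 2000-character cap
  refuses pathological inputs before memory does.
* `kron_rls` with σ → 0 and full-rank kernels reproduces the training
  labels — useful as a sanity limit, tested explicitly.

## Known limitations

* No canonicalization or SMILES validity checking beyond bracket balance.
* The 34-symbol fingerprint alphabet is a labelled reconstruction, not the
  historical list; supply your own file for strict comparability.
* New-*target* imputation is not implemented (the WNN step applies to
  drugs only), and the adjacency is strictly binary — affinity-weighted
  networks are out of scope.
* The TF/TF-IDF vocabulary policy during cross-validation (full corpus vs
  training folds) is a genuine degree of freedom; the default is the full
  corpus, and `vocab_corpus` exists to study the stricter choice.
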