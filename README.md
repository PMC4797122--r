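# smilesim

Compound similarity from SMILES strings, and drug–target interaction
prediction built on top of it.

Most drug–target interaction (DTI) predictors consume a compound–compound
similarity matrix computed by 2D graph matching (e.g. SIMCOMP), which is
accurate but slow. A molecule's SMILES string is a 1D view of the same
structure, and string similarity over SMILES is orders of magnitude cheaper.
`smilesim` implements a family of SMILES string kernels — including
information-retrieval-style TF and TF-IDF cosine kernels over LINGO q-grams —
and wires them into a Weighted Nearest Neighbor / Gaussian Interaction
Profile (WNN-GIP) predictor with Kronecker regularized least squares, so the
whole "kernel → predictor → repeated cross-validation" comparison can be run
from R or the shell. It is aimed at cheminformaticians comparing ligand
similarity functions and at anyone who needs a fast drug kernel for a DTI
model.

## The similarity functions

All kernels operate on preprocessed SMILES: two-character atoms (`Cl`,
`Br`, ...) are collapsed to single characters, and the LINGO-family kernels
additionally set ring-closure digits to `0`.

| Kernel | Definition |
| --- | --- |
| `edit` | 1 − Levenshtein(S₁,S₂) / max(\|S₁\|,\|S₂\|) |
| `nlcs` | \|LCS\|² / (\|S₁\|·\|S₂\|), LCS = longest common subsequence |
| `clcs` | w₁·NLCS + w₂·NMCLCS₁ + w₃·NMCLCSₙ (consecutive-LCS variants, weights 0.33) |
| `substring` | ⟨θ(S₁), θ(S₂)⟩ over all substring frequencies of length ≥ 2 |
| `smifp_cbd`, `smifp_tanimoto` | 34D/38D symbol-count fingerprints compared by City Block distance (as 1/(1+CBD)) or count Tanimoto |
| `lingosim` | mean per-LINGO count Tanimoto, 1/m · Σᵢ (1 − \|N₁ᵢ−N₂ᵢ\|/(N₁ᵢ+N₂ᵢ)) over the m unique q-grams of the pair |
| `tf`, `tfidf` | cosine of corpus-weighted LINGO vectors, weights 1+log₁₀(tf) and (1+log₁₀ tf)·log₁₀(N/df) |

The predictor combines a drug kernel and a target kernel with Gaussian
interaction-profile kernels (K(i,j) = exp(−γ‖yᵢ−yⱼ‖²) on adjacency rows or
columns), imputes profiles for new drugs by a geometrically decaying
weighted-nearest-neighbor sum, and solves the pair-space regularized least
squares through per-kernel eigendecompositions instead of the n·m-sized
Kronecker system.

## Worked example

```r
library(smilesim)

corp <- read_compound_list(system.file("extdata", "example_compounds.tsv",
                                       package = "smilesim"))
S <- pairwise_similarity(corp, "lingosim", q = 4)
round(unclass(S), 3)
#>       SMI1  SMI2  ASA  CAF ETH
#> SMI1 1.000 0.222 0.00 0.00   0
#> SMI2 0.222 1.000 0.00 0.00   0
#> ASA  0.000 0.000 1.00 0.03   0
#> CAF  0.000 0.000 0.03 1.00   0
#> ETH  0.000 0.000 0.00 0.00   0
```

`SMI1`/`SMI2` are the classic toy pair `OC(O)=O` and `CCCCC(O)=C4`: after
ring-digit zeroing they share two of their nine unique 4-character LINGOs,
giving 2/9 ≈ 0.222. Aspirin and caffeine share almost nothing at q = 4
(0.03), and ethanol's three-character SMILES is shorter than a LINGO, so its
profile is empty and it scores 0 against everything (including itself — a
warning flags this degenerate case).

The same corpus can be summarized IDF-wise, mirroring a stop-word analysis
(`(=O)`-style carbonyl LINGOs are the corpus' most ubiquitous terms):

```r
lingo_report(corp, top_k = 3)
#>   lingo doc_freq   idf
#> 1  (=O)        2 0.398
#> 2  (O)=        2 0.398
#> 3  C(O)        2 0.398
```

End-to-end on a synthetic planted-cluster benchmark (60 drugs, 30 targets,
3 communities; every drug carries its community's SMILES motif):

```r
bench <- generate_dti_benchmark(seed = 1)
K <- pairwise_similarity(bench$corpus, "lingosim")
cv <- cross_validate(bench$network, K, bench$target_sim, seed = 1)
glance(cv)[, 1:6]
#>   method   n_folds mean_auc_roc sd_auc_roc mean_auc_pr sd_auc_pr
#> 1 lingosim      25        0.761     0.0399       0.381    0.0498
```

A mean AUC-ROC of 0.76 over 5×5-fold CV says the LINGO kernel recovers the
planted drug-community signal well above chance (0.5) when each fold's
drugs are treated as brand-new compounds. `tidy(cv)` returns the 25
per-fold rows, `autoplot(cv)` draws them, and `paired_ttest()` compares two
kernels evaluated under the same seed.

A thin CLI wrapping the same functions ships in `inst/scripts/smilesim`
(subcommands `similarity`, `predict`, `evaluate`, `lingo-report`, `synth`).

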