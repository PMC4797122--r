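#!/usr/bin/env Rscript
# Optional: run the full repeated-CV comparison protocol against externally
# supplied benchmark files (e.g. the public drug-target benchmark sets for
# enzymes, GPCRs, ion channels and nuclear receptors, with their normalized
# Smith-Waterman target similarities and a SIMCOMP compound matrix).
# Absolute results depend on those inputs and on predictor hyperparameters
# that are not shipped here; nothing in the test suite depends on this
# script.
#
# usage: Rscript scripts/benchmark_protocol.R \
#          --compounds compounds.tsv --adjacency adjacency.tsv \
#          --target-sim target_sim.tsv [--simcomp simcomp.tsv] \
#          [--kernels lingosim,tfidf,...] [--seed 1] [--out report.tsv]

suppressPackageStartupMessages(library(smilesim))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) && i < length(args)) args[i + 1L] else default
}

kernels <- strsplit(get_arg("--kernels",
                            "edit,nlcs,clcs,substring,smifp_cbd,smifp_tanimoto,lingosim,tf,tfidf"),
                    ",")[[1]]

cfg <- list(
  compounds = get_arg("--compounds"),
  adjacency = get_arg("--adjacency"),
  target_sim = get_arg("--target-sim"),
  kernel = kernels,
  composite = get_arg("--simcomp"),
  n_folds = 5L, n_repeats = 5L,
  seed = as.integer(get_arg("--seed", "1")),
  out = get_arg("--out", "benchmark_report.tsv")
)
cfg <- cfg[!vapply(cfg, is.null, TRUE)]

res <- run_evaluate(cfg)
print(as.data.frame(res$report))
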