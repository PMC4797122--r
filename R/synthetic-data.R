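#' Specification for a synthetic drug-target benchmark
#'
#' Describes a planted-cluster world: drugs fall into `n_clusters`
#' communities, each with a private SMILES motif spliced into every member
#' (so SMILES kernels can see the community), and drug-target edges are
#' drawn with a high probability inside matching communities and a low
#' background probability elsewhere (so there is recoverable interaction
#' signal). Everything is deterministic under `seed`.
#'
#' @param n_drugs,n_targets Entity counts (defaults 60 and 30).
#' @param n_clusters Planted community count (default 3).
#' @param p_within Within-cluster interaction probability (default 0.35).
#' @param p_background Background interaction probability (default 0.05).
#' @param motif_len Length of the cluster-specific SMILES motif (default 6).
#' @param n_fragments Range of random fragments per drug (default 4:8).
#' @param stereo Include chirality/directional-bond fragments so the 38D
#'   fingerprint symbols are exercised (default `FALSE`).
#' @param seed Integer seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_drugs = 60L, n_targets = 30L, n_clusters = 3L,
                           p_within = 0.35, p_background = 0.05,
                           motif_len = 6L, n_fragments = 4:8,
                           stereo = FALSE, seed = 1L) {
  stopifnot(p_background >= 0, p_background < p_within, p_within <= 1,
            n_clusters <= min(n_drugs, n_targets), motif_len >= 1)
  structure(list(n_drugs = n_drugs, n_targets = n_targets,
                 n_clusters = n_clusters, p_within = p_within,
                 p_background = p_background, motif_len = motif_len,
                 n_fragments = n_fragments, stereo = stereo, seed = seed),
            class = "synthetic_spec")
}

# small legal-SMILES fragment grammar: branches balanced, ring digits
# paired inside each fragment
.plain_fragments <- c("C", "c", "N", "O", "CC", "CO", "CN", "C(C)", "C(O)",
                      "C(=O)", "C#N", "CCO", "c(N)c", "C1CC1", "c1ccc1",
                      "N(C)C", "OC(C)")
.stereo_fragments <- c("[C@@H](O)", "[C@H](N)", "C(/O)", "C(\\N)", "C.C")

#' Generate a SMILES corpus with planted cluster motifs
#'
#' Each drug's SMILES is a concatenation of random grammar fragments with
#' its cluster's motif (a random string over C/c/N/O of length `motif_len`)
#' spliced in at a fragment boundary, so compounds of a cluster share a
#' contiguous substring that every SMILES kernel can detect.
#'
#' @param spec A [synthetic_spec()].
#' @return Prepared compound tibble (see [prepare_compounds()]) with an
#'   extra `cluster` column.
#' @export
generate_smiles_corpus <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  frags <- c(.plain_fragments, if (spec$stereo) .stereo_fragments)
  .with_local_seed(spec$seed, {
    motifs <- vapply(seq_len(spec$n_clusters), function(k) {
      paste(sample(c("C", "c", "N", "O"), spec$motif_len, replace = TRUE),
            collapse = "")
    }, character(1))
    cluster <- rep(seq_len(spec$n_clusters), length.out = spec$n_drugs)
    smiles <- vapply(seq_len(spec$n_drugs), function(i) {
      k <- sample(spec$n_fragments, 1L)
      parts <- sample(frags, k, replace = TRUE)
      at <- sample(0:k, 1L)
      paste(append(parts, motifs[cluster[i]], after = at), collapse = "")
    }, character(1))
    corpus <- prepare_compounds(tibble::tibble(
      id = sprintf("d%03d", seq_len(spec$n_drugs)), smiles = smiles))
    corpus$cluster <- cluster
    attr(corpus, "motifs") <- motifs
    corpus
  })
}

#' Generate a planted-cluster interaction network and target similarities
#'
#' Targets are assigned to clusters round-robin; an edge between a drug and
#' a target is drawn with probability `p_within` when their clusters match
#' and `p_background` otherwise. The target similarity matrix is high
#' (0.9) within clusters, low (0.2) across, with small seeded symmetric
#' noise, clipped to `[0, 1]` with unit diagonal.
#'
#' @param spec A [synthetic_spec()].
#' @param clusters Integer cluster assignment of the drugs, as produced by
#'   [generate_smiles_corpus()].
#' @return List with `network` (an `interaction_network`), `target_sim`
#'   (a `similarity_matrix`), and `target_cluster`.
#' @export
generate_network <- function(spec, clusters) {
  stopifnot(inherits(spec, "synthetic_spec"),
            length(clusters) == spec$n_drugs)
  .with_local_seed(spec$seed + 104729L, {  # decoupled stream from the corpus
    target_cluster <- rep(seq_len(spec$n_clusters), length.out = spec$n_targets)
    same <- outer(clusters, target_cluster, "==")
    p <- ifelse(same, spec$p_within, spec$p_background)
    A <- matrix(rbinom(length(p), 1L, p), nrow = spec$n_drugs,
                dimnames = list(sprintf("d%03d", seq_len(spec$n_drugs)),
                                sprintf("t%03d", seq_len(spec$n_targets))))
    same_t <- outer(target_cluster, target_cluster, "==")
    S <- ifelse(same_t, 0.9, 0.2)
    noise <- matrix(runif(spec$n_targets^2, -0.05, 0.05), spec$n_targets)
    S <- S + (noise + t(noise)) / 2
    S <- pmin(pmax(S, 0), 1)
    diag(S) <- 1
    rownames(S) <- colnames(S) <- sprintf("t%03d", seq_len(spec$n_targets))
    list(network = interaction_network(A),
         target_sim = similarity_matrix(S, method = "synthetic_target_sim"),
         target_cluster = target_cluster)
  })
}

#' Generate a complete synthetic benchmark bundle
#'
#' Convenience wrapper running [generate_smiles_corpus()] and
#' [generate_network()] under one spec.
#'
#' @inheritParams synthetic_spec
#' @return List with `corpus`, `network`, `target_sim`, `target_cluster`,
#'   and the `spec`.
#' @export
#' @examples
#' bench <- generate_dti_benchmark(n_drugs = 15, n_targets = 8, seed = 7)
#' bench$network
generate_dti_benchmark <- function(n_drugs = 60L, n_targets = 30L,
                                   n_clusters = 3L, p_within = 0.35,
                                   p_background = 0.05, motif_len = 6L,
                                   n_fragments = 4:8, stereo = FALSE,
                                   seed = 1L) {
  spec <- synthetic_spec(n_drugs, n_targets, n_clusters, p_within,
                         p_background, motif_len, n_fragments, stereo, seed)
  corpus <- generate_smiles_corpus(spec)
  net <- generate_network(spec, corpus$cluster)
  c(list(corpus = corpus, spec = spec), net)
}
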