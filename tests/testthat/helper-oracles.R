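# Independent oracles: deliberately naive implementations used only to
# check the package's optimized paths on small instances.

# recursive longest-common-subsequence length (exponential; strings <= 8)
lcs_brute <- function(a, b) {
  if (nchar(a) == 0L || nchar(b) == 0L) return(0L)
  a1 <- substr(a, 1L, 1L); b1 <- substr(b, 1L, 1L)
  ar <- substr(a, 2L, nchar(a)); br <- substr(b, 2L, nchar(b))
  if (a1 == b1) return(1L + lcs_brute(ar, br))
  max(lcs_brute(a, br), lcs_brute(ar, b))
}

# pair-counting AUC-ROC: ties worth one half
auc_brute <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(p, n) (p > n) + 0.5 * (p == n))
  mean(cmp)
}

# Kronecker RLS materializing the full pair-space kernel
kron_rls_brute <- function(K_drug, K_target, Y, sigma) {
  Kd <- unclass(as.matrix(K_drug)); Kt <- unclass(as.matrix(K_target))
  K <- kronecker(Kt, Kd)                      # acts on vec(Y), drugs fastest
  s <- K %*% solve(K + sigma * diag(nrow(K)), as.vector(Y))
  matrix(s, nrow = nrow(Y), dimnames = dimnames(Y))
}

# random SMILES-like strings over a bracket-free alphabet (safe for every
# kernel and for zero_ring_numbers)
random_string <- function(len, alphabet = c("C", "c", "N", "O", "S",
                                            "=", "#", "(", ")", "1", "2")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

sample_corpus <- function(n, min_len = 6L, max_len = 20L) {
  prepare_compounds(data.frame(
    id = sprintf("c%02d", seq_len(n)),
    smiles = vapply(seq_len(n),
                    function(i) random_string(sample(min_len:max_len, 1L)),
                    character(1))
  ))
}
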