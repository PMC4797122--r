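test_that("GIP kernel has unit diagonal and the hand-computed off-diagonal", {
  # orthogonal unit profiles: mean squared norm 1 so gamma = gamma_scale
  P <- rbind(a = c(1, 0), b = c(0, 1))
  K <- gip_kernel(P, gamma_scale = 1)
  expect_equal(K["a", "b"], exp(-2))
  expect_equal(unname(diag(unclass(K))), c(1, 1))
  # identical profiles are maximally similar
  K2 <- gip_kernel(rbind(a = c(1, 1, 0), b = c(1, 1, 0)))
  expect_equal(K2["a", "b"], 1)
  # symmetry on random profile sets
  set.seed(53)
  P3 <- matrix(rbinom(40, 1, 0.4), 8)
  K3 <- unclass(gip_kernel(P3))
  expect_identical(K3, t(K3))
  expect_true(all(K3 >= 0 & K3 <= 1))
  # all-zero rows: bandwidth comes from the nonzero rows only
  P4 <- rbind(c(0, 0), c(1, 1))
  expect_equal(attr(gip_kernel(P4), "params")$gamma, 1 / 2)
  expect_error(gip_kernel(matrix(0, 2, 2)), "bandwidth undefined")
})

test_that("WNN imputation decays geometrically down the similarity ranking", {
  A <- rbind(c(1, 0), c(0, 1))
  expect_equal(wnn_impute(c(0.9, 0.1), A, decay = 0.5), c(1, 0.5))
  # a single training drug contributes its profile exactly
  expect_equal(wnn_impute(0.3, matrix(c(1, 0, 1), 1), decay = 0.7),
               c(1, 0, 1))
  # decay 1 with equal profiles sums then clips to [0, 1]
  expect_equal(wnn_impute(c(0.5, 0.5), rbind(c(1, 0), c(1, 0)), decay = 1),
               c(1, 0))
  # ties broken by training order: first row gets the full weight
  expect_equal(wnn_impute(c(0.5, 0.5), A, decay = 0.25), c(1, 0.25))
  expect_error(wnn_impute(numeric(0), matrix(0, 0, 2)), "empty training")
})

test_that("kernel combination respects its mixing weight", {
  Ka <- similarity_matrix(diag(2), c("a", "b"))
  Kb <- similarity_matrix(matrix(c(1, 0.6, 0.6, 1), 2), c("a", "b"))
  expect_equal(unclass(combine_kernels(Ka, Kb, 1)), unclass(Ka),
               ignore_attr = TRUE)
  expect_equal(unclass(combine_kernels(Ka, Kb, 0)), unclass(Kb),
               ignore_attr = TRUE)
  half <- combine_kernels(Ka, Kb, 0.5)
  expect_equal(unname(diag(unclass(half))), c(1, 1))
  expect_equal(half["a", "b"], 0.3)
  Kc <- similarity_matrix(diag(2), c("a", "x"))
  expect_error(combine_kernels(Ka, Kc), "label mismatch")
})

test_that("eigendecomposition RLS equals the explicit Kronecker solve", {
  set.seed(59)
  for (i in 1:8) {
    nd <- sample(2:5, 1); nt <- sample(2:4, 1)
    Kd <- make_kernel(similarity_matrix(crossprod(matrix(rnorm(nd * nd), nd)) / nd,
                                        paste0("d", 1:nd)))
    Kt <- make_kernel(similarity_matrix(crossprod(matrix(rnorm(nt * nt), nt)) / nt,
                                        paste0("t", 1:nt)))
    Y <- matrix(rbinom(nd * nt, 1, 0.5), nd,
                dimnames = list(paste0("d", 1:nd), paste0("t", 1:nt)))
    sigma <- runif(1, 0.2, 2)
    fast <- kron_rls(Kd, Kt, Y, sigma)
    slow <- kron_rls_brute(Kd, Kt, Y, sigma)
    expect_lt(max(abs(fast - slow)), 1e-8)
  }
})

test_that("RLS has the identity-kernel closed form and the sigma->0 limit", {
  I3 <- similarity_matrix(diag(3), paste0("d", 1:3))
  I2 <- similarity_matrix(diag(2), paste0("t", 1:2))
  Y <- matrix(c(1, 0, 0, 1, 1, 0), 3,
              dimnames = list(paste0("d", 1:3), paste0("t", 1:2)))
  expect_equal(kron_rls(I3, I2, Y, sigma = 1), Y / 2)
  # full-rank kernels reproduce the labels as sigma -> 0+
  set.seed(61)
  Kd <- make_kernel(similarity_matrix(crossprod(matrix(rnorm(9), 3)) + diag(3),
                                      paste0("d", 1:3)))
  expect_equal(kron_rls(Kd, I2, Y, sigma = 1e-10), Y, tolerance = 1e-6)
  # non-PSD kernels are refused with a pointer to make_kernel
  bad <- similarity_matrix(matrix(c(0, 1, 1, 0), 2) - diag(2) * 0.5,
                           paste0("d", 1:2))
  expect_error(kron_rls(bad, I2, Y[1:2, ]), "make_kernel")
})

planted <- generate_dti_benchmark(n_drugs = 24, n_targets = 12,
                                  n_clusters = 3, seed = 67)

test_that("the end-to-end predictor handles empty and unknown test sets", {
  S <- pairwise_similarity(planted$corpus, "lingosim")
  empty <- predict_interactions(planted$network, S, planted$target_sim)
  expect_identical(dim(empty), c(0L, 12L))
  expect_error(
    predict_interactions(planted$network, S, planted$target_sim,
                         test_drugs = "nope"),
    "unknown test drug")
})

test_that("a duplicate-SMILES test drug inherits its twin's targets", {
  corp <- planted$corpus
  corp$smiles[1] <- corp$smiles[2]      # d001 becomes a copy of d002
  corp$norm_smiles[1] <- corp$norm_smiles[2]
  corp$lingo_smiles[1] <- corp$lingo_smiles[2]
  A <- planted$network$adjacency
  A[1, ] <- 0; A[1, which(A[2, ] == 1)] <- 1   # same known targets as d002
  net <- interaction_network(A)
  S <- pairwise_similarity(corp, "lingosim")
  sc <- predict_interactions(net, S, planted$target_sim,
                             test_drugs = "d001")
  truth <- which(A[2, ] == 1)
  top <- order(-sc[1, ])[seq_along(truth)]
  expect_setequal(top, truth)
})

test_that("predictions are invariant under drug permutation", {
  S <- pairwise_similarity(planted$corpus, "lingosim")
  sc1 <- predict_interactions(planted$network, S, planted$target_sim,
                              test_drugs = c("d003", "d010"))
  set.seed(71)
  perm <- sample(nrow(planted$corpus))
  corp_p <- planted$corpus[perm, ]
  net_p <- interaction_network(planted$network$adjacency[perm, ])
  S_p <- pairwise_similarity(corp_p, "lingosim")
  sc2 <- predict_interactions(net_p, S_p, planted$target_sim,
                              test_drugs = c("d003", "d010"))
  expect_equal(sc2[rownames(sc1), ], sc1, tolerance = 1e-9)
})

test_that("with alpha = 1 and identity chemistry, scores depend on Y only", {
  n <- length(planted$network$drug_ids)
  m <- length(planted$network$target_ids)
  Id <- similarity_matrix(diag(n), planted$network$drug_ids)
  It <- similarity_matrix(diag(m), planted$network$target_ids)
  cfg <- gip_config(alpha = 1, wnn_enabled = FALSE)
  sc1 <- predict_interactions(planted$network, Id, It, cfg,
                              test_drugs = "d005")
  # alpha = 1 ignores GIP; identity kernels make the smoother act on Y
  # alone, so a hidden (all-zero) row stays exactly zero
  expect_equal(unname(sc1["d005", ]), rep(0, m))
})
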