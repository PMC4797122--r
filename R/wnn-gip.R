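#' Construct a drug-target interaction network
#'
#' A labeled binary adjacency matrix: rows are drugs, columns targets, a
#' cell is 1 when the pair is known to interact. Rows are drug interaction
#' profiles, columns target interaction profiles.
#'
#' @param adjacency Binary matrix (drugs x targets).
#' @param drug_ids,target_ids Identifier vectors (default: dimnames).
#' @return An `interaction_network`.
#' @export
interaction_network <- function(adjacency, drug_ids = rownames(adjacency),
                                target_ids = colnames(adjacency)) {
  adjacency <- as.matrix(adjacency)
  if (is.null(drug_ids)) drug_ids <- paste0("d", seq_len(nrow(adjacency)))
  if (is.null(target_ids)) target_ids <- paste0("t", seq_len(ncol(adjacency)))
  drug_ids <- as.character(drug_ids); target_ids <- as.character(target_ids)
  if (length(drug_ids) != nrow(adjacency) || length(target_ids) != ncol(adjacency)) {
    abort("id lists do not match adjacency dimensions")
  }
  if (anyDuplicated(drug_ids) || anyDuplicated(target_ids)) {
    abort("drug and target ids must be unique")
  }
  if (!all(adjacency %in% c(0, 1))) abort("adjacency entries must be 0/1")
  storage.mode(adjacency) <- "double"
  dimnames(adjacency) <- list(drug_ids, target_ids)
  structure(list(adjacency = adjacency, drug_ids = drug_ids,
                 target_ids = target_ids),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("<interaction_network> %d drugs x %d targets, %d interactions\n",
              length(x$drug_ids), length(x$target_ids), sum(x$adjacency)))
  invisible(x)
}

#' @rdname interaction_network
#' @param x An `interaction_network`.
#' @param ... Unused.
#' @method tidy interaction_network
#' @export
tidy.interaction_network <- function(x, ...) {
  tibble::tibble(
    drug = rep(x$drug_ids, times = length(x$target_ids)),
    target = rep(x$target_ids, each = length(x$drug_ids)),
    interacts = as.integer(as.vector(x$adjacency))
  )
}

#' Read a labeled binary adjacency matrix
#'
#' Same TSV dialect as [read_similarity_matrix()]: identifiers in the first
#' row and column, cells 0/1.
#'
#' @param path Input path.
#' @return An `interaction_network`.
#' @export
read_interaction_network <- function(path) {
  M <- as.matrix(read.delim(path, row.names = 1L, check.names = FALSE,
                            comment.char = "#"))
  interaction_network(M)
}

#' Gaussian interaction profile (GIP) kernel
#'
#' `K[i, j] = exp(-gamma * ||y_i - y_j||^2)` over the rows of a profile
#' matrix, with the bandwidth normalized by the mean squared profile norm:
#' `gamma = gamma_scale / mean(||y_i||^2)`, the mean taken over profiles
#' with nonzero norm so empty profiles cannot collapse the bandwidth.
#'
#' @param profiles Numeric matrix, one profile per row (binary for observed
#'   entities, real-valued for imputed ones).
#' @param gamma_scale Bandwidth multiplier (default 1).
#' @return A `similarity_matrix` with unit diagonal.
#' @export
gip_kernel <- function(profiles, gamma_scale = 1) {
  stopifnot(gamma_scale > 0)
  profiles <- as.matrix(profiles)
  if (!nrow(profiles)) abort("no profiles")
  norms2 <- rowSums(profiles^2)
  nz <- norms2 > 0
  if (!any(nz)) abort("all interaction profiles are empty; GIP bandwidth undefined")
  gamma <- gamma_scale / mean(norms2[nz])
  # ||yi - yj||^2 = |yi|^2 + |yj|^2 - 2 yi.yj
  G <- tcrossprod(profiles)
  D2 <- outer(norms2, norms2, "+") - 2 * G
  D2[D2 < 0] <- 0
  K <- exp(-gamma * D2)
  K <- (K + t(K)) / 2
  diag(K) <- 1
  similarity_matrix(K, rownames(profiles) %||% as.character(seq_len(nrow(profiles))),
                    method = "gip", params = list(gamma_scale = gamma_scale,
                                                  gamma = gamma))
}

#' Weighted nearest neighbor profile imputation
#'
#' Predicts the interaction profile of a new drug as a geometrically
#' decaying sum of the profiles of the training drugs ranked by decreasing
#' similarity: the rank-r profile enters with weight `decay^(r-1)`, and the
#' sum is clipped to `[0, 1]`. Ties in similarity are broken by the
#' training drugs' identifiers (row names) when available — stable under
#' reordering of the training set — and by training order otherwise, so
#' the result is deterministic either way.
#'
#' @param sim_to_train Numeric vector of similarities of the new drug to
#'   each training drug.
#' @param train_adjacency Binary matrix of training profiles (drugs x
#'   targets) in the same drug order.
#' @param decay Geometric decay factor in `(0, 1]` (default 0.7).
#' @return Numeric profile of length `ncol(train_adjacency)` in `[0, 1]`.
#' @export
wnn_impute <- function(sim_to_train, train_adjacency, decay = 0.7) {
  stopifnot(decay > 0, decay <= 1)
  train_adjacency <- as.matrix(train_adjacency)
  n <- nrow(train_adjacency)
  if (n == 0L) abort("empty training set")
  if (length(sim_to_train) != n) {
    abort("similarity vector length does not match training set size")
  }
  ids <- rownames(train_adjacency)
  ord <- if (is.null(ids)) {
    order(-sim_to_train)            # stable: ties keep training order
  } else {
    order(-sim_to_train, ids)       # ties on similarity follow the ids
  }
  w <- decay^(seq_len(n) - 1L)
  prof <- colSums(train_adjacency[ord, , drop = FALSE] * w)
  pmin(1, pmax(0, prof))
}

#' Convex combination of a similarity kernel and a GIP kernel
#'
#' `alpha * K_sim + (1 - alpha) * K_gip`, the blending step that lets
#' chemical (or genomic) similarity and interaction-profile similarity
#' jointly define the kernel.
#'
#' @param K_sim,K_gip `similarity_matrix` objects with identical labels.
#' @param alpha Weight on the similarity kernel, in `[0, 1]` (default 0.5).
#' @return A `similarity_matrix`.
#' @export
combine_kernels <- function(K_sim, K_gip, alpha = 0.5) {
  stopifnot(alpha >= 0, alpha <= 1)
  if (!identical(rownames(K_sim), rownames(K_gip))) {
    abort("kernel label mismatch")
  }
  similarity_matrix(alpha * unclass(as.matrix(K_sim)) +
                      (1 - alpha) * unclass(as.matrix(K_gip)),
                    rownames(K_sim), method = "combined",
                    params = list(alpha = alpha))
}

#' Kronecker regularized least squares
#'
#' Solves the pair-space smoother `scores = K (K + sigma I)^-1 vec(Y)` with
#' `K = K_target %x% K_drug`, without ever materializing the Kronecker
#' product: with eigendecompositions `K_drug = U L U'` and
#' `K_target = V M V'`, the solution is
#' `U [ (L_i M_j / (L_i M_j + sigma)) * (U' Y V) ] V'`.
#'
#' @param K_drug,K_target Symmetric PSD `similarity_matrix` objects (run
#'   [make_kernel()] first).
#' @param Y Numeric matrix of labels, drugs x targets.
#' @param sigma Regularization strength (> 0, default 1).
#' @return Numeric score matrix, drugs x targets.
#' @export
kron_rls <- function(K_drug, K_target, Y, sigma = 1) {
  stopifnot(sigma > 0)
  Y <- as.matrix(Y)
  Kd <- unclass(as.matrix(K_drug)); Kt <- unclass(as.matrix(K_target))
  if (nrow(Kd) != nrow(Y) || nrow(Kt) != ncol(Y)) {
    abort("kernel dimensions do not match the label matrix")
  }
  ed <- eigen(Kd, symmetric = TRUE)
  et <- eigen(Kt, symmetric = TRUE)
  tol <- -1e-8 * max(1, abs(ed$values[1]), abs(et$values[1]))
  if (min(ed$values) < tol || min(et$values) < tol) {
    abort("kernel is not positive semidefinite; apply make_kernel() first")
  }
  LM <- outer(ed$values, et$values)           # L_i M_j
  W <- LM / (LM + sigma)
  S <- ed$vectors %*% (W * (crossprod(ed$vectors, Y) %*% et$vectors)) %*%
    t(et$vectors)
  dimnames(S) <- dimnames(Y)
  S
}

#' WNN-GIP configuration
#'
#' Bundles the predictor's tunable parameters. `gamma_scale` multiplies the
#' GIP bandwidth; `alpha` mixes the chemical/genomic kernel with the GIP
#' kernel; `sigma` is the RLS regularization; `wnn_decay` is the geometric
#' decay of the nearest-neighbor imputation, which `wnn_enabled` can turn
#' off (new drugs then get empty profiles).
#'
#' @param gamma_scale Positive bandwidth multiplier (default 1).
#' @param alpha Kernel mixing weight in `[0, 1]` (default 0.5).
#' @param sigma Positive regularization (default 1).
#' @param wnn_decay Decay factor in `(0, 1]` (default 0.7).
#' @param wnn_enabled Impute profiles for new drugs (default `TRUE`).
#' @return A `gip_config` list.
#' @export
gip_config <- function(gamma_scale = 1, alpha = 0.5, sigma = 1,
                       wnn_decay = 0.7, wnn_enabled = TRUE) {
  stopifnot(gamma_scale > 0, alpha >= 0, alpha <= 1, sigma > 0,
            wnn_decay > 0, wnn_decay <= 1)
  structure(list(gamma_scale = gamma_scale, alpha = alpha, sigma = sigma,
                 wnn_decay = wnn_decay, wnn_enabled = wnn_enabled),
            class = "gip_config")
}

#' Predict interactions for held-out drugs with WNN-GIP
#'
#' End-to-end predictor: the test drugs' adjacency rows are hidden; their
#' interaction profiles are imputed from chemical similarity to the
#' training drugs ([wnn_impute()]); GIP kernels are built for drugs (over
#' real plus imputed profiles) and for targets (over the training
#' adjacency columns); each is blended with the chemical/genomic kernel,
#' PSD-repaired, and passed to [kron_rls()].
#'
#' @param network An `interaction_network`.
#' @param K_drug_chem Chemical `similarity_matrix` over all drugs of the
#'   network (same order).
#' @param K_target_gen Genomic `similarity_matrix` over all targets.
#' @param config A [gip_config()].
#' @param test_drugs Character vector of drug ids treated as new.
#' @return Numeric score matrix with one row per test drug (0-row matrix if
#'   `test_drugs` is empty).
#' @export
predict_interactions <- function(network, K_drug_chem, K_target_gen,
                                 config = gip_config(),
                                 test_drugs = character()) {
  stopifnot(inherits(network, "interaction_network"))
  if (!identical(rownames(K_drug_chem), network$drug_ids)) {
    abort("drug kernel labels must match the network drug ids (same order)")
  }
  if (!identical(rownames(K_target_gen), network$target_ids)) {
    abort("target kernel labels must match the network target ids (same order)")
  }
  unknown <- setdiff(test_drugs, network$drug_ids)
  if (length(unknown)) {
    abort(paste0("unknown test drug id(s): ", paste(unknown, collapse = ", ")))
  }
  if (!length(test_drugs)) {
    return(matrix(0, 0, length(network$target_ids),
                  dimnames = list(NULL, network$target_ids)))
  }
  is_test <- network$drug_ids %in% test_drugs
  train_ids <- network$drug_ids[!is_test]
  if (!length(train_ids)) abort("no training drugs left")
  Y_train <- network$adjacency[train_ids, , drop = FALSE]

  profiles <- network$adjacency
  profiles[is_test, ] <- 0
  if (config$wnn_enabled) {
    for (d in which(is_test)) {
      profiles[d, ] <- wnn_impute(
        unclass(K_drug_chem)[d, train_ids], Y_train, decay = config$wnn_decay)
    }
  }

  K_gip_d <- gip_kernel(profiles, gamma_scale = config$gamma_scale)
  K_gip_t <- gip_kernel(t(Y_train), gamma_scale = config$gamma_scale)
  Kd <- make_kernel(combine_kernels(K_drug_chem, K_gip_d, alpha = config$alpha))
  Kt <- make_kernel(combine_kernels(K_target_gen, K_gip_t, alpha = config$alpha))

  S <- kron_rls(Kd, Kt, profiles, sigma = config$sigma)
  S[test_drugs, , drop = FALSE]
}
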