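#' Construct a labeled similarity matrix
#'
#' Thin S3 wrapper around a square numeric matrix with unique row/column
#' labels and a record of the kernel and parameters that produced it.
#'
#' @param values Square numeric matrix.
#' @param labels Character vector of identifiers (defaults to existing
#'   dimnames).
#' @param method Kernel name for the metadata record.
#' @param params Named list of kernel parameters.
#' @return A `similarity_matrix`.
#' @export
similarity_matrix <- function(values, labels = rownames(values),
                              method = "precomputed", params = list()) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) abort("similarity matrix must be square")
  if (is.null(labels)) labels <- as.character(seq_len(nrow(values)))
  labels <- as.character(labels)
  if (length(labels) != nrow(values)) abort("labels do not match matrix size")
  if (anyDuplicated(labels)) abort("labels must be unique")
  if (any(!is.finite(values))) abort("similarity matrix has non-finite entries")
  dimnames(values) <- list(labels, labels)
  structure(values, method = method, params = params,
            class = c("similarity_matrix", "matrix", "array"))
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> %d x %d, method = %s\n",
              nrow(x), ncol(x), attr(x, "method")))
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x))),
                   drop = FALSE], ...)
  if (nrow(x) > 6L) cat(sprintf("... %d more rows/cols\n", nrow(x) - 6L))
  invisible(x)
}

#' @rdname similarity_matrix
#' @param x A `similarity_matrix`.
#' @param ... Unused.
#' @method tidy similarity_matrix
#' @export
tidy.similarity_matrix <- function(x, ...) {
  labs <- rownames(x)
  tibble::tibble(
    id1 = rep(labs, times = length(labs)),
    id2 = rep(labs, each = length(labs)),
    similarity = as.vector(unclass(x))
  )
}

# registry: each kernel gets a per-compound representation step and a
# pairwise scorer, so expensive profiles are built once per compound
.kernel_registry <- function(method, corpus, q = 4L, weights = c(0.33, 0.33, 0.33),
                             min_len = 2L, normalize = TRUE,
                             alphabet = "smifp34") {
  switch(method,
    edit = list(
      rep = as.list(corpus$norm_smiles),
      fun = function(a, b) edit_similarity(a, b)
    ),
    nlcs = list(
      rep = as.list(corpus$norm_smiles),
      fun = function(a, b) nlcs(a, b)
    ),
    clcs = list(
      rep = as.list(corpus$norm_smiles),
      fun = function(a, b) clcs_similarity(a, b, weights = weights)
    ),
    substring = list(
      rep = as.list(corpus$norm_smiles),
      fun = function(a, b) substring_kernel(a, b, min_len = min_len,
                                            normalize = normalize)
    ),
    lingosim = list(
      rep = lapply(corpus$lingo_smiles, extract_lingos, q = q),
      fun = function(a, b) lingosim(a, b)
    ),
    smifp_cbd = {
      alpha <- smifp_alphabet(alphabet)
      list(
        rep = lapply(corpus$smiles, compute_fingerprint, alphabet = alpha),
        fun = function(a, b) cbd_similarity(a, b)
      )
    },
    smifp_tanimoto = {
      alpha <- smifp_alphabet(alphabet)
      list(
        rep = lapply(corpus$smiles, compute_fingerprint, alphabet = alpha),
        fun = function(a, b) tanimoto_counts(a, b)
      )
    },
    abort(sprintf("unknown kernel '%s'", method))
  )
}

#' Pairwise compound similarity matrix
#'
#' Evaluates a named kernel on every pair of compounds of a prepared corpus.
#' The upper triangle is computed once and mirrored, so the result is
#' bit-exactly symmetric; the diagonal is computed, not assumed. The TF and
#' TF-IDF cosine kernels are corpus-weighted: compound vectors are built
#' over the vocabulary of this corpus (or of `vocab_corpus` when scoring
#' against a training vocabulary) and similarity is the cosine of the
#' weighted vectors, computed by row-normalized cross products.
#'
#' @param corpus Prepared compound tibble (see [prepare_compounds()]).
#' @param method One of `"edit"`, `"nlcs"`, `"clcs"`, `"substring"`,
#'   `"lingosim"`, `"tf"`, `"tfidf"`, `"smifp_cbd"`, `"smifp_tanimoto"`.
#' @param q LINGO length for the LINGO-family kernels.
#' @param weights CLCS weights.
#' @param min_len,normalize Substring-kernel parameters. Inside similarity
#'   matrices the substring kernel defaults to its cosine-normalized form;
#'   raw inner products are not comparable across molecule sizes.
#' @param alphabet Fingerprint alphabet name or file for the SMIfp kernels.
#' @param vocab_corpus Optional prepared corpus defining the TF/TF-IDF
#'   vocabulary (defaults to `corpus` itself).
#' @return A `similarity_matrix` labeled by compound id.
#' @export
#' @examples
#' corp <- prepare_compounds(data.frame(id = c("s1", "s2"),
#'                                      smiles = c("OC(O)=O", "CCCCC(O)=C4")))
#' pairwise_similarity(corp, "lingosim")["s1", "s2"]  # 2/9
pairwise_similarity <- function(corpus, method = "lingosim", q = 4L,
                                weights = c(0.33, 0.33, 0.33), min_len = 2L,
                                normalize = TRUE, alphabet = "smifp34",
                                vocab_corpus = NULL) {
  if (!nrow(corpus)) abort("empty corpus")
  params <- list(q = q, weights = weights, min_len = min_len,
                 normalize = normalize, alphabet = alphabet)
  if (method %in% c("tf", "tfidf")) {
    vc <- vocab_corpus %||% corpus
    vocab <- build_vocabulary(lapply(vc$lingo_smiles, extract_lingos, q = q))
    scheme <- if (method == "tf") "tf" else "tf-idf"
    V <- t(vapply(corpus$lingo_smiles, function(s) {
      as.numeric(vectorize(extract_lingos(s, q = q), vocab, scheme = scheme))
    }, numeric(length(vocab$terms))))
    norms <- sqrt(rowSums(V^2))
    zero <- norms == 0
    if (any(zero)) {
      warn(sprintf("%d compound(s) with all-zero %s vectors score 0 against everything",
                   sum(zero), scheme))
      norms[zero] <- 1
    }
    M <- tcrossprod(V / norms)
    M[zero, ] <- 0; M[, zero] <- 0
    M <- (M + t(M)) / 2   # remove float asymmetry from the cross product
    return(similarity_matrix(M, corpus$id, method = method, params = params))
  }
  k <- .kernel_registry(method, corpus, q = q, weights = weights,
                        min_len = min_len, normalize = normalize,
                        alphabet = alphabet)
  n <- nrow(corpus)
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in i:n) {
      v <- tryCatch(
        k$fun(k$rep[[i]], k$rep[[j]]),
        error = function(e) abort(sprintf(
          "kernel '%s' failed on pair (%s, %s): %s",
          method, corpus$id[i], corpus$id[j], conditionMessage(e)))
      )
      M[i, j] <- v
      M[j, i] <- v
    }
  }
  similarity_matrix(M, corpus$id, method = method, params = params)
}

#' Repair a similarity matrix into a valid kernel
#'
#' Symmetrizes (`(S + t(S)) / 2`) and, if the smallest eigenvalue falls
#' below `epsilon`, shifts the diagonal up by the deficit so that all
#' eigenvalues are at least `epsilon`. The diagonal shift (rather than
#' eigenvalue clipping) leaves every off-diagonal similarity untouched.
#' Idempotent up to `epsilon`.
#'
#' @param S A `similarity_matrix` (or plain square matrix).
#' @param epsilon Eigenvalue floor (default 1e-9).
#' @return A positive-definite `similarity_matrix`.
#' @export
make_kernel <- function(S, epsilon = 1e-9) {
  M <- unclass(as.matrix(S))
  if (any(!is.finite(M))) abort("non-finite entries; cannot repair kernel")
  M <- (M + t(M)) / 2
  lam_min <- min(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
  if (lam_min < epsilon) {
    diag(M) <- diag(M) + (epsilon - lam_min)
  }
  params <- attr(S, "params") %||% list()
  params$psd_shift <- max(0, epsilon - lam_min)
  similarity_matrix(M, rownames(M) %||% rownames(S),
                    method = attr(S, "method") %||% "precomputed",
                    params = params)
}

#' Composite kernel of a 2D similarity matrix and a SMILES kernel
#'
#' Convex combination `lambda * S_2d + (1 - lambda) * S_f`, the standard way
#' to blend a graph-matching similarity (e.g. SIMCOMP, supplied
#' precomputed) with a SMILES-based one. Mixing happens on the raw
#' similarities; run [make_kernel()] on the result before prediction.
#'
#' @param S_2d,S_f `similarity_matrix` objects with identical labels in
#'   identical order.
#' @param lambda Mixing weight in `[0, 1]` on `S_2d` (default 0.5, the
#'   unweighted average).
#' @return A `similarity_matrix`.
#' @export
composite_kernel <- function(S_2d, S_f, lambda = 0.5) {
  stopifnot(lambda >= 0, lambda <= 1)
  l1 <- rownames(S_2d); l2 <- rownames(S_f)
  if (!identical(l1, l2)) {
    first <- which(l1 != l2)[1] %||% (min(length(l1), length(l2)) + 1L)
    abort(sprintf("label mismatch between matrices (first divergence at %d: '%s' vs '%s')",
                  first, l1[first] %||% "<none>", l2[first] %||% "<none>"))
  }
  M <- lambda * unclass(as.matrix(S_2d)) + (1 - lambda) * unclass(as.matrix(S_f))
  similarity_matrix(M, l1, method = "composite",
                    params = list(lambda = lambda,
                                  components = c(attr(S_2d, "method") %||% "precomputed",
                                                 attr(S_f, "method") %||% "precomputed")))
}

#' Write a labeled similarity matrix as TSV
#'
#' First row and first column carry identifiers; values are written with
#' `precision` significant digits. Metadata (kernel, parameters) is embedded
#' as '#'-prefixed header comments.
#'
#' @param S A `similarity_matrix`.
#' @param path Output path.
#' @param precision Significant digits (default 6).
#' @export
write_similarity_matrix <- function(S, path, precision = 6L) {
  con <- file(path, "w")
  on.exit(close(con))
  params <- attr(S, "params") %||% list()
  meta <- paste(names(params),
                vapply(params, function(p) paste(format(unlist(p)), collapse = ","), ""),
                sep = "=", collapse = " ")
  writeLines(sprintf("# method=%s %s", attr(S, "method") %||% "precomputed", meta), con)
  labs <- rownames(S)
  writeLines(paste(c("", labs), collapse = "\t"), con)
  M <- signif(unclass(as.matrix(S)), precision)
  for (i in seq_along(labs)) {
    writeLines(paste(c(labs[i], format(M[i, ], trim = TRUE, scientific = FALSE)),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a labeled matrix from TSV
#'
#' Reads the dialect written by [write_similarity_matrix()] (and the common
#' supplementary-matrix layout: identifiers in the first row and column).
#' Tolerant of Windows line endings and '#' comment lines.
#'
#' @param path Input path.
#' @return A `similarity_matrix` for square numeric content.
#' @export
read_similarity_matrix <- function(path) {
  M <- as.matrix(read.delim(path, row.names = 1L, check.names = FALSE,
                            comment.char = "#"))
  similarity_matrix(M, rownames(M), method = "precomputed",
                    params = list(source = path))
}
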