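#' Extract LINGO q-gram profile from a SMILES string
#'
#' LINGOs are the overlapping q-character substrings of a SMILES string whose
#' ring digits have been zeroed (see [zero_ring_numbers()]); a string of
#' length n yields `n - (q - 1)` of them, counted with multiplicity.
#'
#' @param s Single character string (ring digits already zeroed).
#' @param q LINGO length in characters (default 4).
#' @return Named integer vector of LINGO counts with attribute `q`; empty if
#'   `nchar(s) < q`.
#' @export
#' @examples
#' extract_lingos("CCCCC(O)=C0")  # CCCC appears twice
extract_lingos <- function(s, q = 4L) {
  stopifnot(q >= 1L)
  n <- nchar(s)
  if (n < q) {
    out <- integer(0)
  } else {
    grams <- substring(s, 1:(n - q + 1L), q:n)
    tab <- table(factor(grams, levels = unique(grams)))  # first-appearance order
    out <- setNames(as.integer(tab), names(tab))
  }
  attr(out, "q") <- as.integer(q)
  out
}

.check_same_q <- function(p1, p2) {
  q1 <- attr(p1, "q"); q2 <- attr(p2, "q")
  if (!is.null(q1) && !is.null(q2) && q1 != q2) {
    abort(sprintf("LINGO length mismatch: q = %d vs q = %d", q1, q2))
  }
}

#' LINGOsim similarity of two LINGO profiles
#'
#' Per-LINGO count Tanimoto averaged over the union of LINGOs of the pair:
#' `mean_i(1 - |N1_i - N2_i| / (N1_i + N2_i))` where i runs over the m
#' unique LINGOs of either profile.
#'
#' @param p1,p2 LINGO profiles from [extract_lingos()] (same `q`).
#' @return Score in `[0, 1]`; 0 with a warning if both profiles are empty.
#' @export
#' @examples
#' lingosim(extract_lingos("OC(O)=O"), extract_lingos("CCCCC(O)=C0"))  # 2/9
lingosim <- function(p1, p2) {
  .check_same_q(p1, p2)
  terms <- union(names(p1), names(p2))
  if (!length(terms)) {
    warn("both LINGO profiles are empty; similarity set to 0")
    return(0)
  }
  n1 <- ifelse(terms %in% names(p1), p1[terms], 0)
  n2 <- ifelse(terms %in% names(p2), p2[terms], 0)
  mean(1 - abs(n1 - n2) / (n1 + n2))
}

#' Sublinear term-frequency weight
#'
#' `1 + log10(count)` for positive counts, 0 for absent terms. Dampens the
#' influence of highly repetitive LINGOs relative to raw counts.
#'
#' @param count Non-negative integer vector of term counts.
#' @return Numeric weights.
#' @export
#' @examples
#' tf_weight(c(0, 1, 2))  # 0, 1, 1.301
tf_weight <- function(count) {
  stopifnot(all(count >= 0))
  ifelse(count > 0, 1 + log10(count), 0)
}

#' Build a LINGO vocabulary over a compound corpus
#'
#' Treats each compound as a document and its LINGOs as terms. Term order is
#' the first-appearance order over the corpus, so vectors and reports are
#' reproducible byte-for-byte for a fixed corpus order.
#'
#' @param profiles List of LINGO profiles (uniform `q`), usually one per
#'   compound of a prepared corpus.
#' @return A `lingo_vocabulary`: list with `terms` (character), `doc_freq`
#'   (named integer), `n_docs`, and `q`.
#' @export
build_vocabulary <- function(profiles) {
  if (!length(profiles)) abort("empty corpus: no profiles to index")
  qs <- unique(unlist(lapply(profiles, attr, "q")))
  if (length(qs) > 1L) abort("profiles with mixed LINGO lengths q")
  terms <- unique(unlist(lapply(profiles, names), use.names = FALSE))
  df <- integer(length(terms))
  names(df) <- terms
  for (p in profiles) {
    present <- names(p)[p > 0L]
    df[present] <- df[present] + 1L
  }
  structure(
    list(terms = terms, doc_freq = df, n_docs = length(profiles),
         q = if (length(qs)) qs else NA_integer_),
    class = "lingo_vocabulary"
  )
}

#' @export
print.lingo_vocabulary <- function(x, ...) {
  cat(sprintf("<lingo_vocabulary> %d terms over %d compounds (q = %s)\n",
              length(x$terms), x$n_docs, x$q))
  invisible(x)
}

#' Inverse document frequency of a LINGO
#'
#' `log10(n_docs / doc_freq)`, without smoothing. A LINGO present in every
#' compound has IDF 0 and behaves like a stop word; rare LINGOs get large
#' weights and dominate TF-IDF similarity.
#'
#' @param term Character vector of LINGOs (must be in the vocabulary).
#' @param vocab A `lingo_vocabulary`.
#' @return Numeric IDF weights.
#' @export
#' @examples
#' # log10(445/300) = 0.17 for a near-ubiquitous LINGO in a 445-compound set
idf <- function(term, vocab) {
  stopifnot(inherits(vocab, "lingo_vocabulary"))
  missing <- setdiff(term, vocab$terms)
  if (length(missing)) {
    abort(paste0("term(s) not in vocabulary: ",
                 paste(head(missing, 5L), collapse = ", ")))
  }
  log10(vocab$n_docs / vocab$doc_freq[term])
}

#' Project a LINGO profile onto a corpus vocabulary
#'
#' Returns the dense weight vector of a compound in the vocabulary's term
#' order. LINGOs absent from the vocabulary (possible when scoring unseen
#' compounds against a restricted vocabulary) are dropped; the number
#' dropped is reported via an attribute.
#'
#' @param profile LINGO profile from [extract_lingos()].
#' @param vocab A `lingo_vocabulary` built at the same `q`.
#' @param scheme `"tf"` (sublinear TF) or `"tf-idf"` (TF times IDF).
#' @return Numeric vector of length `length(vocab$terms)` with attribute
#'   `n_dropped`.
#' @export
vectorize <- function(profile, vocab, scheme = c("tf", "tf-idf")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(vocab, "lingo_vocabulary"))
  qp <- attr(profile, "q")
  if (!is.null(qp) && !is.na(vocab$q) && qp != vocab$q) {
    abort(sprintf("profile q = %d but vocabulary q = %d", qp, vocab$q))
  }
  counts <- numeric(length(vocab$terms))
  names(counts) <- vocab$terms
  keep <- intersect(names(profile), vocab$terms)
  counts[keep] <- profile[keep]
  w <- tf_weight(counts)
  if (scheme == "tf-idf") w <- w * log10(vocab$n_docs / vocab$doc_freq)
  attr(w, "n_dropped") <- length(profile) - length(keep)
  w
}

#' Cosine similarity of two weight vectors
#'
#' `dot(v1, v2) / (||v1|| ||v2||)`; 0 (with a warning) if either vector is
#' all zero.
#'
#' @param v1,v2 Numeric vectors of equal length (same vocabulary order).
#' @return Score in `[0, 1]` for non-negative weights.
#' @export
cosine_similarity <- function(v1, v2) {
  if (length(v1) != length(v2)) {
    abort("vectors come from different vocabularies (length mismatch)")
  }
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) {
    warn("zero-norm vector; cosine similarity set to 0")
    return(0)
  }
  sum(v1 * v2) / (n1 * n2)
}

#' Corpus LINGO report: stop-word-like and rare LINGOs
#'
#' Ranks the vocabulary by ascending IDF (descending document frequency),
#' lexicographic on ties, and returns the top rows. Low-IDF LINGOs are the
#' corpus' "stop words": substructures so common (aromatic ring runs,
#' carbonyls) that they carry little discriminating power.
#'
#' @param corpus Prepared compound tibble (see [prepare_compounds()]).
#' @param q LINGO length (default 4).
#' @param top_k Number of rows to return (default 10).
#' @return Tibble with columns `lingo`, `doc_freq`, `idf`.
#' @export
lingo_report <- function(corpus, q = 4L, top_k = 10L) {
  if (top_k <= 0L) abort("`top_k` must be positive")
  vocab <- build_vocabulary(lapply(corpus$lingo_smiles, extract_lingos, q = q))
  out <- tibble::tibble(
    lingo = vocab$terms,
    doc_freq = as.integer(vocab$doc_freq),
    idf = as.numeric(idf(vocab$terms, vocab))
  )
  out <- dplyr::arrange(out, .data$idf, .data$lingo)
  head(out, top_k)
}
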