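#' Levenshtein edit distance
#'
#' Minimum number of unit-cost insertions, deletions and substitutions
#' turning `s1` into `s2`. Computed by the classic dynamic program, one row
#' at a time with the insertion recurrence folded into a running minimum so
#' each row is vectorized.
#'
#' @param s1,s2 Single character strings.
#' @return Non-negative integer distance.
#' @export
#' @examples
#' edit_distance("OC(O)=O", "CCCCC(O)=C4")  # 6
edit_distance <- function(s1, s2) {
  a <- strsplit(s1, "", fixed = TRUE)[[1]]
  b <- strsplit(s2, "", fixed = TRUE)[[1]]
  n <- length(a); m <- length(b)
  if (n == 0L) return(m)
  if (m == 0L) return(n)
  prev <- 0:m
  idx <- 0:m
  for (i in seq_len(n)) {
    cand <- pmin(prev[-1L] + 1L,                 # deletion from s1
                 prev[-(m + 1L)] + (a[i] != b))  # substitution / match
    # insertion: cur[j] = min(cand[j], cur[j-1] + 1) == cummin over z - idx
    z <- c(i, cand)
    prev <- cummin(z - idx) + idx
  }
  prev[m + 1L]
}

#' Edit similarity
#'
#' `1 - edit_distance / max(nchar(s1), nchar(s2))`; 1 for identical strings,
#' 0 when every position must change. Two empty strings are identical by
#' convention and score 1.
#'
#' @inheritParams edit_distance
#' @return Score in `[0, 1]`.
#' @export
#' @examples
#' edit_similarity("OC(O)=O", "CCCCC(O)=C4")  # 1 - 6/11
edit_similarity <- function(s1, s2) {
  n <- nchar(s1); m <- nchar(s2)
  if (n == 0L && m == 0L) return(1)
  1 - edit_distance(s1, s2) / max(n, m)
}

#' Longest common subsequence length
#'
#' Length of the longest (not necessarily contiguous) common subsequence,
#' by row-rolled dynamic programming.
#'
#' @inheritParams edit_distance
#' @return Non-negative integer length.
#' @export
lcs_length <- function(s1, s2) {
  a <- strsplit(s1, "", fixed = TRUE)[[1]]
  b <- strsplit(s2, "", fixed = TRUE)[[1]]
  n <- length(a); m <- length(b)
  if (n == 0L || m == 0L) return(0L)
  prev <- integer(m)
  for (i in seq_len(n)) {
    diag <- c(0L, prev[-m])
    prev <- cummax(ifelse(a[i] == b, diag + 1L, prev))
  }
  prev[m]
}

#' Longest common contiguous substring length
#'
#' @inheritParams edit_distance
#' @return Non-negative integer length.
#' @export
lcsubstring_length <- function(s1, s2) {
  a <- strsplit(s1, "", fixed = TRUE)[[1]]
  b <- strsplit(s2, "", fixed = TRUE)[[1]]
  n <- length(a); m <- length(b)
  if (n == 0L || m == 0L) return(0L)
  prev <- integer(m)
  best <- 0L
  for (i in seq_len(n)) {
    prev <- (a[i] == b) * (c(0L, prev[-m]) + 1L)
    best <- max(best, prev)
  }
  as.integer(best)
}

.warn_empty <- function(op) {
  warn(sprintf("%s: empty string, similarity set to 0", op))
  0
}

#' Normalized longest common subsequence similarity (NLCS)
#'
#' `len(LCS)^2 / (nchar(s1) * nchar(s2))`. Squaring the LCS length rewards
#' pairs whose common subsequence covers a large fraction of both strings.
#'
#' @inheritParams edit_distance
#' @return Score in `[0, 1]`.
#' @export
#' @examples
#' nlcs("OC(O)=O", "CCCCC(O)=C4")  # 25/77
nlcs <- function(s1, s2) {
  if (nchar(s1) == 0L || nchar(s2) == 0L) return(.warn_empty("nlcs"))
  lcs_length(s1, s2)^2 / (nchar(s1) * nchar(s2))
}

#' Normalized maximal consecutive LCS from the first character (NMCLCS1)
#'
#' Longest prefix of the shorter string occurring as a contiguous substring
#' of the longer one, normalized as `len^2 / (nchar(s1) * nchar(s2))`. For
#' equal-length strings the larger of the two directions is used so the
#' score stays symmetric.
#'
#' @inheritParams edit_distance
#' @return Score in `[0, 1]`.
#' @export
#' @examples
#' nmclcs1("OC(O)=O", "CCCCC(O)=C4")  # 1/77
nmclcs1 <- function(s1, s2) {
  n <- nchar(s1); m <- nchar(s2)
  if (n == 0L || m == 0L) return(.warn_empty("nmclcs1"))
  prefix_in <- function(short, long) {
    for (k in nchar(short):1) {
      if (grepl(substr(short, 1L, k), long, fixed = TRUE)) return(k)
    }
    0L
  }
  len <- if (n < m) {
    prefix_in(s1, s2)
  } else if (m < n) {
    prefix_in(s2, s1)
  } else {
    max(prefix_in(s1, s2), prefix_in(s2, s1))
  }
  len^2 / (n * m)
}

#' Normalized maximal consecutive LCS from any position (NMCLCSn)
#'
#' Longest common contiguous substring, normalized as
#' `len^2 / (nchar(s1) * nchar(s2))`.
#'
#' @inheritParams edit_distance
#' @return Score in `[0, 1]`.
#' @export
#' @examples
#' nmclcsn("OC(O)=O", "CCCCC(O)=C4")  # 25/77 (substring "C(O)=")
nmclcsn <- function(s1, s2) {
  if (nchar(s1) == 0L || nchar(s2) == 0L) return(.warn_empty("nmclcsn"))
  lcsubstring_length(s1, s2)^2 / (nchar(s1) * nchar(s2))
}

#' Combined LCS similarity (CLCS)
#'
#' Weighted sum `w1 * NLCS + w2 * NMCLCS1 + w3 * NMCLCSn`, combining the
#' subsequence, anchored-substring and free-substring views of similarity.
#' The default weights are the literal value 0.33 each (not 1/3), so two
#' identical strings score 0.99. Components enter unrounded.
#'
#' @inheritParams edit_distance
#' @param weights Numeric vector of three non-negative weights
#'   `(w1, w2, w3)`.
#' @return Non-negative score (`sum(weights)` at identity).
#' @export
#' @examples
#' clcs_similarity("OC(O)=O", "CCCCC(O)=C4")  # 0.33 * 51/77 = 0.2186
clcs_similarity <- function(s1, s2, weights = c(0.33, 0.33, 0.33)) {
  stopifnot(is.numeric(weights), length(weights) == 3L, all(weights >= 0))
  weights[1L] * nlcs(s1, s2) +
    weights[2L] * nmclcs1(s1, s2) +
    weights[3L] * nmclcsn(s1, s2)
}

#' Substring frequency profile
#'
#' Counts every contiguous substring of length at least `min_len` (up to the
#' full string). The number of distinct substrings grows quadratically with
#' string length, so inputs longer than `max_len` characters are rejected.
#'
#' @param s Single character string.
#' @param min_len Minimum substring length (default 2).
#' @param max_len Guard against pathological input lengths (default 2000).
#' @return Named integer vector of substring counts (empty, with a warning,
#'   if `nchar(s) < min_len`).
#' @export
#' @examples
#' substring_profile("CCC")  # CC: 2, CCC: 1
substring_profile <- function(s, min_len = 2L, max_len = 2000L) {
  stopifnot(min_len >= 1L)
  n <- nchar(s)
  if (n > max_len) {
    abort(sprintf("string of length %d exceeds the substring-profile cap (%d)",
                  n, max_len))
  }
  if (n < min_len) {
    warn(sprintf("string shorter than min_len = %d: empty profile", min_len))
    return(integer(0))
  }
  subs <- unlist(lapply(min_len:n, function(len) {
    substring(s, 1:(n - len + 1L), len:n)
  }), use.names = FALSE)
  tab <- table(subs)
  setNames(as.integer(tab), names(tab))
}

#' SMILES substring kernel
#'
#' Inner product of the substring frequency profiles of two strings over
#' their shared substrings of length `>= min_len`. The raw inner product is
#' the default (it is not length-normalized); `normalize = TRUE` divides by
#' `sqrt(K(s1,s1) * K(s2,s2))`, which is the variant to use when raw counts
#' must be comparable across molecules of different sizes.
#'
#' @inheritParams edit_distance
#' @inheritParams substring_profile
#' @param normalize If `TRUE`, cosine-normalize the kernel.
#' @return Non-negative score.
#' @export
#' @examples
#' substring_kernel("OC(O)=O", "CCCCC(O)=C4")  # 10
substring_kernel <- function(s1, s2, min_len = 2L, normalize = FALSE) {
  p1 <- suppressWarnings(substring_profile(s1, min_len))
  p2 <- suppressWarnings(substring_profile(s2, min_len))
  shared <- intersect(names(p1), names(p2))
  k12 <- sum(as.numeric(p1[shared]) * as.numeric(p2[shared]))
  if (!normalize) return(k12)
  k11 <- sum(as.numeric(p1)^2)
  k22 <- sum(as.numeric(p2)^2)
  if (k11 == 0 || k22 == 0) return(0)
  k12 / sqrt(k11 * k22)
}
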