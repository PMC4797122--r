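# Built-in fingerprint alphabets. The historical 34-symbol set is not
# reprinted anywhere we ship from, so `smifp34` is a synthetic stand-in
# covering the organic subset, halogens, brackets, bonds, charges, ring
# digits and '%' (see also inst/extdata/smifp34_synthetic.txt). The 38D
# variant is derived from it exactly as published: drop '%', add the
# chirality and directional-bond tokens '@', '@@', '.', '\' and '/'.
.smifp34_symbols <- c(
  "C", "c", "N", "n", "O", "o", "S", "s", "P", "F", "I", "B",
  "Cl", "Br",
  "(", ")", "[", "]",
  "=", "#", "-", "+", "H",
  as.character(0:9),
  "%"
)
.smifp38_symbols <- c(setdiff(.smifp34_symbols, "%"),
                      "@", "@@", ".", "\\", "/")

#' Fingerprint alphabets
#'
#' Returns the ordered symbol list for a SMILES fingerprint. `"smifp34"` is
#' the package's synthetic reconstruction of the classic 34-symbol set;
#' `"smifp38"` removes '%' and adds the chirality ('@', '@@'), component
#' ('.') and directional-bond ('\\', '/') tokens, giving exactly 38 symbols.
#' A file path (one symbol per line) defines a custom alphabet.
#'
#' @param name `"smifp34"`, `"smifp38"`, or a path to a symbol file.
#' @return Character vector of unique symbols with attribute `name`.
#' @export
#' @examples
#' length(smifp_alphabet("smifp38"))  # 38
smifp_alphabet <- function(name = "smifp34") {
  symbols <- switch(name,
    smifp34 = .smifp34_symbols,
    smifp38 = .smifp38_symbols,
    {
      if (!file.exists(name)) {
        abort(sprintf("unknown alphabet '%s' (not smifp34/smifp38 or a file)",
                      name))
      }
      lines <- readLines(name, warn = FALSE)
      # a line that is exactly "#" is the bond symbol, not a comment
      lines[nzchar(lines) & (lines == "#" | !grepl("^#", lines))]
    }
  )
  if (anyDuplicated(symbols)) abort("alphabet symbols must be unique")
  attr(symbols, "name") <- if (name %in% c("smifp34", "smifp38")) name else "custom"
  symbols
}

#' Compute a SMILES fingerprint
#'
#' Counts the occurrences of each alphabet symbol in the raw SMILES string
#' (before two-character atom collapsing, so '@@', '/' and '\\' survive).
#' Tokenization is greedy: a two-character symbol consumes both characters,
#' so "@@" increments '@@' once and '@' not at all. Characters outside the
#' alphabet are ignored (their number is available as attribute
#' `n_ignored`).
#'
#' @param smiles Single raw SMILES string.
#' @param alphabet Symbol vector from [smifp_alphabet()].
#' @return Named integer count vector (class `smifp`) with attributes
#'   `alphabet` and `n_ignored`.
#' @export
#' @examples
#' fp <- compute_fingerprint("C[C@@H](O)N", smifp_alphabet("smifp38"))
#' fp[["@@"]]  # 1
compute_fingerprint <- function(smiles, alphabet = smifp_alphabet("smifp34")) {
  two <- alphabet[nchar(alphabet) == 2L]
  one <- alphabet[nchar(alphabet) == 1L]
  counts <- setNames(integer(length(alphabet)), alphabet)
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)
  ignored <- 0L
  i <- 1L
  while (i <= n) {
    tok <- NULL
    if (i < n) {
      pair <- paste0(chars[i], chars[i + 1L])
      if (pair %in% two) tok <- pair
    }
    if (is.null(tok) && chars[i] %in% one) tok <- chars[i]
    if (is.null(tok)) {
      ignored <- ignored + 1L
      i <- i + 1L
    } else {
      counts[tok] <- counts[tok] + 1L
      i <- i + nchar(tok)
    }
  }
  structure(counts,
            alphabet = attr(alphabet, "name") %||% "custom",
            n_ignored = ignored,
            class = "smifp")
}

.check_same_alphabet <- function(f1, f2) {
  if (length(f1) != length(f2) || !identical(names(f1), names(f2))) {
    abort("fingerprints computed over different alphabets")
  }
}

#' City Block (Manhattan) distance between fingerprints
#'
#' @param f1,f2 Fingerprints over the same alphabet.
#' @return Non-negative integer; 0 iff the count vectors are identical.
#' @export
city_block_distance <- function(f1, f2) {
  .check_same_alphabet(f1, f2)
  sum(abs(as.integer(f1) - as.integer(f2)))
}

#' City-Block-derived similarity
#'
#' `1 / (1 + CBD)`: a monotone decreasing transform of the City Block
#' distance into `(0, 1]`, so the fingerprint distance can slot into kernel
#' machinery that expects similarities. Rankings (and hence AUC metrics)
#' are unaffected by the choice of monotone transform.
#'
#' @inheritParams city_block_distance
#' @return Score in `(0, 1]`.
#' @export
cbd_similarity <- function(f1, f2) {
  1 / (1 + city_block_distance(f1, f2))
}

#' Count Tanimoto similarity between fingerprints
#'
#' `dot(c1, c2) / (||c1||^2 + ||c2||^2 - dot(c1, c2))`; 1 for identical
#' count vectors, 0 for disjoint support.
#'
#' @inheritParams city_block_distance
#' @return Score in `[0, 1]`; 0 with a warning if both are all-zero.
#' @export
tanimoto_counts <- function(f1, f2) {
  .check_same_alphabet(f1, f2)
  a <- as.numeric(f1); b <- as.numeric(f2)
  dot <- sum(a * b)
  denom <- sum(a^2) + sum(b^2) - dot
  if (denom == 0) {
    warn("both fingerprints are all-zero; Tanimoto set to 0")
    return(0)
  }
  dot / denom
}
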