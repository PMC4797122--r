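#' Default two-character atom replacement table
#'
#' Whole-string kernels compare SMILES character by character, so atoms
#' written with two characters ('Cl', 'Br', ...) would be over-weighted or
#' split across substrings. Each such atom is collapsed to a single
#' replacement character that is not itself a SMILES organic-subset symbol.
#'
#' @return Named character vector mapping two-character atom tokens to their
#'   single-character replacements.
#' @export
#' @examples
#' default_atom_table()
default_atom_table <- function() {
  c(Cl = "L", Br = "R", Si = "A", Se = "Z")
}

# single-character atom/bond symbols that replacement values must not shadow
.smiles_reserved <- c(
  "B", "C", "N", "O", "P", "S", "F", "I", "H",
  "b", "c", "n", "o", "p", "s",
  "(", ")", "[", "]", "=", "#", "-", "+", "/", "\\", ".", "@", "%",
  as.character(0:9)
)

#' Collapse two-character atom tokens to single characters
#'
#' Applies the replacement table greedily left-to-right; all other characters
#' pass through unchanged. Whitespace is stripped first (it is not a legal
#' SMILES token). The operation is idempotent.
#'
#' @param smiles Character vector of SMILES strings.
#' @param table Named character vector, two-character token -> single
#'   character, as from [default_atom_table()].
#' @return Character vector of normalized SMILES.
#' @export
#' @examples
#' normalize_atoms("ClCCCl")        # "LCCL"
#' normalize_atoms("BrC(Br)Cl")     # "RC(R)L"
normalize_atoms <- function(smiles, table = default_atom_table()) {
  stopifnot(is.character(smiles))
  if (length(table)) {
    if (is.null(names(table)) || any(names(table) == "")) {
      abort("`table` must be a named character vector (two-char token -> char).")
    }
    if (any(nchar(table) != 1L)) {
      abort("replacement values must be single characters")
    }
    bad <- table[table %in% .smiles_reserved]
    if (length(bad)) {
      abort(paste0(
        "replacement value(s) collide with SMILES symbols: ",
        paste(sprintf("'%s'->'%s'", names(bad), bad), collapse = ", ")
      ))
    }
  }
  out <- gsub("[[:space:]]+", "", smiles)
  # longer keys first so e.g. a 3-char key would win over its 2-char prefix
  for (key in names(table)[order(-nchar(names(table)))]) {
    out <- gsub(key, table[[key]], out, fixed = TRUE)
  }
  out
}

#' Set ring-closure digits to zero
#'
#' LINGO profiles treat ring-closure numbers as arbitrary bookkeeping labels:
#' the same ring drawn with label 1 or 4 is the same structure, so all ring
#' digits outside square-bracket atom blocks are set to '0' before q-gram
#' extraction. Digits inside `[...]` (isotopes, charges, hydrogen counts) are
#' untouched. Length-preserving and idempotent.
#'
#' @param smiles Character vector of (normalized) SMILES strings.
#' @return Character vector with ring digits zeroed.
#' @export
#' @examples
#' zero_ring_numbers("CCCCC(O)=C4")  # "CCCCC(O)=C0"
#' zero_ring_numbers("c1ccccc1")     # "c0ccccc0"
zero_ring_numbers <- function(smiles) {
  stopifnot(is.character(smiles))
  vapply(smiles, function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    depth <- 0L
    for (i in seq_along(chars)) {
      ch <- chars[i]
      if (ch == "[") {
        depth <- depth + 1L
      } else if (ch == "]") {
        depth <- depth - 1L
        if (depth < 0L) {
          abort(sprintf("unbalanced ']' at position %d in \"%s\"", i, s))
        }
      } else if (depth == 0L && ch >= "0" && ch <= "9") {
        chars[i] <- "0"
      }
    }
    if (depth != 0L) {
      abort(sprintf("unbalanced '[' in \"%s\" (%d unclosed)", s, depth))
    }
    paste(chars, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Prepare a compound corpus for the similarity kernels
#'
#' Takes a data frame of compound identifiers and raw SMILES and adds the two
#' preprocessed forms every kernel consumes: `norm_smiles` (whitespace
#' stripped, two-character atoms collapsed) and `lingo_smiles` (additionally
#' ring digits zeroed, used by the LINGO-family kernels). SMILES are assumed
#' already canonical; no canonicalization is attempted.
#'
#' @param compounds Data frame with columns `id` and `smiles`.
#' @param atom_table Replacement table passed to [normalize_atoms()].
#' @return A tibble with columns `id`, `smiles`, `norm_smiles`,
#'   `lingo_smiles`.
#' @export
#' @examples
#' prepare_compounds(data.frame(id = c("a", "b"),
#'                              smiles = c("OC(O)=O", "CCCCC(O)=C4")))
prepare_compounds <- function(compounds, atom_table = default_atom_table()) {
  compounds <- tibble::as_tibble(compounds)
  if (!all(c("id", "smiles") %in% names(compounds))) {
    abort("`compounds` must have columns `id` and `smiles`")
  }
  ids <- as.character(compounds$id)
  if (any(is.na(ids) | ids == "")) abort("compound ids must be non-empty")
  if (anyDuplicated(ids)) {
    abort(paste0("duplicated compound id(s): ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  norm <- normalize_atoms(compounds$smiles, atom_table)
  tibble::tibble(
    id = ids,
    smiles = as.character(compounds$smiles),
    norm_smiles = norm,
    lingo_smiles = zero_ring_numbers(norm)
  )
}

#' Read a compound list file
#'
#' Two-column tab-separated text, `id<TAB>smiles`; lines starting with '#'
#' are comments. Returns the prepared corpus (see [prepare_compounds()]).
#'
#' @param path Path to the file.
#' @inheritParams prepare_compounds
#' @return A prepared compound tibble.
#' @export
read_compound_list <- function(path, atom_table = default_atom_table()) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) abort(sprintf("no compound records in '%s'", path))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2L)) {
    abort(sprintf("line(s) without an id<TAB>smiles pair in '%s'", path))
  }
  prepare_compounds(
    data.frame(
      id = vapply(parts, `[[`, "", 1L),
      smiles = vapply(parts, `[[`, "", 2L)
    ),
    atom_table = atom_table
  )
}
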