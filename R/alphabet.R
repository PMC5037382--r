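#' The six-group hydropathy-reduced amino-acid alphabet
#'
#' Residues are partitioned by hydropathy character into six groups:
#' strongly hydrophilic/polar (R, D, E, N, Q, K, H), strongly hydrophobic
#' (L, I, V, A, M, F), weakly hydrophilic/hydrophobic (S, T, Y, W), and the
#' singletons proline, glycine and cysteine, whose backbone chemistry sets
#' them apart. Group indices 1..6 are the symbols of the reduced alphabet.
#'
#' @param groups optional list of 6 character vectors overriding the default
#'   partition; must be disjoint and cover the 20 canonical residues.
#' @return An object of class `reduced_alphabet`: a list with `groups`
#'   (named list of residue vectors) and `map` (named integer vector,
#'   residue -> group index).
#' @examples
#' raac_alphabet()
#' @export
raac_alphabet <- function(groups = NULL) {
  if (is.null(groups)) {
    groups <- list(
      g1 = c("R", "D", "E", "N", "Q", "K", "H"),
      g2 = c("L", "I", "V", "A", "M", "F"),
      g3 = c("S", "T", "Y", "W"),
      g4 = "P",
      g5 = "G",
      g6 = "C")
  }
  if (length(groups) != 6) stopf("a reduced alphabet must have exactly 6 groups")
  all_res <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(all_res))
    stopf("groups overlap at residue '%s'", all_res[anyDuplicated(all_res)])
  if (!setequal(all_res, AA_ALPHABET))
    stopf("groups must partition the 20 canonical residues exactly")
  map <- integer(0)
  for (g in seq_along(groups)) map[groups[[g]]] <- g
  out <- list(groups = groups, map = map[AA_ALPHABET])
  class(out) <- "reduced_alphabet"
  out
}

#' @export
print.reduced_alphabet <- function(x, ...) {
  cat("reduced_alphabet (6 groups):\n")
  for (g in seq_along(x$groups))
    cat(sprintf("  %d: %s\n", g, paste(x$groups[[g]], collapse = " ")))
  invisible(x)
}

#' Rewrite a peptide sequence in the reduced alphabet
#'
#' Maps each residue to its group index, producing a digit string of the same
#' length, e.g. `"PGC"` -> `"456"` under the default partition.
#'
#' @param sequence character vector of peptide sequences.
#' @param alphabet a [raac_alphabet()].
#' @return character vector of group-index strings, one per input sequence.
#' @export
reduce_sequence <- function(sequence, alphabet = raac_alphabet()) {
  stopifnot(inherits(alphabet, "reduced_alphabet"))
  sequence <- toupper(as.character(sequence))
  vapply(sequence, function(s) {
    res <- strsplit(s, "")[[1]]
    idx <- alphabet$map[res]
    if (anyNA(idx))
      stopf("residue '%s' not covered by the reduced alphabet", res[is.na(idx)][1])
    paste(idx, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
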