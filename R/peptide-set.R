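#' Peptide datasets
#'
#' A `peptide_set` holds identified peptide sequences over the 20 canonical
#' amino-acid letters, each optionally labelled `"positive"` (anticancer) or
#' `"negative"`. It is the input container for every encoder, the classifier
#' and the cross-validation harness.
#'
#' @param id character vector of unique, non-empty record identifiers.
#' @param sequence character vector of peptide sequences (canonical 20-letter
#'   alphabet; lower case is folded to upper case).
#' @param label optional character vector, each element `"positive"`,
#'   `"negative"` or `NA` (unlabelled).
#' @return An object of class `peptide_set`: a data frame with columns
#'   `id`, `sequence`, `label`.
#' @examples
#' peptide_set(c("p1", "p2"), c("GLFDIVK", "KWKLFKK"), c("positive", "negative"))
#' @export
peptide_set <- function(id, sequence, label = NULL) {
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  if (length(id) != length(sequence))
    stopf("id and sequence must have the same length")
  if (any(!nzchar(id)) || anyNA(id))
    stopf("record ids must be non-empty strings")
  if (anyDuplicated(id))
    stopf("duplicate record id: '%s'", id[anyDuplicated(id)])
  if (is.null(label)) label <- rep(NA_character_, length(id))
  label <- as.character(label)
  if (length(label) != length(id))
    stopf("label must have one entry per record")
  bad <- !is.na(label) & !label %in% c("positive", "negative")
  if (any(bad))
    stopf("invalid label '%s' (must be 'positive' or 'negative')", label[bad][1])
  validate_sequences(sequence, id)
  out <- data.frame(id = id, sequence = sequence, label = label,
                    stringsAsFactors = FALSE)
  class(out) <- c("peptide_set", "data.frame")
  out
}

validate_sequences <- function(sequence, id) {
  if (any(nchar(sequence) < 1))
    stopf("empty sequence in record '%s'", id[nchar(sequence) < 1][1])
  ok <- grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", sequence)
  if (any(!ok)) {
    i <- which(!ok)[1]
    ch <- regmatches(sequence[i], regexpr("[^ACDEFGHIKLMNPQRSTVWY]", sequence[i]))
    stopf("record '%s' contains non-canonical residue '%s'", id[i], ch)
  }
  invisible(TRUE)
}

#' @export
print.peptide_set <- function(x, ...) {
  cat(sprintf("peptide_set: %d record(s), %d positive, %d negative, %d unlabelled\n",
              nrow(x), sum(x$label == "positive", na.rm = TRUE),
              sum(x$label == "negative", na.rm = TRUE), sum(is.na(x$label))))
  if (nrow(x) > 0) {
    show <- utils::head(as.data.frame(x), 6)
    show$sequence <- ifelse(nchar(show$sequence) > 30,
                            paste0(substr(show$sequence, 1, 27), "..."),
                            show$sequence)
    print(show, row.names = FALSE)
    if (nrow(x) > 6) cat(sprintf("... and %d more\n", nrow(x) - 6))
  }
  invisible(x)
}

#' Class sizes of a labelled peptide set
#'
#' @param x a `peptide_set`.
#' @return Named integer vector with elements `n_pos` and `n_neg`.
#' @export
class_counts <- function(x) {
  stopifnot(inherits(x, "peptide_set"))
  c(n_pos = sum(x$label == "positive", na.rm = TRUE),
    n_neg = sum(x$label == "negative", na.rm = TRUE))
}

#' Read peptides from a FASTA file
#'
#' Sequences are upper-cased and validated against the canonical 20-letter
#' amino-acid alphabet. Residue codes outside it (B, J, O, U, X, Z, ...) are
#' handled according to `ambiguous`: `"strict"` (default) raises an error
#' naming the record and the offending character, `"drop-record"` silently
#' removes the affected records, `"delete-residue"` strips the offending
#' characters (a record left empty is then dropped).
#'
#' @param path FASTA file path.
#' @param label optional class tag (`"positive"` or `"negative"`) applied to
#'   every record, mirroring class-separated benchmark files.
#' @param ambiguous policy for non-canonical residues (see Details).
#' @return A [peptide_set].
#' @seealso [write_fasta()], [read_label_tsv()]
#' @export
read_fasta <- function(path, label = NULL,
                       ambiguous = c("strict", "drop-record", "delete-residue")) {
  ambiguous <- match.arg(ambiguous)
  if (!file.exists(path)) stopf("FASTA file not found: '%s'", path)
  set <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) stopf("cannot parse FASTA '%s': %s", path, conditionMessage(e)))
  if (length(set) == 0) stopf("FASTA '%s' contains no records", path)
  # first whitespace-delimited token of the header is the id
  ids <- vapply(strsplit(names(set), "[ \t]+"), `[`, character(1), 1)
  if (any(is.na(ids) | !nzchar(ids)))
    stopf("FASTA '%s' has a record with an empty header", path)
  seqs <- toupper(gsub("[ \t]", "", as.character(set)))
  if (ambiguous != "strict") {
    canon <- grepl("^[ACDEFGHIKLMNPQRSTVWY]*$", seqs)
    if (ambiguous == "drop-record") {
      keep <- canon & nchar(seqs) > 0
      ids <- ids[keep]; seqs <- seqs[keep]
    } else {
      seqs <- gsub("[^ACDEFGHIKLMNPQRSTVWY]", "", seqs)
      keep <- nchar(seqs) > 0
      ids <- ids[keep]; seqs <- seqs[keep]
    }
    if (length(ids) == 0)
      stopf("no records left in '%s' after ambiguity filtering", path)
  }
  lab <- if (is.null(label)) NULL else rep(label, length(ids))
  peptide_set(ids, seqs, lab)
}

#' Write a peptide set to FASTA
#'
#' Round-trip guarantee: `read_fasta()` on the output reproduces ids and
#' sequences exactly. Labels are not stored in FASTA; use [write_label_tsv()].
#'
#' @param x a non-empty `peptide_set`.
#' @param path output file path.
#' @param width sequence line width (default 60 columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60L) {
  stopifnot(inherits(x, "peptide_set"))
  if (nrow(x) == 0) stopf("refusing to write an empty peptide_set")
  set <- Biostrings::AAStringSet(x$sequence)
  names(set) <- x$id
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Read a two-column id/label TSV and attach labels to a peptide set
#'
#' The file has two tab-separated columns, id and label (`positive` or
#' `negative`), no header.
#'
#' @param path label TSV path.
#' @return data frame with columns `id`, `label`.
#' @export
read_label_tsv <- function(path) {
  if (!file.exists(path)) stopf("label file not found: '%s'", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character", col.names = c("id", "label"))
  bad <- !df$label %in% c("positive", "negative")
  if (any(bad)) stopf("invalid label '%s' for id '%s'", df$label[bad][1], df$id[bad][1])
  if (anyDuplicated(df$id)) stopf("duplicate id in label file: '%s'", df$id[anyDuplicated(df$id)])
  df
}

#' @rdname read_label_tsv
#' @param x a `peptide_set`.
#' @export
write_label_tsv <- function(x, path) {
  stopifnot(inherits(x, "peptide_set"))
  utils::write.table(x[, c("id", "label")], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Attach labels from a lookup table
#'
#' @param x a `peptide_set`.
#' @param labels data frame with columns `id` and `label` (as from
#'   [read_label_tsv()]).
#' @return `x` with its `label` column filled in.
#' @export
apply_labels <- function(x, labels) {
  stopifnot(inherits(x, "peptide_set"))
  m <- match(x$id, labels$id)
  if (anyNA(m)) stopf("no label for record '%s'", x$id[is.na(m)][1])
  peptide_set(x$id, x$sequence, labels$label[m])
}

# rbind two peptide sets, keeping class and id uniqueness checks
combine_sets <- function(a, b) {
  peptide_set(c(a$id, b$id), c(a$sequence, b$sequence), c(a$label, b$label))
}
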