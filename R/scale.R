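ATOM_ORDER <- c("HA", "HN", "N15", "CA13")

#' Chemical-shift reference scales
#'
#' A `shift_scale` stores, for each backbone atom type (1H-alpha `HA`,
#' amide 1H `HN`, 15N `N15`, 13C-alpha `CA13`), a reference average chemical
#' shift (ppm) per canonical residue. The acACS descriptor reads sequences
#' through these per-residue values.
#'
#' `shift_scale()` builds one from a residue-by-atom matrix;
#' `read_shift_scale()` parses the packaged TSV format (`#provenance:` comment
#' lines, then a `residue<TAB>HA<TAB>HN<TAB>N15<TAB>CA13` header and 20 data
#' rows); `default_shift_scale()` loads the scale shipped with the package —
#' a synthetic stand-in of approximate random-coil-style average shifts, fully
#' user-overridable.
#'
#' @param values numeric matrix, rownames the 20 canonical residues, colnames
#'   a subset of `HA`, `HN`, `N15`, `CA13`.
#' @param provenance free-text source note.
#' @return An object of class `shift_scale`: list with `values` (matrix,
#'   atoms ordered HA, HN, N15, CA13), `provenance`, `standardized` flag.
#' @export
shift_scale <- function(values, provenance = "user-supplied") {
  values <- as.matrix(values)
  if (!setequal(rownames(values), AA_ALPHABET))
    stopf("scale must cover exactly the 20 canonical residues")
  atoms <- colnames(values)
  if (is.null(atoms) || !all(atoms %in% ATOM_ORDER) || length(atoms) == 0)
    stopf("scale atoms must be a non-empty subset of %s",
          paste(ATOM_ORDER, collapse = ", "))
  values <- values[AA_ALPHABET, ATOM_ORDER[ATOM_ORDER %in% atoms], drop = FALSE]
  storage.mode(values) <- "double"
  if (!all(is.finite(values)))
    stopf("scale contains non-finite values")
  out <- list(values = values, provenance = provenance, standardized = FALSE)
  class(out) <- "shift_scale"
  out
}

#' @export
print.shift_scale <- function(x, ...) {
  cat(sprintf("shift_scale: atoms %s%s\n  provenance: %s\n",
              paste(colnames(x$values), collapse = ", "),
              if (x$standardized) " (standardized)" else "",
              x$provenance))
  invisible(x)
}

#' @rdname shift_scale
#' @param path TSV file path.
#' @export
read_shift_scale <- function(path) {
  if (!file.exists(path)) stopf("scale file not found: '%s'", path)
  lines <- readLines(path)
  prov <- sub("^#provenance:\\s*", "", grep("^#provenance:", lines, value = TRUE))
  if (length(prov) == 0) prov <- "unspecified"
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.table(text = body, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "residue")
    stopf("scale TSV must have 'residue' as its first column")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$residue
  shift_scale(m, provenance = paste(prov, collapse = "; "))
}

#' @rdname shift_scale
#' @export
default_shift_scale <- function() {
  read_shift_scale(system.file("extdata", "chemical_shift_scale_synthetic.tsv",
                               package = "acpep", mustWork = TRUE))
}

#' Standardize a chemical-shift scale
#'
#' Per atom, replaces the 20 residue values v by (v - mean)/sd so that every
#' atom contributes on a common dimensionless footing to acACS. Idempotent up
#' to floating-point error; errors on a zero-variance atom.
#'
#' @param scale a [shift_scale()].
#' @return The standardized `shift_scale` (flagged, provenance annotated).
#' @export
standardize_scale <- function(scale) {
  stopifnot(inherits(scale, "shift_scale"))
  v <- scale$values
  for (a in colnames(v)) {
    s <- stats::sd(v[, a])
    if (s < .Machine$double.eps^0.5)
      stopf("atom %s has zero variance across residues; cannot standardize", a)
    v[, a] <- (v[, a] - mean(v[, a])) / s
  }
  out <- scale
  out$values <- v
  if (!out$standardized)
    out$provenance <- paste0(out$provenance, " [standardized]")
  out$standardized <- TRUE
  out
}

#' Per-position chemical-shift profile of a sequence
#'
#' Reads a sequence through a (standardized) scale for one atom, giving the
#' numeric series the acACS correlation factors are computed on. A raw scale
#' is standardized on the fly.
#'
#' @param sequence single peptide sequence.
#' @param scale a [shift_scale()].
#' @param atom one of `"HA"`, `"HN"`, `"N15"`, `"CA13"`, present in `scale`.
#' @return numeric vector of length `nchar(sequence)`.
#' @export
shift_profile <- function(sequence, scale, atom) {
  stopifnot(inherits(scale, "shift_scale"), length(sequence) == 1)
  if (!atom %in% colnames(scale$values))
    stopf("atom '%s' not present in scale (has: %s)", atom,
          paste(colnames(scale$values), collapse = ", "))
  if (!scale$standardized) scale <- standardize_scale(scale)
  res <- strsplit(toupper(sequence), "")[[1]]
  if (!all(res %in% AA_ALPHABET))
    stopf("sequence contains a residue outside the canonical alphabet")
  unname(scale$values[res, atom])
}
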