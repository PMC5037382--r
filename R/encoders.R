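#' Amino-acid composition (AAC)
#'
#' The 20-component vector of per-residue occurrence frequencies
#' f_i = n_i / L, residues in fixed alphabetical order
#' `ACDEFGHIKLMNPQRSTVWY`. Each row sums to 1.
#'
#' @param sequence character vector of peptide sequences (length >= 1 each).
#' @return numeric matrix, one row per sequence, 20 columns named by residue.
#' @examples
#' encode_aac("GLFG")  # G 0.5, L 0.25, F 0.25
#' @export
encode_aac <- function(sequence) {
  sequence <- toupper(as.character(sequence))
  if (any(nchar(sequence) < 1)) stopf("cannot encode an empty sequence")
  out <- t(vapply(sequence, function(s) {
    res <- strsplit(s, "")[[1]]
    if (!all(res %in% AA_ALPHABET))
      stopf("sequence contains a residue outside the canonical alphabet")
    tab <- table(factor(res, levels = AA_ALPHABET))
    as.numeric(tab) / length(res)
  }, numeric(20), USE.NAMES = FALSE))
  colnames(out) <- AA_ALPHABET
  out
}

RAAC_PAIRS <- as.vector(t(outer(1:6, 1:6, function(i, j) paste0(i, "-", j))))

#' Reduced-alphabet dipeptide composition (RAAC)
#'
#' Counts the 36 ordered dipeptides of the six-group hydropathy alphabet over
#' the L-1 overlapping windows of width 2, ordered row-major by group pair
#' (1-1, 1-2, ..., 6-6). The literal normalization divides counts by the
#' sequence length L (`"L"`, so components sum to (L-1)/L); `"L1"` divides by
#' L-1 so they sum to 1.
#'
#' @param sequence character vector of peptide sequences, each of length >= 2.
#' @param alphabet a [raac_alphabet()].
#' @param normalization `"L"` (default, divide by L) or `"L1"` (divide by L-1).
#' @return numeric matrix, one row per sequence, 36 columns named `"i-j"`.
#' @examples
#' encode_raac("RLRL", normalization = "L1")  # 1-2: 2/3, 2-1: 1/3
#' @export
encode_raac <- function(sequence, alphabet = raac_alphabet(),
                        normalization = c("L", "L1")) {
  normalization <- match.arg(normalization)
  sequence <- toupper(as.character(sequence))
  if (any(nchar(sequence) < 2))
    stopf("RAAC needs sequence length >= 2 (got length %d)",
          min(nchar(sequence)))
  reduced <- reduce_sequence(sequence, alphabet)
  out <- t(vapply(reduced, function(r) {
    g <- as.integer(strsplit(r, "")[[1]])
    L <- length(g)
    pair <- paste0(g[-L], "-", g[-1])
    counts <- table(factor(pair, levels = RAAC_PAIRS))
    den <- if (normalization == "L") L else L - 1
    as.numeric(counts) / den
  }, numeric(36), USE.NAMES = FALSE))
  colnames(out) <- RAAC_PAIRS
  out
}

#' acACS correlation factor at one lag
#'
#' For a per-position shift series s and lag d, the correlation factor is the
#' mean squared lagged difference
#' theta(d) = (1/(L-d)) * sum_p (s_p - s_(p+d))^2 (`form = "sqdiff"`, the
#' default), or the centered lagged autocovariance
#' (1/(L-d)) * sum_p (s_p - mean(s)) * (s_(p+d) - mean(s))
#' (`form = "autocov"`). Both vanish on a constant profile.
#'
#' @param series numeric vector (a [shift_profile()]).
#' @param lag integer lag d >= 1; requires `length(series) >= lag + 1`.
#' @param form functional form, `"sqdiff"` or `"autocov"`.
#' @return scalar correlation factor.
#' @export
acacs_theta <- function(series, lag, form = c("sqdiff", "autocov")) {
  form <- match.arg(form)
  L <- length(series)
  lag <- as.integer(lag)
  if (lag < 1) stopf("lag must be >= 1")
  if (L <= lag) stopf("sequence shorter than lag+1 (L = %d, lag = %d)", L, lag)
  a <- series[seq_len(L - lag)]
  b <- series[seq_len(L - lag) + lag]
  if (form == "sqdiff") mean((a - b)^2)
  else mean((a - mean(series)) * (b - mean(series)))
}

#' Auto-covariance of average chemical shifts (acACS)
#'
#' Encodes each sequence as the concatenation, over the selected atoms (fixed
#' order HA, HN, N15, CA13) and lags d = 1..lambda, of the correlation factors
#' of its standardized chemical-shift profiles, giving |atoms| * lambda
#' features. Default lambda = 5, the value at which jackknife accuracy peaks
#' for this descriptor family; the atom set defaults to all four.
#'
#' @param sequence character vector of peptide sequences, each of length
#'   >= `lambda + 1`.
#' @param scale a [shift_scale()]; standardized on the fly if raw.
#' @param lambda maximum lag (>= 1).
#' @param atoms non-empty subset of the scale's atoms.
#' @param form passed to [acacs_theta()].
#' @return numeric matrix, one row per sequence, columns named
#'   `"<atom>:d<lag>"`.
#' @export
encode_acacs <- function(sequence, scale = default_shift_scale(), lambda = 5L,
                         atoms = colnames(scale$values),
                         form = c("sqdiff", "autocov")) {
  form <- match.arg(form)
  stopifnot(inherits(scale, "shift_scale"))
  lambda <- as.integer(lambda)
  if (lambda < 1) stopf("lambda must be >= 1")
  if (length(atoms) == 0) stopf("atom set must be non-empty")
  if (!all(atoms %in% colnames(scale$values)))
    stopf("atom '%s' not present in scale", setdiff(atoms, colnames(scale$values))[1])
  atoms <- ATOM_ORDER[ATOM_ORDER %in% atoms]
  sequence <- toupper(as.character(sequence))
  short <- nchar(sequence) <= lambda
  if (any(short))
    stopf("sequence of length %d too short for lambda = %d (need L >= lambda + 1)",
          nchar(sequence[short][1]), lambda)
  if (!scale$standardized) scale <- standardize_scale(scale)
  cn <- as.vector(t(outer(atoms, seq_len(lambda),
                          function(a, d) paste0(a, ":d", d))))
  out <- t(vapply(sequence, function(s) {
    unlist(lapply(atoms, function(a) {
      prof <- shift_profile(s, scale, a)
      vapply(seq_len(lambda), function(d) acacs_theta(prof, d, form), numeric(1))
    }))
  }, numeric(length(atoms) * lambda), USE.NAMES = FALSE))
  colnames(out) <- cn
  out
}

#' Encode a peptide set as a feature matrix
#'
#' Concatenates the selected encoders column-wise in the order given by
#' `parts`, one row per record. Feature names are prefixed by encoder
#' (`aac:G`, `raac:1-2`, `acacs:N15:d3`) so column identity is reproducible
#' across runs; encoder parameters are recorded in the `"meta"` attribute.
#'
#' @param x a [peptide_set()].
#' @param parts ordered subset of `"aac"`, `"raac"`, `"acacs"`.
#' @param alphabet a [raac_alphabet()] (RAAC part).
#' @param normalization RAAC normalization, `"L"` or `"L1"`.
#' @param scale a [shift_scale()] (acACS part).
#' @param lambda,atoms,form acACS parameters, see [encode_acacs()].
#' @return An `acp_features` numeric matrix (rownames = record ids) with a
#'   `"meta"` attribute listing the encoders and their parameters.
#' @export
encode_features <- function(x, parts = c("aac", "raac", "acacs"),
                            alphabet = raac_alphabet(),
                            normalization = "L",
                            scale = default_shift_scale(),
                            lambda = 5L, atoms = colnames(scale$values),
                            form = "sqdiff") {
  stopifnot(inherits(x, "peptide_set"))
  if (nrow(x) == 0) stopf("cannot encode an empty peptide_set")
  parts <- match.arg(tolower(parts), c("aac", "raac", "acacs"), several.ok = TRUE)
  if (anyDuplicated(parts)) stopf("duplicated encoder in parts")
  blocks <- lapply(parts, function(p) {
    enc <- switch(p,
      aac = function() encode_aac(x$sequence),
      raac = function() encode_raac(x$sequence, alphabet, normalization),
      acacs = function() encode_acacs(x$sequence, scale, lambda, atoms, form))
    b <- tryCatch(enc(), error = function(e) {
      # re-run record-wise to name the offender
      for (i in seq_len(nrow(x))) {
        ok <- tryCatch({
          switch(p,
            aac = encode_aac(x$sequence[i]),
            raac = encode_raac(x$sequence[i], alphabet, normalization),
            acacs = encode_acacs(x$sequence[i], scale, lambda, atoms, form))
          TRUE
        }, error = function(e2) FALSE)
        if (!ok) stopf("encoder '%s' failed on record '%s': %s",
                       p, x$id[i], conditionMessage(e))
      }
      stop(e)
    })
    colnames(b) <- paste0(p, ":", colnames(b))
    b
  })
  m <- do.call(cbind, blocks)
  rownames(m) <- x$id
  atoms_used <- ATOM_ORDER[ATOM_ORDER %in% atoms]
  attr(m, "meta") <- list(
    parts = parts,
    lambda = if ("acacs" %in% parts) as.integer(lambda) else NULL,
    atoms = if ("acacs" %in% parts) atoms_used else NULL,
    acacs_form = if ("acacs" %in% parts) form else NULL,
    raac_normalization = if ("raac" %in% parts) normalization else NULL)
  class(m) <- c("acp_features", class(m))
  m
}

#' @export
print.acp_features <- function(x, ...) {
  meta <- attr(x, "meta")
  cat(sprintf("acp_features: %d record(s) x %d feature(s) [%s]\n",
              nrow(x), ncol(x), paste(meta$parts, collapse = " + ")))
  invisible(x)
}

#' Write / read a feature matrix as TSV
#'
#' Plain TSV with an `id` first column followed by the feature columns in
#' their deterministic order.
#'
#' @param m feature matrix (from [encode_features()]).
#' @param path file path.
#' @return `path` (writer) or a plain numeric matrix with rownames (reader).
#' @export
write_features_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m), unclass(m)[, , drop = FALSE],
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features_tsv
#' @export
read_features_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
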