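# approximate vertebrate/UniProt-style background residue frequencies,
# renormalized; used only when background = "natural"
NATURAL_FREQS <- c(
  A = 0.0826, C = 0.0137, D = 0.0546, E = 0.0672, F = 0.0386,
  G = 0.0708, H = 0.0228, I = 0.0593, K = 0.0581, L = 0.0965,
  M = 0.0241, N = 0.0406, P = 0.0472, Q = 0.0393, R = 0.0553,
  S = 0.0660, T = 0.0535, V = 0.0687, W = 0.0110, Y = 0.0292)

#' Specification of a synthetic two-class peptide set
#'
#' The generator emulates the structure of ACP benchmark sets: two classes of
#' i.i.d.-residue peptides with lengths uniform on `length_range` (default
#' 12-50, the typical ACP length band). Negatives draw residues from a
#' background distribution; positives draw from the mixture
#' (1 - effect) * background + effect * uniform(enriched), i.e. a fraction
#' `effect` of probability mass is moved onto the enriched residue set. The
#' default enriched set {K, L, F, G} mirrors the cationic/hydrophobic
#' character of real anticancer peptides. `effect = 0` makes the classes
#' identically distributed.
#'
#' @param n_pos,n_neg class sizes.
#' @param length_range integer length bounds (min, max).
#' @param effect compositional divergence delta in [0, 1).
#' @param enriched residue subset enriched in the positive class.
#' @param background `"uniform"` (default; analytically tractable) or
#'   `"natural"` (approximate proteome frequencies).
#' @param seed integer seed; generation is fully deterministic given it.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_pos = 138L, n_neg = 206L,
                           length_range = c(12L, 50L), effect = 0,
                           enriched = c("K", "L", "F", "G"),
                           background = c("uniform", "natural"), seed = 1L) {
  background <- match.arg(background)
  if (n_pos < 1 || n_neg < 1) stopf("class sizes must be >= 1")
  length_range <- as.integer(length_range)
  if (length(length_range) != 2 || length_range[1] < 1 ||
      length_range[1] > length_range[2])
    stopf("length_range must be (min, max) with 1 <= min <= max")
  if (!is.finite(effect) || effect < 0 || effect >= 1)
    stopf("effect must lie in [0, 1)")
  enriched <- unique(toupper(enriched))
  if (length(enriched) == 0 || !all(enriched %in% AA_ALPHABET))
    stopf("enriched must be a non-empty subset of the canonical residues")
  out <- list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
              length_range = length_range, effect = effect,
              enriched = enriched, background = background,
              seed = as.integer(seed))
  class(out) <- "synthetic_spec"
  out
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(paste0("synthetic_spec: %d pos / %d neg, lengths %d-%d, ",
                     "effect %.2f on {%s}, %s background, seed %d\n"),
              x$n_pos, x$n_neg, x$length_range[1], x$length_range[2],
              x$effect, paste(x$enriched, collapse = ","), x$background,
              x$seed))
  invisible(x)
}

# class residue distributions implied by a spec
class_distributions <- function(spec) {
  bg <- if (spec$background == "uniform")
    stats::setNames(rep(1 / 20, 20), AA_ALPHABET)
  else NATURAL_FREQS[AA_ALPHABET] / sum(NATURAL_FREQS)
  pos <- (1 - spec$effect) * bg
  pos[spec$enriched] <- pos[spec$enriched] + spec$effect / length(spec$enriched)
  list(positive = pos, negative = bg)
}

#' Simulate a labelled two-class peptide set
#'
#' @param spec a [synthetic_spec()].
#' @return A [peptide_set()] with ids `pos_0001`, ..., `neg_0001`, ... and
#'   labels set; byte-identical across runs with the same spec.
#' @examples
#' simulate_peptides(synthetic_spec(n_pos = 5, n_neg = 5, seed = 7))
#' @export
simulate_peptides <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dists <- class_distributions(spec)
  with_seed(spec$seed, {
    draw <- function(n, prefix, prob) {
      lens <- sample(seq(spec$length_range[1], spec$length_range[2]), n,
                     replace = TRUE)
      seqs <- vapply(lens, function(L)
        paste(sample(AA_ALPHABET, L, replace = TRUE, prob = prob),
              collapse = ""), character(1))
      list(id = sprintf("%s_%04d", prefix, seq_len(n)), sequence = seqs)
    }
    pos <- draw(spec$n_pos, "pos", dists$positive)
    neg <- draw(spec$n_neg, "neg", dists$negative)
  })
  peptide_set(c(pos$id, neg$id), c(pos$sequence, neg$sequence),
              c(rep("positive", spec$n_pos), rep("negative", spec$n_neg)))
}

#' Serialize / restore a synthetic spec (JSON)
#'
#' Round-trip provenance for generated datasets.
#'
#' @param spec a [synthetic_spec()].
#' @param path JSON file path.
#' @return `path` (writer) or the restored `synthetic_spec` (reader).
#' @export
write_spec_json <- function(spec, path) {
  stopifnot(inherits(spec, "synthetic_spec"))
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_spec_json
#' @export
read_spec_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  synthetic_spec(n_pos = x$n_pos, n_neg = x$n_neg,
                 length_range = x$length_range, effect = x$effect,
                 enriched = x$enriched, background = x$background,
                 seed = x$seed)
}
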