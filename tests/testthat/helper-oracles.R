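# Independent brute-force oracles and small fixtures shared across tests.
# The oracles deliberately avoid the package's own code paths.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# position-by-position residue counting, no table()/factor machinery
brute_aac <- function(seq) {
  res <- strsplit(seq, "")[[1]]
  out <- setNames(numeric(20), AA20)
  for (r in res) out[r] <- out[r] + 1
  out / length(res)
}

# overlapping dipeptide tally over the reduced alphabet
brute_raac <- function(seq, den = c("L", "L1")) {
  den <- match.arg(den)
  map <- c(R = 1, D = 1, E = 1, N = 1, Q = 1, K = 1, H = 1,
           L = 2, I = 2, V = 2, A = 2, M = 2, F = 2,
           S = 3, T = 3, Y = 3, W = 3, P = 4, G = 5, C = 6)
  g <- map[strsplit(seq, "")[[1]]]
  L <- length(g)
  out <- setNames(numeric(36),
                  as.vector(t(outer(1:6, 1:6, function(i, j) paste0(i, "-", j)))))
  for (p in seq_len(L - 1)) {
    key <- paste0(g[p], "-", g[p + 1])
    out[key] <- out[key] + 1
  }
  out / if (den == "L") L else L - 1
}

# lagged mean squared difference, written as an explicit position loop
brute_theta <- function(series, d) {
  L <- length(series)
  acc <- 0
  for (p in seq_len(L - d)) acc <- acc + (series[p] - series[p + d])^2
  acc / (L - d)
}

# toy chemical-shift scale with hand-picked distinct values
toy_scale <- function(atoms = c("HA", "N15")) {
  m <- cbind(HA = seq(1, 20, length.out = 20)^1.3,
             HN = c(seq(5, 14.5, by = 0.5)),
             N15 = c(101:110, 121:130),
             CA13 = 3 * (1:20) + c(rep(0, 10), rep(7, 10)))
  rownames(m) <- AA20
  shift_scale(m[, atoms, drop = FALSE], provenance = "toy test scale")
}

random_peptides <- function(n, lmin = 5, lmax = 30) {
  vapply(sample(lmin:lmax, n, replace = TRUE), function(L)
    paste(sample(AA20, L, replace = TRUE), collapse = ""), character(1))
}

# two well-separated gaussian feature blobs for classifier tests
blob_data <- function(n_per = 20, sep = 4, p = 3, sd = 0.7) {
  X <- rbind(matrix(rnorm(n_per * p, 0, sd), n_per),
             matrix(rnorm(n_per * p, sep, sd), n_per))
  colnames(X) <- paste0("f", seq_len(p))
  rownames(X) <- sprintf("r%03d", seq_len(2 * n_per))
  list(x = X, labels = rep(c("negative", "positive"), each = n_per))
}

write_tmp_fasta <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}
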