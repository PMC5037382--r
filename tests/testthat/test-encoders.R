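test_that("AAC frequencies match direct hand counts", {
  expect_equal(unname(encode_aac("AAAA")[1, "A"]), 1)
  expect_equal(sum(encode_aac("AAAA")[1, ] > 0), 1)
  expect_equal(unname(encode_aac(paste(AA20, collapse = ""))[1, ]),
               rep(0.05, 20))
  v <- encode_aac("GLFG")[1, ]
  expect_equal(unname(v[c("G", "L", "F")]), c(0.5, 0.25, 0.25))
  expect_equal(sum(v), 1)
  expect_error(encode_aac(""), "empty")
})

test_that("AAC agrees with a brute-force counter and is permutation invariant", {
  set.seed(101)
  seqs <- random_peptides(200)
  enc <- encode_aac(seqs)
  expect_true(all(abs(rowSums(enc) - 1) < 1e-12))
  for (i in seq_along(seqs))
    expect_equal(enc[i, ], brute_aac(seqs[i]))
  shuffled <- vapply(strsplit(seqs, ""), function(r)
    paste(sample(r), collapse = ""), character(1))
  expect_equal(encode_aac(shuffled), enc, ignore_attr = TRUE)
})

test_that("the default reduced alphabet reproduces the hydropathy groups", {
  expect_equal(reduce_sequence("RDENQKH"), "1111111")
  expect_equal(reduce_sequence("LIVAMF"), "222222")
  expect_equal(reduce_sequence("STYW"), "3333")
  expect_equal(reduce_sequence("PGC"), "456")
  expect_equal(nchar(reduce_sequence("GLFDIVKKWWKK")), 12)
  # a partition must cover all 20 residues exactly
  expect_error(raac_alphabet(list("A", "C", "D", "E", "F", "G")), "partition")
})

test_that("RAAC dipeptide frequencies follow the chosen normalization", {
  expect_equal(unname(encode_raac("RK")[1, "1-1"]), 0.5)
  expect_equal(sum(encode_raac("RK")), 0.5)
  expect_equal(unname(encode_raac("RK", normalization = "L1")[1, "1-1"]), 1)
  v <- encode_raac("RLRL", normalization = "L1")[1, ]
  expect_equal(unname(v[c("1-2", "2-1")]), c(2 / 3, 1 / 3))
  expect_error(encode_raac("R"), "length >= 2")

  set.seed(102)
  seqs <- random_peptides(120)
  encL <- encode_raac(seqs)
  encL1 <- encode_raac(seqs, normalization = "L1")
  L <- nchar(seqs)
  expect_equal(ncol(encL), 36)
  expect_equal(unname(rowSums(encL)), (L - 1) / L)
  expect_true(all(abs(rowSums(encL1) - 1) < 1e-12))
  for (i in seq_along(seqs)) {
    expect_equal(encL[i, ], brute_raac(seqs[i], "L"))
    expect_equal(encL1[i, ], brute_raac(seqs[i], "L1"))
  }
})

test_that("RAAC is order sensitive where AAC is not", {
  a <- "RLRLRL"
  b <- "RRRLLL"   # same composition, different adjacencies
  expect_equal(encode_aac(a), encode_aac(b), ignore_attr = TRUE)
  expect_false(isTRUE(all.equal(encode_raac(a), encode_raac(b),
                                check.attributes = FALSE)))
})

test_that("scale standardization centers, scales and is idempotent", {
  sc <- standardize_scale(toy_scale(c("HA", "HN", "N15", "CA13")))
  for (a in colnames(sc$values)) {
    expect_equal(mean(sc$values[, a]), 0, tolerance = 1e-9)
    expect_equal(sd(sc$values[, a]), 1, tolerance = 1e-9)
  }
  twice <- standardize_scale(sc)
  expect_equal(twice$values, sc$values, tolerance = 1e-12)

  flat <- toy_scale("HA")
  flat$values[, "HA"] <- 7
  expect_error(standardize_scale(flat), "zero variance")
})

test_that("shift profiles look residues up in order", {
  sc <- standardize_scale(toy_scale("N15"))
  expect_equal(shift_profile("AAAAAA", sc, "N15"),
               rep(sc$values["A", "N15"], 6))
  expect_equal(shift_profile("GK", sc, "N15"),
               unname(sc$values[c("G", "K"), "N15"]))
  set.seed(103)
  s <- random_peptides(1)
  expect_length(shift_profile(s, sc, "N15"), nchar(s))
  expect_error(shift_profile("GK", sc, "CA13"), "not present")
})

test_that("acACS correlation factors match brute force and behave at lags", {
  expect_equal(acacs_theta(rep(2.5, 8), 3), 0)
  expect_equal(acacs_theta(c(0, 1, 0, 1), 1), 1)
  expect_equal(acacs_theta(c(0, 1, 0, 1), 2), 0)
  expect_error(acacs_theta(c(1, 2), 2), "shorter than lag")

  set.seed(104)
  for (i in 1:25) {
    s <- rnorm(sample(4:30, 1))
    d <- sample(seq_len(length(s) - 1), 1)
    expect_equal(acacs_theta(s, d), brute_theta(s, d))
    # the squared-difference form is reversal invariant (same summands,
    # reversed accumulation order, so equality up to addition rounding)
    expect_equal(acacs_theta(s, d), acacs_theta(rev(s), d), tolerance = 1e-13)
  }
  # centered autocovariance alternative also vanishes on constants
  expect_equal(acacs_theta(rep(1.3, 9), 2, form = "autocov"), 0)
})

test_that("acACS encoding has the right geometry and values", {
  sc <- toy_scale(c("HA", "HN", "N15", "CA13"))
  m <- encode_acacs("GLFDIVKAAK", sc, lambda = 5)
  expect_equal(ncol(m), 20)
  expect_equal(colnames(m)[1:6], c(paste0("HA:d", 1:5), "HN:d1"))

  expect_true(all(encode_acacs(strrep("L", 12), sc, lambda = 5) == 0))

  # brute-force oracle on a toy scale, lambda = 2, single atom
  sc1 <- standardize_scale(toy_scale("N15"))
  prof <- unname(sc1$values[strsplit("GKGK", "")[[1]], "N15"])
  got <- encode_acacs("GKGK", sc1, lambda = 2, atoms = "N15")
  expect_equal(unname(got[1, ]), c(brute_theta(prof, 1), brute_theta(prof, 2)))

  expect_error(encode_acacs("GKG", sc, lambda = 5), "too short")
  expect_error(encode_acacs("GKGKGK", sc, lambda = 2, atoms = character(0)),
               "non-empty")
})

test_that("combined encoding concatenates blocks deterministically", {
  set.seed(105)
  d <- peptide_set(sprintf("s%02d", 1:8), random_peptides(8, 10, 30))
  sc <- toy_scale(c("HA", "HN", "N15", "CA13"))
  m <- encode_features(d, parts = c("aac", "raac", "acacs"), scale = sc,
                       lambda = 5)
  expect_equal(dim(m), c(8, 76))
  expect_equal(rownames(m), d$id)
  expect_true(all(grepl("^(aac|raac|acacs):", colnames(m))))
  expect_identical(attr(m, "meta")$lambda, 5L)

  aac_only <- encode_features(d, parts = "aac")
  expect_equal(unclass(aac_only)[, ], encode_aac(d$sequence),
               ignore_attr = TRUE)

  # reordering parts permutes blocks, not values
  m2 <- encode_features(d, parts = c("raac", "aac", "acacs"), scale = sc)
  expect_equal(m2[, colnames(m)], unclass(m)[, ], ignore_attr = TRUE)

  # repeated calls byte-identical
  expect_identical(m, encode_features(d, parts = c("aac", "raac", "acacs"),
                                      scale = sc, lambda = 5))

  # a record failing a sub-encoder is named
  short <- peptide_set(c("long1", "tiny"), c("GLFDIVKAAK", "GKG"))
  expect_error(encode_features(short, parts = "acacs", scale = sc, lambda = 5),
               "tiny")
})

test_that("feature TSV writer round-trips", {
  set.seed(106)
  d <- peptide_set(letters[1:5], random_peptides(5, 8, 20))
  m <- encode_features(d, parts = c("aac", "raac"))
  f <- tempfile(fileext = ".tsv")
  write_features_tsv(m, f)
  back <- read_features_tsv(f)
  expect_equal(back, unclass(m)[, ], ignore_attr = TRUE, tolerance = 1e-12)
  expect_identical(colnames(back), colnames(m))
})
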