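test_that("filter_hits applies the inclusive relative bit-score cut", {
  hits <- data.frame(qseqid = "q", sseqid = c("a", "b", "c"),
                     bitscore = c(100, 50, 39.9), qstart = 1L,
                     qseq = "M", sseq = "M", stringsAsFactors = FALSE)
  expect_equal(filter_hits(hits)$sseqid, c("a", "b"))
  hits$bitscore <- c(100, 40, 39.9)
  expect_equal(filter_hits(hits)$sseqid, c("a", "b"))  # boundary kept
  expect_equal(filter_hits(hits[1, ])$sseqid, "a")     # best always kept
  expect_equal(nrow(filter_hits(hits[0, ])), 0L)       # empty in, empty out
  expect_error(filter_hits(hits, 0), "fraction")
  expect_error(filter_hits(hits, 1.2), "fraction")
})

test_that("raising the bit-score fraction never enlarges the retained set", {
  set.seed(42)
  for (r in 1:20) {
    hits <- data.frame(qseqid = "q", sseqid = paste0("s", 1:30),
                       bitscore = round(runif(30, 10, 400), 1), qstart = 1L,
                       qseq = "M", sseq = "M", stringsAsFactors = FALSE)
    fracs <- sort(runif(5, 0.05, 1))
    kept <- lapply(fracs, function(f) filter_hits(hits, f)$sseqid)
    for (i in seq_len(length(kept) - 1))
      expect_true(all(kept[[i + 1]] %in% kept[[i]]))
  }
})

test_that("build_profile counts non-gap standard subject letters per query position", {
  query <- c("M", "K", "V")
  hits <- data.frame(qseqid = "q", sseqid = c("s1", "s2", "s3"),
                     bitscore = 100, qstart = 1L, qseq = "MKV",
                     sseq = c("MRV", "M-V", "MKX"),
                     stringsAsFactors = FALSE)
  prof <- build_profile(query, hits)
  expect_equal(unname(prof$counts["R", 2]), 1L)
  expect_equal(unname(prof$n_aligned[2]), 2L)   # gap excluded entirely
  expect_equal(unname(prof$n_aligned[3]), 2L)   # X subject letter excluded
  expect_equal(prof$n_hits, 3L)
  expect_equal(sum(prof$counts[, 1]), 3L)
})

test_that("build_profile honours qstart offsets and validates the aligned query", {
  query <- c("M", "K", "V", "L", "W")
  hits <- data.frame(qseqid = "q", sseqid = "s1", bitscore = 100,
                     qstart = 3L, qseq = "VLW", sseq = "ALW",
                     stringsAsFactors = FALSE)
  prof <- build_profile(query, hits)
  expect_equal(unname(prof$counts["A", 3]), 1L)
  expect_equal(unname(prof$n_aligned[1]), 0L)
  ## inconsistent aligned query letter
  hits$qseq <- "VAW"
  expect_error(build_profile(query, hits), "position 4")
  ## alignment running past the query end
  hits$qseq <- "VLWMM"; hits$sseq <- "ALWMM"
  expect_error(build_profile(query, hits), "past query length")
})

test_that("entropies match a brute-force multiset oracle on random columns", {
  set.seed(101)
  for (r in 1:1000) {
    n <- sample(1:40, 1)
    letters <- sample(AA20, n, replace = TRUE,
                      prob = rgamma(20, shape = runif(1, 0.05, 2)))
    prof <- profile_from_column(letters)
    expect_equal(entropy20(prof, 1), entropy_oracle(letters),
                 tolerance = 1e-12)
    expect_equal(entropy6(prof, 1), entropy_oracle(six_class_of(letters)),
                 tolerance = 1e-12)
  }
})

test_that("entropy bounds and closed-form columns hold exactly", {
  expect_equal(entropy20(profile_from_column(rep("L", 8)), 1), 0)
  expect_equal(entropy6(profile_from_column(c("V", "V", "V", "L")), 1), 0)
  expect_equal(entropy20(profile_from_column(AA20), 1), log(20))
  one_per_class <- c("A", "F", "S", "K", "D", "G")
  expect_equal(entropy6(profile_from_column(one_per_class), 1), log(6))
  expect_equal(entropy20(profile_from_column(c("V", "V", "L", "L")), 1),
               log(2), tolerance = 1e-12)
  ## class probabilities {0.75, 0.25}
  expect_equal(entropy6(profile_from_column(c("V", "A", "L", "S")), 1),
               -(0.75 * log(0.75) + 0.25 * log(0.25)), tolerance = 1e-12)
  ## no aligned residues -> missing
  prof <- build_profile(c("M", "K"), data.frame(
    qseqid = "q", sseqid = "s", bitscore = 1, qstart = 1L,
    qseq = "M", sseq = "M", stringsAsFactors = FALSE))
  expect_true(is.na(entropy20(prof, 2)))
  expect_true(is.na(entropy6(prof, 2)))
})

test_that("class-reduced entropy never exceeds the 20-state entropy", {
  set.seed(77)
  for (r in 1:200) {
    letters <- sample(AA20, sample(1:30, 1), replace = TRUE)
    prof <- profile_from_column(letters)
    e20 <- entropy20(prof, 1); e6 <- entropy6(prof, 1)
    expect_gte(e20, e6 - 1e-12)
    expect_gte(e6, 0)
  }
})

test_that("entropies are invariant to hit order and whole-set duplication", {
  set.seed(11)
  letters <- sample(AA20, 15, replace = TRUE)
  prof <- profile_from_column(letters)
  prof_perm <- profile_from_column(sample(letters))
  prof_dup <- profile_from_column(c(letters, letters))
  for (f in list(entropy20, entropy6, fshp, fsr)) {
    expect_equal(f(prof, 1), f(prof_perm, 1), tolerance = 1e-12)
    expect_equal(f(prof, 1), f(prof_dup, 1), tolerance = 1e-12)
  }
})

test_that("hydrophobic and small fractions follow their residue sets", {
  prof <- profile_from_column(c("V", "L", "A", "G"))
  expect_equal(fshp(prof, 1), 0.5)
  expect_equal(fsr(prof, 1), 0.5)
  expect_equal(fshp(profile_from_column(rep("W", 5)), 1), 1.0)
  expect_equal(fshp(profile_from_column(rep("G", 5)), 1), 0.0)
  expect_equal(fsr(profile_from_column(rep("A", 3)), 1), 1.0)
  expect_equal(fsr(profile_from_column(c("K", "R", "D")), 1), 0.0)
  ## complement property: fshp + (1 - fshp) == 1 by construction of counts
  set.seed(3)
  letters <- sample(AA20, 25, replace = TRUE)
  prof <- profile_from_column(letters)
  nonh <- mean(!(letters %in% c("V", "L", "I", "F", "Y", "M", "W")))
  expect_equal(fshp(prof, 1) + nonh, 1, tolerance = 1e-12)
})

test_that("homology status is decided by retained hit count with inclusive boundary", {
  mk <- function(n) list(n_hits = n)
  expect_equal(homology_status(mk(10L)), "optimum")
  expect_equal(homology_status(mk(9L)), "non_optimum")
  expect_equal(homology_status(mk(0L)), "non_optimum")
  expect_equal(homology_status(mk(9L), min_hits = 5), "optimum")
})
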