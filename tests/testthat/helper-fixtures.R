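# Shared builders for small in-code fixtures.

# A profile whose single alignment column is exactly `letters`
# (one subject sequence per letter, query residue `query`).
profile_from_column <- function(letters, query = "A") {
  hits <- data.frame(
    qseqid = "q", sseqid = paste0("s", seq_along(letters)),
    bitscore = 100, qstart = 1L, qseq = query, sseq = letters,
    stringsAsFactors = FALSE)
  build_profile(query, hits, chain_id = "q")
}

# Brute-force entropy of a multiset of class assignments: direct
# enumeration, independent of the profile/count code path.
entropy_oracle <- function(assignments) {
  tab <- table(assignments)
  p <- tab / sum(tab)
  -sum(p * log(p))
}

# Map one-letter codes to six-class names under the default scheme.
six_class_of <- function(letters) {
  sch <- aa_class_scheme()
  map <- rep(names(sch), lengths(sch))
  names(map) <- unlist(sch)
  unname(map[letters])
}

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Minimal residue record table with descriptors filled in.
make_records <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    chain_id = "synA", position = seq_len(n),
    aa = sample(AA20, n, replace = TRUE),
    aqn_prev = sample(AA20, n, replace = TRUE),
    aqn_next = sample(AA20, n, replace = TRUE),
    e20 = runif(n, 0, log(20)), e6 = runif(n, 0, log(6)),
    fshp = runif(n), fsr = runif(n), lgdp = runif(n),
    homology_status = "optimum",
    stringsAsFactors = FALSE)
}

# A small intercept-only design matrix (bypasses model_spec, which
# requires at least one descriptor).
intercept_design <- function(y) {
  structure(list(
    X = matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)")),
    y = as.integer(y), rows = seq_along(y), levels = list(),
    spec = model_spec("E6")), class = "design_matrix")
}
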