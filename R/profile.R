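#' Filter homolog hits by relative bit score
#'
#' Keeps hits whose bit score is at least \code{fraction} of the best bit
#' score among the hits (boundary inclusive), the standard relative cut that
#' retains only confidently homologous subjects.  Input order is preserved
#' and the best-scoring hit is always retained.
#'
#' @param hits Data frame of pairwise hits for one query
#'   (see [read_alignment_table()]).
#' @param fraction Relative bit-score cutoff in (0, 1]; default 0.4.
#' @return The retained subset of \code{hits}.
#' @examples
#' hits <- data.frame(qseqid = "q", sseqid = c("a", "b", "c"),
#'                    bitscore = c(100, 50, 39.9), qstart = 1,
#'                    qseq = "MKV", sseq = "MKV")
#' filter_hits(hits)$sseqid  # "a" "b"
#' @export
filter_hits <- function(hits, fraction = 0.4) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1)
    stop("fraction must be a single value in (0, 1]")
  if (nrow(hits) == 0L) return(hits)
  if (length(unique(hits$qseqid)) > 1L)
    stop("filter_hits expects hits for a single query; got ",
         length(unique(hits$qseqid)))
  hits[hits$bitscore >= fraction * max(hits$bitscore), , drop = FALSE]
}

#' Build a per-position residue-count profile from aligned hits
#'
#' Accumulates, for every query position, the counts of aligned (non-gap)
#' subject residues over the 20 standard amino-acid types.  Each hit
#' contributes at query positions where its aligned query string has a
#' non-gap character; gap characters and non-standard subject letters are
#' excluded from the counts (they enter neither numerator nor denominator of
#' any downstream descriptor).  The aligned query string must reproduce the
#' query sequence at its stated offset; positions where the query itself is
#' undefined (\code{X}) accept any aligned letter.
#'
#' @param query Character vector of one-letter codes for the query chain
#'   (one element of [read_fasta()] output).
#' @param hits Data frame of (already filtered) pairwise hits for this query.
#' @param chain_id Chain identifier stored with the profile.
#' @return An object of class \code{alignment_profile}: a list with
#'   \code{chain_id}, \code{counts} (20 x L integer matrix, rows named by
#'   amino-acid letter), \code{n_aligned} (per-position column sums) and
#'   \code{n_hits} (number of contributing subject sequences).
#' @export
build_profile <- function(query, hits, chain_id = "query") {
  check_aa(query, allow_x = TRUE, what = "query residue")
  L <- length(query)
  counts <- matrix(0L, nrow = 20L, ncol = L,
                   dimnames = list(AA_LETTERS, NULL))
  if (nrow(hits) > 0L) {
    for (i in seq_len(nrow(hits))) {
      qs <- strsplit(hits$qseq[i], "", fixed = TRUE)[[1]]
      ss <- strsplit(hits$sseq[i], "", fixed = TRUE)[[1]]
      if (length(qs) != length(ss))
        stop("hit ", hits$sseqid[i], ": aligned strings differ in length")
      qpos <- hits$qstart[i] - 1L + cumsum(qs != "-")
      nongap <- qs != "-"
      if (any(nongap) && max(qpos[nongap]) > L)
        stop("hit ", hits$sseqid[i], ": alignment extends past query length (",
             max(qpos[nongap]), " > ", L, ")")
      mism <- nongap & qs != query[qpos] & query[qpos] != "X"
      if (any(mism))
        stop("hit ", hits$sseqid[i], ": aligned query letter '",
             qs[which(mism)[1]], "' does not match query residue '",
             query[qpos[which(mism)[1]]], "' at position ",
             qpos[which(mism)[1]])
      use <- nongap & ss %in% AA_LETTERS
      if (any(use)) {
        ## each query position occurs at most once per hit, so matrix
        ## indexing cannot collide within one hit
        idx <- cbind(match(ss[use], AA_LETTERS), qpos[use])
        counts[idx] <- counts[idx] + 1L
      }
    }
  }
  structure(list(chain_id = chain_id, counts = counts,
                 n_aligned = colSums(counts), n_hits = nrow(hits)),
            class = "alignment_profile")
}

#' @export
print.alignment_profile <- function(x, ...) {
  cat("Alignment profile for chain", x$chain_id, "\n")
  cat("  positions:", ncol(x$counts), "  hits:", x$n_hits,
      "  mean aligned depth:", round(mean(x$n_aligned), 2), "\n")
  invisible(x)
}

## Column probabilities at position k; NULL if nothing aligned there.
profile_column_p <- function(profile, k) {
  ck <- profile$counts[, k]
  n <- sum(ck)
  if (n == 0L) return(NULL)
  ck / n
}

#' Shannon sequence entropy over 20 amino-acid types (E20)
#'
#' For alignment column \code{k}, computes
#' \eqn{s_k = -\sum_j P_{jk} \ln P_{jk}} over the 20 amino-acid types, where
#' \eqn{P_{jk}} is the frequency of type \eqn{j} among the \eqn{N_k} aligned
#' (non-gap) subject residues at position \eqn{k}, with the convention
#' \eqn{0 \ln 0 = 0}.  Entropies are in nats; the range is
#' \eqn{[0, \ln 20]}.  Positions with no aligned residues give \code{NA}.
#'
#' @param profile An \code{alignment_profile}.
#' @param k Query position (1-based); may be a vector.
#' @return Numeric vector of entropies (nats), \code{NA} where \eqn{N_k = 0}.
#' @export
entropy20 <- function(profile, k = seq_len(ncol(profile$counts))) {
  vapply(k, function(kk) {
    p <- profile_column_p(profile, kk)
    if (is.null(p)) return(NA_real_)
    p <- p[p > 0]
    -sum(p * log(p))
  }, numeric(1))
}

#' Shannon sequence entropy over six amino-acid classes (E6)
#'
#' As [entropy20()], but the per-type counts are first pooled into the six
#' physicochemical classes of \code{scheme}, so the entropy is taken over at
#' most six states and ranges over \eqn{[0, \ln 6]}.  Class-reduced entropy
#' is a more sensitive conservation measure for residue packing than the
#' 20-state form.
#'
#' @inheritParams entropy20
#' @param scheme An [aa_class_scheme()].
#' @return Numeric vector of entropies (nats), \code{NA} where \eqn{N_k = 0}.
#' @export
entropy6 <- function(profile, k = seq_len(ncol(profile$counts)),
                     scheme = aa_class_scheme()) {
  cls <- aa_class_of(scheme)[rownames(profile$counts)]
  vapply(k, function(kk) {
    ck <- profile$counts[, kk]
    n <- sum(ck)
    if (n == 0L) return(NA_real_)
    p <- tapply(ck, cls, sum) / n
    p <- p[p > 0]
    -sum(p * log(p))
  }, numeric(1))
}

#' Fraction of aligned residues that are strongly hydrophobic (FSHP)
#'
#' Fraction of the aligned subject residues at each position belonging to
#' the strongly hydrophobic set \code{V L I F Y M W}.
#'
#' @inheritParams entropy20
#' @return Numeric vector in \eqn{[0, 1]}, \code{NA} where \eqn{N_k = 0}.
#' @export
fshp <- function(profile, k = seq_len(ncol(profile$counts))) {
  hyd <- colSums(profile$counts[AA_STRONGLY_HYDROPHOBIC, , drop = FALSE])
  out <- hyd[k] / profile$n_aligned[k]
  out[profile$n_aligned[k] == 0L] <- NA_real_
  unname(out)
}

#' Fraction of aligned residues that are small (FSR)
#'
#' Fraction of the aligned subject residues at each position that are
#' glycine or alanine.
#'
#' @inheritParams entropy20
#' @return Numeric vector in \eqn{[0, 1]}, \code{NA} where \eqn{N_k = 0}.
#' @export
fsr <- function(profile, k = seq_len(ncol(profile$counts))) {
  small <- colSums(profile$counts[AA_SMALL, , drop = FALSE])
  out <- small[k] / profile$n_aligned[k]
  out[profile$n_aligned[k] == 0L] <- NA_real_
  unname(out)
}

#' Homology status of a query chain
#'
#' A chain has \emph{optimum homology} when at least \code{min_hits} subject
#' sequences survive the relative bit-score filter; only then are the
#' homology descriptors (E20, E6, FSHP, FSR) considered reliable.
#'
#' @param profile An \code{alignment_profile} built from filtered hits.
#' @param min_hits Minimum number of retained subject sequences; default 10.
#' @return \code{"optimum"} or \code{"non_optimum"}.
#' @export
homology_status <- function(profile, min_hits = 10L) {
  if (profile$n_hits >= min_hits) "optimum" else "non_optimum"
}
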