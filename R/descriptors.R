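#' Compute the full per-residue descriptor table
#'
#' For every chain: filters its homolog hits by relative bit score, builds
#' the alignment profile, computes the homology descriptors (E20, E6, FSHP,
#' FSR) and the chain's homology status, and adds the query-sequence
#' descriptors (residue identity and adjacent query neighbours).  Positions
#' with no aligned subject residues get missing homology descriptors even
#' inside an optimum-homology chain and are excluded from homology-model
#' fitting downstream.
#'
#' @param sequences Named list of chains from [read_fasta()].
#' @param hits Hit table from [read_alignment_table()] (all chains pooled;
#'   matched by \code{qseqid}).
#' @param bitscore_fraction Relative bit-score cutoff; default 0.4.
#' @param min_hits Minimum retained hits for optimum homology; default 10.
#' @param scheme Six-class scheme for E6; default [aa_class_scheme()].
#' @return A residue data frame with columns \code{chain_id},
#'   \code{position}, \code{aa}, \code{aqn_prev}, \code{aqn_next},
#'   \code{n_hits}, \code{n_aligned}, \code{e20}, \code{e6}, \code{fshp},
#'   \code{fsr}, \code{homology_status}.
#' @export
compute_descriptors <- function(sequences, hits,
                                bitscore_fraction = 0.4, min_hits = 10L,
                                scheme = aa_class_scheme()) {
  if (length(sequences) == 0L) stop("no chains supplied")
  out <- vector("list", length(sequences))
  for (i in seq_along(sequences)) {
    id <- names(sequences)[i]
    seq <- sequences[[i]]
    chain_hits <- hits[hits$qseqid == id, , drop = FALSE]
    kept <- filter_hits(chain_hits, bitscore_fraction)
    prof <- build_profile(seq, kept, chain_id = id)
    k <- seq_along(seq)
    aqn <- aqn_neighbors(seq, k)
    n0 <- prof$n_aligned == 0L
    if (any(!n0) && any(n0))
      message("chain ", id, ": ", sum(n0),
              " position(s) with no aligned residues; ",
              "homology descriptors left missing")
    out[[i]] <- data.frame(
      chain_id = id, position = k, aa = seq,
      aqn_prev = aqn$aqn_prev, aqn_next = aqn$aqn_next,
      n_hits = prof$n_hits, n_aligned = unname(prof$n_aligned),
      e20 = entropy20(prof, k), e6 = entropy6(prof, k, scheme),
      fshp = fshp(prof, k), fsr = fsr(prof, k),
      homology_status = homology_status(prof, min_hits),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
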