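#' Adjacent query neighbours (AQN) of a residue
#'
#' Returns the one-letter codes of the residues at positions \code{k - 1}
#' and \code{k + 1} of the query chain.  At a chain terminus the missing
#' neighbour is reported as the distinguished \code{"boundary"} level, which
#' becomes its own category in dummy coding.  An undefined (\code{X})
#' neighbour is reported as alanine: undefined residues are assumed to be
#' alanine for the purposes of adjacent-neighbour analysis only.
#'
#' @param seq Character vector of one-letter codes for the chain.
#' @param k Position (1-based); may be a vector.
#' @return A data frame with columns \code{aqn_prev} and \code{aqn_next}.
#' @examples
#' aqn_neighbors(c("M", "K", "V"), 2)   # M, V
#' aqn_neighbors(c("M", "K", "V"), 1)   # boundary, K
#' @export
aqn_neighbors <- function(seq, k) {
  L <- length(seq)
  if (any(k < 1L | k > L)) stop("position out of range 1..", L)
  pick <- function(pos) {
    out <- rep(AQN_BOUNDARY, length(pos))
    inside <- pos >= 1L & pos <= L
    v <- seq[pos[inside]]
    v[v == "X"] <- "A"
    out[inside] <- v
    out
  }
  data.frame(aqn_prev = pick(k - 1L), aqn_next = pick(k + 1L),
             stringsAsFactors = FALSE)
}

#' Attach disorder propensities (LGDP) to residue records
#'
#' Merges an externally computed per-residue intrinsic-disorder propensity
#' (Lobanov-Galzitskaya disorder probability) into the record table, keyed
#' by chain id and position.  Records with no LGDP entry keep a missing
#' value and remain usable for models that do not include LGDP.
#'
#' @param records Residue data frame with \code{chain_id} and
#'   \code{position}.
#' @param lgdp_table Data frame with columns \code{chain_id},
#'   \code{position}, \code{lgdp}; values must lie in \eqn{[0, 1]}.
#' @return \code{records} with an \code{lgdp} column filled where matched.
#' @export
attach_lgdp <- function(records, lgdp_table) {
  need <- c("chain_id", "position", "lgdp")
  if (!all(need %in% names(lgdp_table)))
    stop("lgdp_table must have columns chain_id, position, lgdp")
  bad <- !is.na(lgdp_table$lgdp) &
    (lgdp_table$lgdp < 0 | lgdp_table$lgdp > 1)
  if (any(bad))
    stop("LGDP value(s) outside [0, 1]: ",
         paste(utils::head(lgdp_table$lgdp[bad], 5), collapse = ", "))
  key_r <- paste(records$chain_id, records$position, sep = "\r")
  key_l <- paste(lgdp_table$chain_id, lgdp_table$position, sep = "\r")
  if (anyDuplicated(key_l))
    stop("duplicate (chain_id, position) entries in lgdp_table")
  records$lgdp <- lgdp_table$lgdp[match(key_r, key_l)]
  covered <- mean(!is.na(records$lgdp))
  message(sprintf("LGDP coverage: %.1f%% of %d residues",
                  100 * covered, nrow(records)))
  records
}

#' Drop records whose own residue is undefined
#'
#' Records whose query residue is \code{X} cannot be dummy-coded on the AA
#' factor and are removed from fitting and evaluation (their neighbours were
#' already resolved to alanine by [aqn_neighbors()]).  The number removed is
#' reported.
#'
#' @param records Residue data frame with an \code{aa} column.
#' @return \code{records} without \code{aa == "X"} rows.
#' @export
resolve_query_x <- function(records) {
  drop <- records$aa == "X"
  if (any(drop))
    message("dropping ", sum(drop), " residue(s) with undefined (X) identity")
  records[!drop, , drop = FALSE]
}
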