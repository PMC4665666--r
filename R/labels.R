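#' Binarize relative solvent accessibility into buried/exposed labels
#'
#' A residue with RSA strictly below the threshold is buried (0); a residue
#' at or above it is accessible (1).  The conventional threshold is 20\%
#' relative exposure, with 25\% a commonly explored alternative.
#'
#' @param rsa Numeric vector of relative accessibilities (percent, >= 0).
#' @param threshold Threshold in percent (default 20).
#' @return Integer vector of labels in \{0, 1\} (NA where \code{rsa} is NA).
#' @examples
#' binarize_rsa(c(19.9, 20, 42))  # 0 1 1
#' @export
binarize_rsa <- function(rsa, threshold = 20) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop("threshold must be a single positive value")
  if (any(rsa < 0, na.rm = TRUE)) stop("negative RSA value")
  as.integer(rsa >= threshold)
}

#' Flag likely interfacial residues from paired accessibilities
#'
#' A residue whose accessibility computed on the isolated chain exceeds its
#' accessibility in the complex (biological-unit) context by more than
#' \code{min_delta} is buried by a partner chain and flagged as likely
#' interfacial.
#'
#' @param single_chain RSA table (data frame with \code{position},
#'   \code{rsa}) computed on the isolated chain.
#' @param complex_ctx RSA table computed in the complex context.
#' @param min_delta Minimal increase (percentage points) counted as
#'   measurable; default 0, i.e. any positive change.
#' @return Integer vector of flagged positions.
#' @export
flag_interfacial <- function(single_chain, complex_ctx, min_delta = 0) {
  common <- intersect(single_chain$position, complex_ctx$position)
  if (length(common) == 0L)
    stop("single-chain and complex RSA tables share no positions")
  s <- single_chain$rsa[match(common, single_chain$position)]
  x <- complex_ctx$rsa[match(common, complex_ctx$position)]
  sort(common[!is.na(s) & !is.na(x) & (s - x) > min_delta])
}

#' Label residue records from RSA tables
#'
#' Fills \code{rsa}, \code{label} and (when a complex-context table is
#' given) \code{rsa_complex} and \code{interfacial} columns of a residue
#' record table.  For oligomer chains with complex-context accessibilities
#' the gold-standard label is taken from the complex-context value, since
#' the biological unit defines the physically meaningful exposure;
#' interfacial flags come from the single-chain minus complex difference.
#' Records with no RSA entry keep a missing label and are excluded from
#' evaluation.
#'
#' @param records Residue data frame with \code{chain_id}, \code{position}.
#' @param rsa_single RSA table for the isolated chain(s) as returned by
#'   [read_naccess_rsa()] (or same-shaped data frame; may cover several
#'   chains).
#' @param rsa_complex Optional complex-context RSA table.
#' @param threshold RSA threshold in percent passed to [binarize_rsa()].
#' @param min_delta Passed to [flag_interfacial()].
#' @return \code{records} with label columns filled.
#' @export
label_records <- function(records, rsa_single, rsa_complex = NULL,
                          threshold = 20, min_delta = 0) {
  key <- function(df) paste(df$chain_id, df$position, sep = "\r")
  krec <- key(records)
  records$rsa <- rsa_single$rsa[match(krec, key(rsa_single))]
  if (!is.null(rsa_complex)) {
    records$rsa_complex <- rsa_complex$rsa[match(krec, key(rsa_complex))]
    records$interfacial <- !is.na(records$rsa) & !is.na(records$rsa_complex) &
      (records$rsa - records$rsa_complex) > min_delta
    effective <- ifelse(is.na(records$rsa_complex), records$rsa,
                        records$rsa_complex)
  } else {
    effective <- records$rsa
  }
  records$label <- binarize_rsa(effective, threshold)
  n_miss <- sum(is.na(records$label))
  if (n_miss > 0L)
    message(n_miss, " residue(s) lack RSA coverage; labels left missing")
  records
}
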