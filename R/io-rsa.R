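#' Read per-residue relative accessibilities from a NACCESS .rsa file
#'
#' Parses the \code{RES} records of a NACCESS \code{.rsa} output file and
#' extracts the all-atoms \emph{relative} accessibility (second numeric field
#' of each \code{RES} line, in percent).  Residues are keyed by sequential
#' 1-based position in file order; the author-assigned residue number and any
#' insertion code are kept as provenance.  Relative values slightly above
#' 100\% occur for extended residues and are accepted.
#'
#' @param path Path to a \code{.rsa} file.
#' @param context Either \code{"single_chain"} (chain isolated from its
#'   partners) or \code{"complex"} (chain in its biological unit).
#' @return A data frame with columns \code{chain_id}, \code{position}
#'   (sequential 1-based), \code{res_name}, \code{res_number} (string, with
#'   insertion code if present), \code{rsa} (percent) and \code{context}.
#' @export
read_naccess_rsa <- function(path, context = c("single_chain", "complex")) {
  context <- match.arg(context)
  if (!file.exists(path)) stop(".rsa file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  res <- grep("^RES ", lines, value = TRUE)
  if (length(res) == 0L)
    stop("no RES records in .rsa file: ", path)
  ## RES <name> <chain> <number[icode]> <abs all> <rel all> <abs side> ...
  fields <- strsplit(trimws(res), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 6L))
    stop("malformed RES line(s) in ", path, ": ",
         paste(which(nf < 6L)[seq_len(min(5L, sum(nf < 6L)))], collapse = ", "))
  m <- t(vapply(fields, function(f) f[1:6], character(6)))
  rel <- suppressWarnings(as.numeric(m[, 6]))
  if (anyNA(rel))
    stop("non-numeric relative-accessibility field in ", path, " at RES line(s): ",
         paste(which(is.na(rel))[seq_len(min(5L, sum(is.na(rel))))],
               collapse = ", "))
  if (any(rel < 0)) stop("negative relative accessibility in ", path)
  data.frame(chain_id = m[, 3], position = seq_along(rel),
             res_name = m[, 2], res_number = m[, 4],
             rsa = rel, context = context, stringsAsFactors = FALSE)
}

## Columns a residue CSV may carry, with their expected types.
RESIDUE_CSV_COLUMNS <- c(
  chain_id = "character", position = "integer", aa = "character",
  aqn_prev = "character", aqn_next = "character",
  n_hits = "integer", n_aligned = "integer",
  e20 = "numeric", e6 = "numeric", fshp = "numeric", fsr = "numeric",
  lgdp = "numeric", homology_status = "character",
  rsa = "numeric", rsa_complex = "numeric",
  oligomer = "logical", interfacial = "logical", label = "integer"
)

#' Read a per-residue descriptor table from CSV
#'
#' Reads a header-defined CSV carrying any subset of the residue-record
#' columns (\code{chain_id}, \code{position}, \code{aa}, descriptor, RSA,
#' label and flag columns).  Absent columns stay absent; empty fields and
#' \code{NA} become missing values, never zero.  Unknown column names are an
#' error so that typos do not silently drop a descriptor.
#'
#' @param path Path to a CSV file with a header row.
#' @return A data frame with validated column types.
#' @seealso [write_residue_csv()]
#' @export
read_residue_csv <- function(path) {
  if (!file.exists(path)) stop("residue CSV not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""), check.names = FALSE)
  unknown <- setdiff(names(df), names(RESIDUE_CSV_COLUMNS))
  if (length(unknown))
    stop("unknown residue CSV column(s): ", paste(unknown, collapse = ", "))
  if (!all(c("chain_id", "position") %in% names(df)))
    stop("residue CSV must carry at least chain_id and position columns")
  for (col in names(df)) {
    type <- RESIDUE_CSV_COLUMNS[[col]]
    v <- df[[col]]
    conv <- switch(type,
      character = as.character(v),
      numeric = {
        x <- suppressWarnings(as.numeric(v))
        if (any(is.na(x) & !is.na(v)))
          stop("non-numeric value in numeric column '", col, "'")
        x
      },
      integer = {
        x <- suppressWarnings(as.integer(v))
        if (any(is.na(x) & !is.na(v)))
          stop("non-integer value in column '", col, "'")
        x
      },
      logical = {
        if (is.logical(v)) v
        else {
          x <- toupper(as.character(v))
          out <- rep(NA, length(x))
          out[x %in% c("TRUE", "T", "1")] <- TRUE
          out[x %in% c("FALSE", "F", "0")] <- FALSE
          if (any(is.na(out) & !is.na(v)))
            stop("non-logical value in column '", col, "'")
          out
        }
      })
    df[[col]] <- conv
  }
  if (anyNA(df$position) || anyNA(df$chain_id))
    stop("chain_id and position must be complete in a residue CSV")
  df
}

#' Write a per-residue descriptor table to CSV
#'
#' @param records Residue data frame (any subset of the residue-record
#'   columns).
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_residue_csv <- function(records, path) {
  unknown <- setdiff(names(records), names(RESIDUE_CSV_COLUMNS))
  if (length(unknown))
    stop("unknown residue column(s): ", paste(unknown, collapse = ", "))
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}
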