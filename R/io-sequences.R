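#' Read query chain sequences from a FASTA file
#'
#' Reads protein chain sequences, uppercases them, and maps any letter outside
#' the 20 standard one-letter codes to \code{X} (undefined residue) with a
#' warning.  Record ids are taken from the first whitespace-delimited token of
#' each header.
#'
#' @param path Path to a FASTA file.
#' @return A named list of character vectors of one-letter residue codes, one
#'   element per record, named by chain id.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">1abcA", "MKVLW"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  recs <- tryCatch(
    seqinr::read.fasta(path, seqtype = "AA", as.string = FALSE,
                       forceDNAtolower = FALSE),
    error = function(e) stop("cannot parse FASTA file ", path, ": ",
                             conditionMessage(e))
  )
  if (length(recs) == 0L) stop("FASTA file has no records: ", path)
  ids <- vapply(recs, function(r) strsplit(attr(r, "name"), "\\s+")[[1]][1],
                character(1))
  if (anyDuplicated(ids))
    stop("duplicate FASTA record id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  out <- vector("list", length(recs))
  names(out) <- ids
  for (i in seq_along(recs)) {
    res <- toupper(as.character(recs[[i]]))
    if (length(res) == 0L)
      stop("zero-length FASTA record: ", ids[i])
    bad <- !(res %in% AA_LETTERS)
    if (any(bad)) {
      nonstd <- setdiff(unique(res[bad]), "X")
      if (length(nonstd))
        warning(sum(bad), " non-standard residue letter(s) in record '",
                ids[i], "' (", paste(nonstd, collapse = ", "),
                ") mapped to X", call. = FALSE)
      res[bad] <- "X"
    }
    out[[i]] <- res
  }
  out
}

#' Read a BLAST-style tabular alignment file
#'
#' Parses the alignment-input dialect used by the descriptor pipeline: a
#' tab-separated file with columns \code{qseqid, sseqid, bitscore, qstart,
#' qseq, sseq}, producible with a single BLASTp invocation
#' (\code{-outfmt "6 qseqid sseqid bitscore qstart qseq sseq"}).  \code{qseq}
#' and \code{sseq} are the gapped aligned query and subject strings (gap
#' character \code{-}).  A header line is tolerated and detected by a
#' non-numeric \code{bitscore} field.
#'
#' @param path Path to the tab-separated hit table.
#' @return A data frame of pairwise hits with columns \code{qseqid},
#'   \code{sseqid}, \code{bitscore} (numeric), \code{qstart} (integer),
#'   \code{qseq} and \code{sseq}.
#' @export
read_alignment_table <- function(path) {
  if (!file.exists(path)) stop("alignment table not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("[ \t\r]+$", "", lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(data.frame(qseqid = character(), sseqid = character(),
                      bitscore = numeric(), qstart = integer(),
                      qseq = character(), sseq = character(),
                      stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 6L))
    stop("ragged alignment table: line(s) ",
         paste(which(nf != 6L)[seq_len(min(5L, sum(nf != 6L)))],
               collapse = ", "),
         " do not have 6 tab-separated fields")
  m <- do.call(rbind, fields)
  ## optional header: non-numeric bitscore in the first row
  if (is.na(suppressWarnings(as.numeric(m[1, 3])))) {
    m <- m[-1, , drop = FALSE]
    if (nrow(m) == 0L)
      return(data.frame(qseqid = character(), sseqid = character(),
                        bitscore = numeric(), qstart = integer(),
                        qseq = character(), sseq = character(),
                        stringsAsFactors = FALSE))
  }
  bitscore <- suppressWarnings(as.numeric(m[, 3]))
  qstart <- suppressWarnings(as.integer(m[, 4]))
  if (anyNA(bitscore)) stop("non-numeric bitscore field in alignment table")
  if (anyNA(qstart) || any(qstart < 1L))
    stop("qstart must be a positive integer in alignment table")
  if (any(bitscore < 0)) stop("negative bit score in alignment table")
  qseq <- toupper(m[, 5]); sseq <- toupper(m[, 6])
  badlen <- nchar(qseq) != nchar(sseq)
  if (any(badlen))
    stop("aligned query/subject strings differ in length at line(s): ",
         paste(which(badlen)[seq_len(min(5L, sum(badlen)))], collapse = ", "))
  data.frame(qseqid = m[, 1], sseqid = m[, 2], bitscore = bitscore,
             qstart = qstart, qseq = qseq, sseq = sseq,
             stringsAsFactors = FALSE)
}
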