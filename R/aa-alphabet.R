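#' @keywords internal
"_PACKAGE"

## One-letter codes for the 20 standard amino acids, alphabetical.
AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## One-letter -> three-letter (reporting and NACCESS parsing).
AA_THREE <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
              Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
              L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
              S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

AA_ONE <- structure(names(AA_THREE), names = AA_THREE)

## Strongly hydrophobic set used by the FSHP descriptor.
AA_STRONGLY_HYDROPHOBIC <- c("V", "L", "I", "F", "Y", "M", "W")

## Small residues used by the FSR descriptor.
AA_SMALL <- c("G", "A")

## Level used for the neighbour of a terminal residue in AQN factors.
AQN_BOUNDARY <- "boundary"

#' Six-class amino-acid grouping for class-reduced entropy
#'
#' Builds (or validates) a partition of the 20 standard amino acids into six
#' disjoint, exhaustive physicochemical classes, used by [entropy6()].  The
#' default grouping follows the common reduced-alphabet convention:
#' aliphatic/hydrophobic \code{A V L I M C}, aromatic \code{F W Y H}, polar
#' \code{S T N Q}, basic \code{K R}, acidic \code{D E} and
#' conformationally special \code{G P}.
#'
#' @param classes Named list of six character vectors of one-letter codes
#'   partitioning the 20 standard amino acids.  Omit for the default scheme.
#' @param name Label stored with the scheme.
#' @return An object of class \code{aa_class_scheme}: a named list of six
#'   character vectors with a \code{name} attribute.
#' @examples
#' sch <- aa_class_scheme()
#' names(sch)
#' @export
aa_class_scheme <- function(classes = NULL, name = "default6") {
  if (is.null(classes)) {
    classes <- list(
      aliphatic = c("A", "V", "L", "I", "M", "C"),
      aromatic  = c("F", "W", "Y", "H"),
      polar     = c("S", "T", "N", "Q"),
      basic     = c("K", "R"),
      acidic    = c("D", "E"),
      special   = c("G", "P")
    )
  }
  if (length(classes) != 6L)
    stop("a class scheme must have exactly six classes, got ", length(classes))
  members <- unlist(classes, use.names = FALSE)
  if (anyDuplicated(members))
    stop("class scheme has overlapping classes: ",
         paste(unique(members[duplicated(members)]), collapse = ", "))
  if (!setequal(members, AA_LETTERS))
    stop("class scheme must partition the 20 standard amino acids; ",
         "missing: ", paste(setdiff(AA_LETTERS, members), collapse = ", "))
  if (is.null(names(classes)))
    names(classes) <- paste0("class", seq_along(classes))
  structure(classes, name = name, class = "aa_class_scheme")
}

## Membership lookup: one-letter code -> class name, for a given scheme.
aa_class_of <- function(scheme) {
  stopifnot(inherits(scheme, "aa_class_scheme"))
  map <- rep(names(scheme), lengths(scheme))
  names(map) <- unlist(scheme, use.names = FALSE)
  map
}

## Validate a vector of one-letter residue codes (optionally allowing X).
check_aa <- function(x, allow_x = FALSE, what = "residue") {
  ok <- AA_LETTERS
  if (allow_x) ok <- c(ok, "X")
  bad <- setdiff(unique(x), ok)
  if (length(bad))
    stop("invalid ", what, " code(s): ", paste(bad, collapse = ", "))
  invisible(x)
}
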