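## Descriptor names understood by model specs, and the record column or
## factor each maps to.
QUANT_DESCRIPTORS <- c(E20 = "e20", E6 = "e6", FSHP = "fshp", FSR = "fsr",
                       LGDP = "lgdp")
CAT_DESCRIPTORS <- c(AA = "aa", AQN_prev = "aqn_prev", AQN_next = "aqn_next")

#' Define a logistic model specification
#'
#' A model spec names the descriptors entering the linear predictor, the
#' baseline level of each categorical factor (valine by convention), the RSA
#' threshold the response labels were built with, and the probability cutoff
#' used for classification.  Three named models are provided:
#' \describe{
#'   \item{\code{"classic"}}{E20 + E6 + FSR + FSHP + AA, the saturated
#'     homology model.}
#'   \item{\code{"comprehensive"}}{E6 + FSR + FSHP + AA + LGDP + AQN, the
#'     best-performing mixed model.}
#'   \item{\code{"non_homology"}}{LGDP + AA + AQN, for chains whose homology
#'     descriptors are unreliable (non-optimum homology).}
#' }
#'
#' @param descriptors Character vector drawn from \code{E20, E6, FSHP, FSR,
#'   LGDP, AA, AQN_prev, AQN_next}, or one of the model names above.
#' @param baseline Baseline amino acid for treatment coding (one-letter);
#'   default valine.
#' @param rsa_threshold RSA threshold (percent) defining the response.
#' @param cutoff Classification probability cutoff; default 0.5.
#' @return An object of class \code{model_spec}.
#' @examples
#' model_spec("classic")
#' model_spec(c("E6", "AA"), rsa_threshold = 25)
#' @export
model_spec <- function(descriptors, baseline = "V", rsa_threshold = 20,
                       cutoff = 0.5) {
  named <- list(
    classic       = c("E20", "E6", "FSR", "FSHP", "AA"),
    comprehensive = c("E6", "FSR", "FSHP", "AA", "LGDP",
                      "AQN_prev", "AQN_next"),
    non_homology  = c("LGDP", "AA", "AQN_prev", "AQN_next")
  )
  name <- NULL
  if (length(descriptors) == 1L && descriptors %in% names(named)) {
    name <- descriptors
    descriptors <- named[[name]]
  }
  descriptors <- sub("^AQN$", "AQN_prev", descriptors)  # convenience alias
  known <- c(names(QUANT_DESCRIPTORS), names(CAT_DESCRIPTORS))
  bad <- setdiff(descriptors, known)
  if (length(bad))
    stop("unknown descriptor(s): ", paste(bad, collapse = ", "),
         "; known: ", paste(known, collapse = ", "))
  if (length(descriptors) == 0L) stop("at least one descriptor is required")
  check_aa(baseline)
  if (!is.numeric(cutoff) || cutoff <= 0 || cutoff >= 1)
    stop("cutoff must be in (0, 1)")
  structure(list(name = if (is.null(name)) "custom" else name,
                 descriptors = unique(descriptors), baseline = baseline,
                 rsa_threshold = rsa_threshold, cutoff = cutoff),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Logistic model spec '", x$name, "': ",
      paste(x$descriptors, collapse = " + "),
      " (baseline ", AA_THREE[[x$baseline]],
      ", RSA threshold ", x$rsa_threshold,
      "%, cutoff ", x$cutoff, ")\n", sep = "")
  invisible(x)
}

## Display level for a categorical value: three-letter code, or the
## boundary marker itself.
level_display <- function(v) {
  out <- AA_THREE[v]
  out[is.na(out)] <- v[is.na(out)]
  unname(out)
}
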