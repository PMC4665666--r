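#' Construct a logistic model from explicit coefficients
#'
#' Builds a \code{logistic_fit} object directly from a named coefficient
#' vector, without fitting — for encoding published coefficient tables or
#' for use as generative truth in simulations.  Coefficient names follow
#' the design-matrix convention: \code{"(Intercept)"}, quantitative
#' descriptor names (\code{"E6"}, ...), and \code{"FACTOR:LEVEL"} dummy
#' columns with three-letter residue levels (e.g. \code{"AA:LYS"},
#' \code{"AQN_prev:boundary"}).  Factor levels are inferred from the dummy
#' column names.
#'
#' @param coefficients Named numeric vector including \code{"(Intercept)"}.
#' @param se Optional named vector of standard errors (same names).
#' @param baseline Baseline residue (one-letter); default valine.
#' @param rsa_threshold,cutoff Stored thresholds.
#' @return A \code{logistic_fit} usable with [predict_proba()],
#'   [classify()] and [odds_ratio()].
#' @examples
#' m <- manual_model(c("(Intercept)" = -0.5, E6 = 0.9))
#' odds_ratio(m, "E6")
#' @export
manual_model <- function(coefficients, se = NULL, baseline = "V",
                         rsa_threshold = 20, cutoff = 0.5) {
  if (is.null(names(coefficients)) || !"(Intercept)" %in% names(coefficients))
    stop("coefficients must be named and include \"(Intercept)\"")
  nm <- names(coefficients)
  is_dummy <- grepl(":", nm, fixed = TRUE)
  quant <- setdiff(nm[!is_dummy], "(Intercept)")
  bad <- setdiff(quant, names(QUANT_DESCRIPTORS))
  if (length(bad))
    stop("unknown quantitative descriptor(s): ", paste(bad, collapse = ", "))
  factors <- unique(sub(":.*$", "", nm[is_dummy]))
  bad <- setdiff(factors, names(CAT_DESCRIPTORS))
  if (length(bad))
    stop("unknown categorical descriptor(s): ", paste(bad, collapse = ", "))
  levels <- lapply(factors, function(f) {
    disp <- sub("^[^:]*:", "", nm[is_dummy & startsWith(nm, paste0(f, ":"))])
    vals <- ifelse(disp %in% names(AA_ONE), AA_ONE[disp], disp)
    check_aa(setdiff(vals, AQN_BOUNDARY), what = paste0(f, " level"))
    unname(vals)
  })
  names(levels) <- factors
  spec <- model_spec(c(quant, factors), baseline = baseline,
                     rsa_threshold = rsa_threshold, cutoff = cutoff)
  if (is.null(se))
    se <- stats::setNames(rep(NA_real_, length(coefficients)), nm)
  z <- coefficients / se[nm]
  structure(list(coefficients = coefficients, se = se[nm], z = z,
                 p_value = 2 * stats::pnorm(-abs(z)),
                 odds_ratio = exp(coefficients),
                 loglik = NA_real_, n = NA_integer_,
                 n_accessible = NA_integer_,
                 converged = TRUE, diagnostics = character(),
                 levels = levels, spec = spec, fitted = NULL),
            class = "logistic_fit")
}

#' Published classic-model coefficients (1363-chain learning set)
#'
#' The classic accessibility model (E20 + E6 + FSR + FSHP + AA, valine
#' baseline, 20\% RSA threshold) with the coefficients and standard errors
#' published for a fit on a domain-complete 1363-chain X-ray structure
#' learning set.  Shipped as a model JSON under \code{inst/extdata}; useful
#' for prediction without refitting, as generative truth for the synthetic
#' fixtures, and for odds-ratio arithmetic (e.g. the lysine odds ratio
#' \eqn{\exp(1.509) = 4.522}).
#'
#' @return A \code{logistic_fit}.
#' @examples
#' fit <- classic_model_1363()
#' round(odds_ratio(fit, "AA:LYS"), 3)
#' @export
classic_model_1363 <- function() {
  path <- system.file("extdata", "classic_model_1363.json",
                      package = "rsalogit", mustWork = TRUE)
  read_model_json(path)
}
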