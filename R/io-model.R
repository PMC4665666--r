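MODEL_JSON_VERSION <- "1.0"

#' Write a fitted logistic model to JSON
#'
#' Serializes a \code{logistic_fit} (coefficients, standard errors, factor
#' levels, model spec, fit statistics) so a fitted model can be reused for
#' prediction without refitting.  Coefficient values round-trip at full
#' double precision.  Entropy descriptors are in nats (natural-log
#' entropies); this is recorded in the file since coefficient magnitudes
#' depend on the base.
#'
#' @param fit A \code{logistic_fit}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @seealso [read_model_json()]
#' @export
write_model_json <- function(fit, path) {
  stopifnot(inherits(fit, "logistic_fit"))
  obj <- list(
    version = MODEL_JSON_VERSION,
    descriptors = fit$spec$descriptors,
    baseline = fit$spec$baseline,
    rsa_threshold = fit$spec$rsa_threshold,
    cutoff = fit$spec$cutoff,
    entropy_units = "nats",
    coefficients = as.list(fit$coefficients),
    se = as.list(fit$se),
    levels = fit$levels,
    loglik = fit$loglik,
    n = fit$n,
    n_accessible = fit$n_accessible,
    converged = fit$converged,
    diagnostics = fit$diagnostics
  )
  ## 17 significant digits: doubles survive the round trip bit-for-bit
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a logistic model from JSON
#'
#' Reads a model written by [write_model_json()] (or hand-written in the
#' same schema, e.g. to encode published coefficient tables) back into a
#' \code{logistic_fit} usable with [predict_proba()], [classify()] and
#' [odds_ratio()].
#'
#' @param path Path to a model JSON file.
#' @return A \code{logistic_fit}.
#' @export
read_model_json <- function(path) {
  if (!file.exists(path)) stop("model JSON not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  need <- c("version", "descriptors", "baseline", "coefficients")
  miss <- setdiff(need, names(obj))
  if (length(miss))
    stop("model JSON missing key(s): ", paste(miss, collapse = ", "))
  if (!identical(as.character(obj$version), MODEL_JSON_VERSION))
    stop("model JSON version '", obj$version, "' not supported (expected ",
         MODEL_JSON_VERSION, ")")
  spec <- model_spec(unlist(obj$descriptors),
                     baseline = obj$baseline,
                     rsa_threshold = if (is.null(obj$rsa_threshold)) 20
                                     else obj$rsa_threshold,
                     cutoff = if (is.null(obj$cutoff)) 0.5 else obj$cutoff)
  beta <- unlist(obj$coefficients)
  levels <- lapply(obj$levels, function(l) unlist(l))
  ## every declared categorical level must have a coefficient column
  for (d in names(levels)) {
    want <- paste0(d, ":", level_display(levels[[d]]))
    miss <- setdiff(want, names(beta))
    if (length(miss))
      stop("model JSON lacks coefficient(s) for declared level(s): ",
           paste(miss, collapse = ", "))
  }
  if (!"(Intercept)" %in% names(beta))
    stop("model JSON lacks an (Intercept) coefficient")
  se <- if (is.null(obj$se)) stats::setNames(rep(NA_real_, length(beta)),
                                             names(beta))
        else unlist(obj$se)[names(beta)]
  z <- beta / se
  structure(list(
    coefficients = beta, se = se, z = z,
    p_value = 2 * stats::pnorm(-abs(z)),
    odds_ratio = exp(beta),
    loglik = if (is.null(obj$loglik)) NA_real_ else obj$loglik,
    n = if (is.null(obj$n)) NA_integer_ else obj$n,
    n_accessible = if (is.null(obj$n_accessible)) NA_integer_
                   else obj$n_accessible,
    converged = if (is.null(obj$converged)) TRUE else obj$converged,
    diagnostics = unlist(obj$diagnostics),
    levels = levels, spec = spec, fitted = NULL),
    class = "logistic_fit")
}

#' Write a coefficient report as tab-separated text
#'
#' Emits the standard report layout: variable, beta, SE, exp(beta), z, p.
#'
#' @param fit A \code{logistic_fit}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_fit_report <- function(fit, path) {
  utils::write.table(coef_table(fit), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
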