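#' Linear least-squares baseline: continuous RSA on one descriptor plus AA
#'
#' Ordinary least squares of the continuous relative accessibility
#' (percent) on a single quantitative descriptor with additive amino-acid
#' effects: a common slope and one intercept per residue type (treatment
#' coding, valine baseline).  Classification follows by thresholding the
#' predicted RSA at the active threshold, giving the classical linear
#' counterpart to the logistic model.
#'
#' @param records Residue data frame with \code{rsa}, \code{aa} and the
#'   chosen descriptor column.
#' @param descriptor Quantitative descriptor name (default \code{"E6"}).
#' @param rsa_threshold Threshold (percent) used by
#'   [predict.linear_baseline()] for classification.
#' @return An object of class \code{linear_baseline}: the underlying
#'   \code{lm} fit, the common \code{slope}, per-amino-acid
#'   \code{intercepts}, and metadata.
#' @examples
#' rec <- data.frame(chain_id = "c", position = 1:6,
#'                   aa = c("V", "V", "D", "D", "K", "K"),
#'                   e6 = c(0, 1, 0, 1, 0.5, 1.5))
#' rec$rsa <- 10 * rec$e6 + c(14, 14, 45, 45, 30, 30)
#' fit <- fit_linear_baseline(rec)
#' fit$slope  # 10
#' @export
fit_linear_baseline <- function(records, descriptor = "E6",
                                rsa_threshold = 20) {
  if (!descriptor %in% names(QUANT_DESCRIPTORS))
    stop("descriptor must be one of: ",
         paste(names(QUANT_DESCRIPTORS), collapse = ", "))
  col <- QUANT_DESCRIPTORS[[descriptor]]
  need <- c("rsa", "aa", col)
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records lack column(s): ",
                         paste(miss, collapse = ", "))
  ok <- !is.na(records$rsa) & !is.na(records[[col]]) &
    records$aa %in% AA_LETTERS
  rec <- records[ok, , drop = FALSE]
  if (nrow(rec) < 3L) stop("too few complete records for the baseline fit")
  aa_f <- droplevels(
    factor(rec$aa, levels = c("V", sort(setdiff(unique(rec$aa), "V")))))
  dat <- data.frame(rsa = rec$rsa, x = rec[[col]], aa = aa_f)
  ## a single residue type reduces to simple regression on the descriptor
  fit <- if (nlevels(aa_f) > 1L) stats::lm(rsa ~ x + aa, data = dat)
         else stats::lm(rsa ~ x, data = dat)
  if (any(is.na(stats::coef(fit))))
    stop("degenerate baseline design: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "))
  cf <- stats::coef(fit)
  lv <- levels(aa_f)
  intercepts <- stats::setNames(rep(cf[["(Intercept)"]], length(lv)), lv)
  extra <- grep("^aa", names(cf), value = TRUE)
  intercepts[sub("^aa", "", extra)] <-
    intercepts[sub("^aa", "", extra)] + cf[extra]
  structure(list(lm = fit, slope = unname(cf[["x"]]),
                 intercepts = stats::setNames(unname(intercepts),
                                              level_display(names(intercepts))),
                 descriptor = descriptor, rsa_threshold = rsa_threshold,
                 n = nrow(rec)),
            class = "linear_baseline")
}

#' @export
print.linear_baseline <- function(x, ...) {
  cat("Linear RSA baseline: RSA ~ ", x$descriptor, " + AA, n = ", x$n,
      "\n  common slope (", x$descriptor, "): ",
      format(x$slope, digits = 6), "\n  intercept range: ",
      format(min(x$intercepts), digits = 4), " (",
      names(x$intercepts)[which.min(x$intercepts)], ") to ",
      format(max(x$intercepts), digits = 4), " (",
      names(x$intercepts)[which.max(x$intercepts)], ")\n", sep = "")
  invisible(x)
}

#' Predict RSA (and optionally classify) with the linear baseline
#'
#' @param object A \code{linear_baseline}.
#' @param records Residue data frame.
#' @param type \code{"rsa"} for predicted percent accessibility,
#'   \code{"class"} for the 0/1 call obtained by thresholding the predicted
#'   RSA at the fit's threshold (boundary inclusive, matching
#'   [binarize_rsa()]).
#' @param ... Unused.
#' @return Numeric (or integer) vector aligned to \code{records} rows.
#' @export
predict.linear_baseline <- function(object, records, type = c("rsa", "class"),
                                    ...) {
  type <- match.arg(type)
  col <- QUANT_DESCRIPTORS[[object$descriptor]]
  disp <- level_display(records$aa)
  ok <- !is.na(records[[col]]) & disp %in% names(object$intercepts)
  out <- rep(NA_real_, nrow(records))
  out[ok] <- object$intercepts[disp[ok]] +
    object$slope * records[[col]][ok]
  if (type == "rsa") return(out)
  as.integer(out >= object$rsa_threshold)
}
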