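#' Fit a logistic regression by maximum likelihood
#'
#' Maximizes the Bernoulli log-likelihood of buried/accessible labels under
#' the logit link by iteratively reweighted least squares (Newton-Raphson on
#' the log-likelihood), the standard GLM algorithm.  Standard errors come
#' from the inverse of the observed information at the optimum; Wald
#' \eqn{z = \beta / \mathrm{SE}} statistics are referred to the standard
#' normal for two-sided p-values, and \eqn{\exp(\beta)} gives the odds
#' ratio per unit descriptor increase.  No regularization is applied:
#' complete separation and rank deficiency are flagged, not penalized.
#'
#' @param design A [build_design()] result with a response.
#' @param max_iter Maximum Newton iterations (default 100).
#' @param tol Convergence tolerance on the relative log-likelihood change
#'   (default 1e-10).
#' @return An object of class \code{logistic_fit}: coefficients, standard
#'   errors, \code{z}, \code{p_value}, \code{odds_ratio} (\eqn{\exp\beta}),
#'   log-likelihood, \code{n}, convergence flags, factor levels and the
#'   model spec.
#' @export
fit_logistic <- function(design, max_iter = 100L, tol = 1e-10) {
  stopifnot(inherits(design, "design_matrix"))
  X <- design$X
  y <- design$y
  if (is.null(y)) stop("design has no response; build with require_label = TRUE")
  if (length(unique(y)) < 2L)
    stop("response has a single class (all ", y[1],
         "); a logistic model cannot be fitted")
  qrX <- qr(X)
  diagnostics <- character()
  rank_deficient <- qrX$rank < ncol(X)
  if (rank_deficient) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    diagnostics <- c(diagnostics,
                     paste0("rank-deficient design; aliased column(s): ",
                            paste(dropped, collapse = ", ")))
  }
  p_cols <- ncol(X)
  beta <- rep(0, p_cols)
  ## log(1 + e^eta) written to avoid overflow at large |eta|
  loglik <- function(eta)
    sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta)))))
  eta <- drop(X %*% beta)
  ll <- loglik(eta)
  converged <- FALSE
  if (!rank_deficient) {
    for (it in seq_len(max_iter)) {
      p <- stats::plogis(eta)
      w <- pmax(p * (1 - p), .Machine$double.eps)
      XtWX <- crossprod(X, X * w)
      score <- crossprod(X, y - p)
      step <- tryCatch(solve(XtWX, score), error = function(e) NULL)
      if (is.null(step)) {
        diagnostics <- c(diagnostics,
                         "information matrix numerically singular")
        break
      }
      beta_new <- beta + drop(step)
      eta_new <- drop(X %*% beta_new)
      ll_new <- loglik(eta_new)
      ## step-halving keeps Newton monotone on near-separated data
      halvings <- 0L
      while ((!is.finite(ll_new) || ll_new < ll) && halvings < 30L) {
        beta_new <- (beta + beta_new) / 2
        eta_new <- drop(X %*% beta_new)
        ll_new <- loglik(eta_new)
        halvings <- halvings + 1L
      }
      done <- is.finite(ll_new) &&
        abs(ll_new - ll) < tol * (abs(ll) + tol)
      beta <- beta_new; eta <- eta_new; ll <- ll_new
      if (done) { converged <- TRUE; break }
    }
  }
  p_hat <- stats::plogis(eta)
  eps <- 1e-10
  separated <- any(p_hat < eps | p_hat > 1 - eps)
  if (separated) {
    diagnostics <- c(diagnostics, paste0(
      "fitted probabilities numerically 0 or 1 (possible separation) for ",
      sum(p_hat < eps | p_hat > 1 - eps), " record(s)"))
    converged <- FALSE
  }
  se <- rep(NA_real_, p_cols)
  if (converged) {
    w <- pmax(p_hat * (1 - p_hat), .Machine$double.eps)
    info <- crossprod(X, X * w)
    vcov <- tryCatch(solve(info), error = function(e) NULL)
    if (!is.null(vcov)) se <- sqrt(diag(vcov))
  }
  names(beta) <- names(se) <- colnames(X)
  z <- beta / se
  fit <- structure(list(
    coefficients = beta, se = se, z = z,
    p_value = 2 * stats::pnorm(-abs(z)),
    odds_ratio = exp(beta),
    loglik = ll, n = nrow(X),
    n_accessible = sum(y == 1L),
    converged = converged, diagnostics = diagnostics,
    levels = design$levels, spec = design$spec,
    fitted = p_hat),
    class = "logistic_fit")
  if (!converged)
    warning("logistic fit did not converge cleanly: ",
            paste(diagnostics, collapse = "; "), call. = FALSE)
  fit
}

#' Convenience wrapper: fit a model spec directly on records
#'
#' @param records Residue data frame with labels.
#' @param spec A [model_spec()] or a name accepted by it.
#' @param ... Passed to [fit_logistic()].
#' @return A \code{logistic_fit}.
#' @export
fit_model <- function(records, spec, ...) {
  if (!inherits(spec, "model_spec")) spec <- model_spec(spec)
  fit_logistic(build_design(records, spec), ...)
}

#' @export
print.logistic_fit <- function(x, digits = 3, ...) {
  cat("Logistic accessibility model (",
      paste(x$spec$descriptors, collapse = " + "), "), n = ", x$n,
      ", logLik = ", format(x$loglik, digits = 8),
      if (!x$converged) " [NOT CONVERGED]", "\n", sep = "")
  print(coef_table(x, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Coefficient table with Wald statistics
#'
#' Returns the fit as a report table: variable, \eqn{\beta}, standard
#' error, \eqn{\exp(\beta)}, Wald \eqn{z} and two-sided \eqn{p}.
#'
#' @param fit A \code{logistic_fit}.
#' @param digits Rounding for display columns (default no rounding).
#' @return A data frame with one row per model column.
#' @export
coef_table <- function(fit, digits = NULL) {
  tab <- data.frame(variable = names(fit$coefficients),
                    beta = unname(fit$coefficients),
                    se = unname(fit$se),
                    exp_beta = unname(fit$odds_ratio),
                    z = unname(fit$z),
                    p = unname(fit$p_value),
                    stringsAsFactors = FALSE)
  if (!is.null(digits))
    for (cc in c("beta", "se", "exp_beta", "z", "p"))
      tab[[cc]] <- round(tab[[cc]], digits)
  tab
}

#' Odds ratio for a descriptor change
#'
#' The multiplicative change \eqn{\exp(\delta \beta)} in the odds of
#' accessibility when the named model column increases by \code{delta}
#' units (for an indicator column, the odds ratio of that level against the
#' baseline).
#'
#' @param fit A \code{logistic_fit}.
#' @param column Model column name (e.g. \code{"E6"} or \code{"AA:LYS"}).
#' @param delta Descriptor increase; default 1.
#' @return The odds ratio, a single number.
#' @export
odds_ratio <- function(fit, column, delta = 1) {
  if (!column %in% names(fit$coefficients))
    stop("unknown model column: ", column, "; available: ",
         paste(names(fit$coefficients), collapse = ", "))
  exp(delta * fit$coefficients[[column]])
}

#' Predict accessibility probabilities for residue records
#'
#' Evaluates the fitted linear predictor for each record complete for the
#' model's descriptors and maps it through the logistic function,
#' numerically stable for large magnitudes.  Incomplete records get
#' \code{NA} with a report.
#'
#' @param fit A \code{logistic_fit} (or a model read back with
#'   [read_model_json()]).
#' @param records Residue data frame.
#' @return Numeric vector of probabilities aligned to \code{records} rows
#'   (NA for skipped records).
#' @export
predict_proba <- function(fit, records) {
  stopifnot(inherits(fit, "logistic_fit"))
  des <- build_design(records, fit$spec, require_label = FALSE,
                      levels = fit$levels)
  missing_cols <- setdiff(names(fit$coefficients), colnames(des$X))
  X <- cbind(des$X,
             matrix(0, nrow(des$X), length(missing_cols),
                    dimnames = list(NULL, missing_cols)))
  X <- X[, names(fit$coefficients), drop = FALSE]
  eta <- drop(X %*% fit$coefficients)
  out <- rep(NA_real_, nrow(records))
  out[des$rows] <- stats::plogis(eta)
  out
}

#' Classify accessibility probabilities
#'
#' Converts probabilities to binary accessibility calls: accessible (1)
#' when \eqn{p \ge} \code{cutoff} (boundary inclusive), buried (0)
#' otherwise.
#'
#' @param probabilities Numeric vector in \eqn{[0, 1]}.
#' @param cutoff Probability cutoff; default 0.5.
#' @return Integer vector of 0/1 calls (NA preserved).
#' @export
classify <- function(probabilities, cutoff = 0.5) {
  if (any(probabilities < 0 | probabilities > 1, na.rm = TRUE))
    stop("probabilities must lie in [0, 1]")
  as.integer(probabilities >= cutoff)
}
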