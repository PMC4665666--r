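## Rows of `records` usable for `spec` (all required descriptors present,
## and label present when required).
complete_for_spec <- function(records, spec, require_label = TRUE) {
  ok <- rep(TRUE, nrow(records))
  for (d in spec$descriptors) {
    col <- c(QUANT_DESCRIPTORS, CAT_DESCRIPTORS)[[d]]
    if (!col %in% names(records)) ok <- ok & FALSE
    else ok <- ok & !is.na(records[[col]])
  }
  if ("aa" %in% names(records)) ok <- ok & records$aa != "X"
  if (require_label) {
    if (!"label" %in% names(records)) ok <- ok & FALSE
    else ok <- ok & !is.na(records$label)
  }
  ok
}

## Dummy-code one categorical column against the level set `levels`
## (values, not display names).  Baseline contributes no column.
code_factor <- function(values, levels, baseline, prefix) {
  unseen <- setdiff(unique(values), c(levels, baseline))
  if (length(unseen))
    stop("level(s) ", paste(level_display(unseen), collapse = ", "),
         " of ", prefix, " absent from the learning set")
  if (length(levels) == 0L)
    return(matrix(numeric(0), nrow = length(values), ncol = 0))
  m <- vapply(levels, function(l) as.numeric(values == l),
              numeric(length(values)))
  m <- matrix(m, nrow = length(values), ncol = length(levels))
  colnames(m) <- paste0(prefix, ":", level_display(levels))
  m
}

## Non-baseline levels observed for a categorical, in deterministic
## (C-locale alphabetical by display name) order.
observed_levels <- function(values, baseline) {
  lev <- setdiff(unique(values), baseline)
  lev[order(level_display(lev), method = "radix")]
}

#' Assemble a design matrix for a logistic model
#'
#' Encodes residue records into a numeric design matrix: an intercept
#' column, quantitative descriptors as-is, and each categorical descriptor
#' expanded to 0/1 indicator variables for every non-baseline level observed
#' in the data (treatment coding, valine baseline by default; for the AA
#' factor on data covering all residue types this yields exactly 19
#' indicators).  Dummy columns are ordered alphabetically within each factor
#' so refits are reproducible.  Records missing any required descriptor (or
#' the label, when required) are excluded; their count is reported.
#'
#' @param records Residue data frame.
#' @param spec A [model_spec()].
#' @param require_label If \code{TRUE} (fitting) rows need a 0/1
#'   \code{label}; if \code{FALSE} (prediction) labels are not required.
#' @param levels Optional named list of factor level sets from a previous
#'   fit; encoding errors if a record carries a level not in the set.
#' @return An object of class \code{design_matrix}: list with \code{X}
#'   (numeric matrix with intercept), \code{y} (response or NULL),
#'   \code{rows} (indices into \code{records}), \code{levels} and
#'   \code{spec}.
#' @export
build_design <- function(records, spec, require_label = TRUE,
                         levels = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  ok <- complete_for_spec(records, spec, require_label)
  if (!any(ok))
    stop("no record is complete for descriptors ",
         paste(spec$descriptors, collapse = " + "))
  if (any(!ok))
    message(sum(!ok), " of ", length(ok),
            " record(s) incomplete for this model; excluded")
  rec <- records[ok, , drop = FALSE]
  blocks <- list(`(Intercept)` = matrix(1, nrow(rec), 1,
                                        dimnames = list(NULL, "(Intercept)")))
  lev_out <- list()
  for (d in spec$descriptors) {
    if (d %in% names(QUANT_DESCRIPTORS)) {
      col <- QUANT_DESCRIPTORS[[d]]
      blocks[[d]] <- matrix(rec[[col]], ncol = 1,
                            dimnames = list(NULL, d))
    } else {
      col <- CAT_DESCRIPTORS[[d]]
      vals <- rec[[col]]
      lv <- if (!is.null(levels) && d %in% names(levels)) levels[[d]]
            else observed_levels(vals, spec$baseline)
      blocks[[d]] <- code_factor(vals, lv, spec$baseline, d)
      lev_out[[d]] <- lv
    }
  }
  X <- do.call(cbind, blocks)
  y <- if (require_label) as.integer(rec$label) else NULL
  structure(list(X = X, y = y, rows = which(ok), levels = lev_out,
                 spec = spec),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat("Design matrix:", nrow(x$X), "records x", ncol(x$X), "columns (",
      paste(x$spec$descriptors, collapse = " + "), ")\n")
  invisible(x)
}
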