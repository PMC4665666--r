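#' Two-state classification accuracy
#'
#' The standard two-state accuracy: the percentage of residues whose
#' buried/accessible call matches the label, counting both classes
#' (\eqn{100 (TP + TN) / (P + N)}).
#'
#' @param predictions Integer vector of 0/1 calls.
#' @param labels Integer vector of 0/1 labels.
#' @return Accuracy in percent.
#' @examples
#' accuracy(c(1, 1, 0, 0), c(1, 0, 0, 0))  # 75
#' @export
accuracy <- function(predictions, labels) {
  if (length(predictions) != length(labels))
    stop("predictions and labels differ in length")
  keep <- !is.na(predictions) & !is.na(labels)
  if (!any(keep)) stop("no scored residue pairs")
  if (!all(labels[keep] %in% c(0L, 1L)))
    stop("labels must be 0 or 1")
  100 * mean(predictions[keep] == labels[keep])
}

#' Residue-count-weighted mean accuracy over strata
#'
#' @param n Integer vector of residue counts per stratum.
#' @param acc Numeric vector of per-stratum accuracies (percent).
#' @return The weighted mean accuracy in percent.
#' @examples
#' weighted_accuracy(c(100, 50), c(80, 70))  # 76.667
#' @export
weighted_accuracy <- function(n, acc) {
  if (length(n) != length(acc) || length(n) == 0L)
    stop("n and acc must be equal-length, non-empty vectors")
  if (any(n <= 0)) stop("stratum residue counts must be positive")
  sum(n * acc) / sum(n)
}

## Accuracy difference -> M/O/P code: M below -0.5, P above +0.5, else O.
delta_code <- function(delta) {
  if (is.na(delta)) return(NA_character_)
  if (delta < -0.5) "M" else if (delta > 0.5) "P" else "O"
}

#' Stratified two-branch evaluation of accessibility predictions
#'
#' Applies the branch-appropriate model to each labeled record — the
#' homology-descriptor model to optimum-homology chains, the non-homology
#' model to the rest — and reports accuracies for the standard strata:
#' both homology branches, oligomer and non-oligomer chains, oligomer
#' residues with likely interfacial residues removed, and the interfacial
#' residues alone.  The all-proteins number is the residue-count-weighted
#' mean of the two branch accuracies.  Accuracy differences
#' (oligomer minus non-oligomer; interface-removed minus full oligomer) are
#' coded \code{M} (below -0.5), \code{O} (within +/-0.5) or \code{P}
#' (above +0.5) percentage points.
#'
#' @param records Labeled residue data frame with \code{homology_status}
#'   and, optionally, \code{oligomer} and \code{interfacial} columns.
#' @param fit_optimum \code{logistic_fit} applied to optimum-homology
#'   records (may use homology descriptors).  Required if any record is
#'   optimum.
#' @param fit_non_homology \code{logistic_fit} with exclusively
#'   non-homology descriptors, applied to non-optimum records.  Required if
#'   any record is non-optimum; never silently replaced by the homology
#'   model.
#' @param cutoff Classification cutoff (default: each fit's own).
#' @return An object of class \code{evaluation_report}: a strata table
#'   (\code{stratum}, \code{n}, \code{accuracy}), the weighted all-proteins
#'   accuracy, and the delta codes.
#' @export
evaluate <- function(records, fit_optimum = NULL, fit_non_homology = NULL,
                     cutoff = NULL) {
  if (!"homology_status" %in% names(records))
    stop("records lack homology_status")
  if (!"label" %in% names(records))
    stop("records lack labels; run label_records() first")
  records <- records[!is.na(records$label), , drop = FALSE]
  if (nrow(records) == 0L) stop("no labeled records to evaluate")
  bad <- !records$homology_status %in% c("optimum", "non_optimum")
  if (any(bad))
    stop("unknown homology status value(s): ",
         paste(unique(records$homology_status[bad]), collapse = ", "))
  is_opt <- records$homology_status == "optimum"
  if (any(is_opt) && is.null(fit_optimum))
    stop("optimum-homology records present but no optimum-branch model given")
  if (any(!is_opt) && is.null(fit_non_homology))
    stop("non-optimum records present but no non-homology model given")
  if (!is.null(fit_non_homology)) {
    homol <- intersect(fit_non_homology$spec$descriptors,
                       c("E20", "E6", "FSHP", "FSR"))
    if (length(homol))
      stop("the non-optimum branch model must use exclusively non-homology ",
           "descriptors; found: ", paste(homol, collapse = ", "))
  }
  pred <- rep(NA_integer_, nrow(records))
  branch_pred <- function(fit, rows) {
    p <- predict_proba(fit, records[rows, , drop = FALSE])
    classify(p, if (is.null(cutoff)) fit$spec$cutoff else cutoff)
  }
  if (any(is_opt)) pred[is_opt] <- branch_pred(fit_optimum, is_opt)
  if (any(!is_opt)) pred[!is_opt] <- branch_pred(fit_non_homology, !is_opt)
  scored <- !is.na(pred)
  if (any(!scored))
    message(sum(!scored), " labeled record(s) not scorable by the branch ",
            "model; excluded from evaluation")
  stratum_row <- function(name, idx) {
    idx <- idx & scored
    if (!any(idx)) return(NULL)
    data.frame(stratum = name, n = sum(idx),
               accuracy = accuracy(pred[idx], records$label[idx]),
               stringsAsFactors = FALSE)
  }
  olig <- if ("oligomer" %in% names(records)) records$oligomer else
    rep(NA, nrow(records))
  intf <- if ("interfacial" %in% names(records)) records$interfacial else
    rep(NA, nrow(records))
  rows <- list(
    stratum_row("all", rep(TRUE, nrow(records))),
    stratum_row("optimum", is_opt),
    stratum_row("non_optimum", !is_opt),
    stratum_row("oligomer", !is.na(olig) & olig),
    stratum_row("non_oligomer", !is.na(olig) & !olig),
    stratum_row("oligomer_without_interface",
                !is.na(olig) & olig & !is.na(intf) & !intf),
    stratum_row("interfacial_only", !is.na(intf) & intf)
  )
  strata <- do.call(rbind, rows)
  get <- function(s, what = "accuracy") {
    i <- match(s, strata$stratum)
    if (is.na(i)) NA_real_ else strata[[what]][i]
  }
  branch <- strata[strata$stratum %in% c("optimum", "non_optimum"), ,
                   drop = FALSE]
  weighted_all <- weighted_accuracy(branch$n, branch$accuracy)
  structure(list(
    strata = strata,
    weighted_all_proteins = weighted_all,
    delta_oligomer = get("oligomer") - get("non_oligomer"),
    delta_oligomer_code =
      delta_code(get("oligomer") - get("non_oligomer")),
    delta_interface_removed =
      get("oligomer_without_interface") - get("oligomer"),
    delta_interface_removed_code =
      delta_code(get("oligomer_without_interface") - get("oligomer")),
    n_scored = sum(scored)),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Stratified accessibility evaluation (", x$n_scored,
      " residues scored)\n", sep = "")
  tab <- x$strata
  tab$accuracy <- round(tab$accuracy, 2)
  print(tab, row.names = FALSE)
  cat(sprintf("weighted all-proteins accuracy: %.2f%%\n",
              x$weighted_all_proteins))
  if (!is.na(x$delta_oligomer))
    cat(sprintf("oligomer - non-oligomer: %+.2f (%s)\n",
                x$delta_oligomer, x$delta_oligomer_code))
  if (!is.na(x$delta_interface_removed))
    cat(sprintf("interface-removed - full oligomer: %+.2f (%s)\n",
                x$delta_interface_removed, x$delta_interface_removed_code))
  invisible(x)
}

#' Write an evaluation report to JSON
#'
#' @param report An \code{evaluation_report}.
#' @param path Output path.
#' @param config Optional named list echoed into the file.
#' @return Invisibly, \code{path}.
#' @export
write_evaluation_json <- function(report, path, config = NULL) {
  obj <- list(strata = report$strata,
              weighted_all_proteins = report$weighted_all_proteins,
              delta_oligomer = report$delta_oligomer,
              delta_oligomer_code = report$delta_oligomer_code,
              delta_interface_removed = report$delta_interface_removed,
              delta_interface_removed_code = report$delta_interface_removed_code,
              n_scored = report$n_scored)
  if (!is.null(config)) obj$config <- config
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", dataframe = "rows")
  invisible(path)
}
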