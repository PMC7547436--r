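#' Incremental cost-effectiveness comparison of two arms
#'
#' Computes the cost and QALY increments of an intervention arm over a
#' comparator, the incremental cost-effectiveness ratio
#' `ICER = delta_cost / delta_qaly` where defined, and the dominance
#' classification: an arm that saves money and gains QALYs is *dominant*;
#' one that costs more and loses QALYs is *dominated*; otherwise the signed
#' ICER is reported with its cost-effectiveness-plane quadrant.
#'
#' @param intervention,comparator [economic_result()] objects evaluated
#'   under the same [model_config()].
#' @return An object of class `comparison_result` with elements
#'   `delta_cost`, `delta_qaly`, `icer` (`NA` when `delta_qaly == 0`),
#'   `dominance_label`, and the arm names.
#' @examples
#' cur <- economic_result(407.4e6, 8471, "current")
#' opt <- economic_result(413.3e6, 8399, "option1")
#' compute_icer(opt, cur)
#' @export
compute_icer <- function(intervention, comparator) {
  stopifnot(inherits(intervention, "economic_result"),
            inherits(comparator, "economic_result"))
  dc <- intervention$total_cost - comparator$total_cost
  dq <- intervention$total_qaly - comparator$total_qaly
  if (dq == 0) {
    icer <- NA_real_
    label <- if (dc == 0) "equivalent" else
      sprintf("equal effect; cost difference %.0f AUD", dc)
  } else {
    icer <- dc / dq
    label <- if (dc <= 0 && dq > 0) "dominant (cost saving and more effective)"
    else if (dc > 0 && dq < 0) "dominated (more costly and less effective)"
    else if (dc <= 0 && dq < 0) "less costly and less effective"
    else "more costly and more effective"
  }
  structure(list(intervention = intervention$name, comparator = comparator$name,
                 delta_cost = dc, delta_qaly = dq, icer = icer,
                 dominance_label = label),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("Comparison%s: delta cost %.2f M AUD, delta QALY %.1f\n",
              if (is.null(x$intervention)) "" else
                sprintf(" %s vs %s", x$intervention, x$comparator),
              x$delta_cost / 1e6, x$delta_qaly))
  if (is.na(x$icer)) {
    cat(sprintf("  %s\n", x$dominance_label))
  } else if (grepl("^domina", x$dominance_label)) {
    cat(sprintf("  %s\n", x$dominance_label))
  } else {
    cat(sprintf("  ICER %s AUD/QALY (%s)\n",
                format(trunc(x$icer), big.mark = ","), x$dominance_label))
  }
  invisible(x)
}

#' Net monetary benefit
#'
#' `NMB = WTP x QALY - cost`, monetizing health gains at the
#' willingness-to-pay threshold. Accepts either an [economic_result()] or a
#' raw `(cost, qaly)` pair via `total_cost`/`total_qaly`.
#'
#' @param result An [economic_result()].
#' @param wtp Willingness to pay per QALY (AUD, > 0).
#' @return Net monetary benefit in AUD.
#' @export
compute_nmb <- function(result, wtp) {
  stopifnot(inherits(result, "economic_result"))
  if (wtp <= 0) stop("'wtp' must be positive")
  wtp * result$total_qaly - result$total_cost
}

#' Incremental net monetary benefit versus current practice
#'
#' Difference of the absolute NMBs of an option and the usual-care arm at a
#' shared willingness-to-pay threshold; positive values indicate the option
#' is cost-effective versus current practice at that threshold.
#'
#' @param option_result,current_result [economic_result()] objects under a
#'   shared [model_config()].
#' @inheritParams compute_nmb
#' @return Incremental NMB in AUD.
#' @export
incremental_nmb <- function(option_result, current_result, wtp) {
  compute_nmb(option_result, wtp) - compute_nmb(current_result, wtp)
}

#' Option ranking by incremental NMB across WTP thresholds
#'
#' Ranks the non-comparator options by incremental NMB versus the
#' comparator arm at each threshold, for checking that conclusions are
#' insensitive to the willingness-to-pay value.
#'
#' @param results Named list of [economic_result()] objects including the
#'   comparator arm.
#' @param wtp_list Numeric vector of thresholds (AUD per QALY).
#' @param comparator Name of the usual-care arm in `results`.
#' @return A data frame with one row per (threshold, option) holding the
#'   incremental NMB and the rank (1 = highest incremental NMB).
#' @export
wtp_ordering <- function(results, wtp_list, comparator = "current") {
  stopifnot(length(results) >= 2L, comparator %in% names(results))
  opts <- setdiff(names(results), comparator)
  out <- do.call(rbind, lapply(wtp_list, function(w) {
    inmb <- vapply(opts, function(o)
      incremental_nmb(results[[o]], results[[comparator]], w), numeric(1))
    data.frame(wtp = w, option = opts, incremental_nmb = inmb,
               rank = rank(-inmb, ties.method = "min"), row.names = NULL)
  }))
  out
}

#' Base-case league table
#'
#' One row per allocation option, in the conventional published layout:
#' total discounted cost in millions of AUD, total QALYs, average cost per
#' QALY, and the ICER versus current practice or its dominance label. ICERs
#' are computed on unrounded totals; printed ICER values are truncated
#' toward zero to whole AUD, matching the usual reporting convention.
#'
#' @param results Named list of [economic_result()] objects including the
#'   comparator.
#' @param comparator Name of the usual-care arm.
#' @return A data frame of class `league_table`.
#' @export
league_table <- function(results, comparator = "current") {
  stopifnot(comparator %in% names(results))
  rows <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    icer <- NA_real_
    label <- ""
    if (nm != comparator) {
      cmp <- compute_icer(r, results[[comparator]])
      label <- cmp$dominance_label
      if (!grepl("^dominant", label)) icer <- cmp$icer
    }
    data.frame(option = nm,
               total_cost_millions = r$total_cost / 1e6,
               total_qaly = r$total_qaly,
               cost_per_qaly = r$total_cost / r$total_qaly,
               icer = icer,
               result = label,
               row.names = NULL)
  })
  structure(do.call(rbind, rows), class = c("league_table", "data.frame"),
            comparator = comparator)
}

#' @export
print.league_table <- function(x, ...) {
  y <- x
  y$total_cost_millions <- sprintf("%.1f", y$total_cost_millions)
  y$total_qaly <- sprintf("%.0f", y$total_qaly)
  y$cost_per_qaly <- sprintf("%s", format(trunc(y$cost_per_qaly), big.mark = ","))
  y$icer <- ifelse(is.na(x$icer), "",
                   format(trunc(x$icer), big.mark = ",", trim = TRUE))
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}
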