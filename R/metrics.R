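#' Count set-level errors against a known truth
#'
#' Given the decisions of a hypothesis-set test and the ground truth, counts
#' the quantities that define the overall and mixed-directional false
#' discovery rates:
#' \describe{
#'   \item{R}{number of rejected sets;}
#'   \item{V}{number of *falsely* rejected sets — rejected sets in which at
#'     least one true null was rejected. A rejected set whose nulls are all
#'     true counts in `V` automatically, because rejecting it rejects its
#'     (true) screening null;}
#'   \item{S}{number of rejected sets not in `V` for which at least one
#'     directional error was made: a false individual null rejected with a
#'     declared direction different from the true sign.}
#' }
#' `V` and `S` are disjoint by construction, so \eqn{V + S \le R}.
#'
#' @param report An [hset_test()] result, or a tidy data frame with columns
#'   `set_id`, `hypothesis_id`, `rejected`, `direction`, `set_rejected`.
#' @param truth A data frame with columns `set_id`, `hypothesis_id` and
#'   `true_sign` in `{-1, 0, 1}` (0 where the individual null is true). Must
#'   cover exactly the hypotheses in `report`.
#'
#' @return A list with integer components `R`, `V`, `S`.
#'
#' @seealso [ofdr()], [mdfdr()], [evaluate_decisions()]
#' @export
count_errors <- function(report, truth) {
  joined <- join_report_truth(report, truth)
  per_set <- joined %>%
    group_by(.data$set_id) %>%
    summarise(
      set_rejected = .data$set_rejected[1],
      all_null = all(.data$true_sign == 0),
      false_rej = any(.data$rejected & .data$true_sign == 0),
      dir_err = any(.data$rejected & .data$true_sign != 0 &
                      .data$direction != .data$true_sign)
    )
  v <- per_set$set_rejected & (per_set$all_null | per_set$false_rej)
  s <- per_set$set_rejected & !v & per_set$dir_err
  list(
    R = as.integer(sum(per_set$set_rejected)),
    V = as.integer(sum(v)),
    S = as.integer(sum(s))
  )
}

#' Overall and mixed-directional false discovery proportions
#'
#' Per-replication ratios behind the OFDR and mdFDR: `ofdr()` returns
#' \eqn{V/\max(R,1)}, the proportion of falsely rejected hypothesis sets;
#' `mdfdr()` returns \eqn{(V+S)/\max(R,1)}, which additionally counts
#' correctly rejected sets that carry a directional error. Their
#' expectations over replications are the OFDR and mdFDR. `ofdr() <=
#' mdfdr()` always.
#'
#' @param R Number of rejected sets.
#' @param V Number of falsely rejected sets.
#' @param S Number of correctly rejected sets with a directional error.
#' @return A proportion in `[0, 1]`.
#' @examples
#' ofdr(R = 4, V = 1)          # 0.25
#' mdfdr(R = 4, V = 1, S = 1)  # 0.5
#' @export
ofdr <- function(R, V) {
  stopifnot(V >= 0, R >= 0, V <= max(R, 1))
  V / max(R, 1)
}

#' @rdname ofdr
#' @export
mdfdr <- function(R, V, S) {
  stopifnot(V >= 0, S >= 0, R >= 0, V + S <= max(R, 1))
  (V + S) / max(R, 1)
}

#' Proportion of false individual nulls correctly rejected
#'
#' The individual-hypothesis notion of power: the proportion, among all
#' false individual nulls, that are rejected with the correct declared
#' direction. With `strict_direction = FALSE` a rejection with the wrong
#' direction also counts as a success.
#'
#' @inheritParams count_errors
#' @param strict_direction If `TRUE` (default), a false null rejected with
#'   the wrong sign does not count as correctly rejected.
#' @return A proportion in `[0, 1]`. Errors if the truth contains no false
#'   individual null (the proportion is undefined).
#' @export
power_individual <- function(report, truth, strict_direction = TRUE) {
  joined <- join_report_truth(report, truth)
  false_null <- joined$true_sign != 0
  if (!any(false_null)) {
    abort("`power_individual()` is undefined: no false individual nulls in `truth`.")
  }
  hit <- if (strict_direction) {
    joined$rejected & false_null & joined$direction == joined$true_sign
  } else {
    joined$rejected & false_null
  }
  sum(hit) / sum(false_null)
}

#' Proportion of false-null sets with entirely correct decisions
#'
#' The set-level notion of power: a false-null set (one containing at least
#' one false individual null) counts as correctly rejected only when every
#' decision inside it is correct — every false individual null rejected
#' (with the correct direction, unless `strict_direction = FALSE`) and no
#' true individual null rejected.
#'
#' @inheritParams power_individual
#' @return A proportion in `[0, 1]`. Errors if the truth contains no
#'   false-null set.
#' @export
power_setwise <- function(report, truth, strict_direction = TRUE) {
  joined <- join_report_truth(report, truth)
  per_set <- joined %>%
    group_by(.data$set_id) %>%
    summarise(
      false_null_set = any(.data$true_sign != 0),
      all_correct = all(
        (.data$true_sign == 0 & !.data$rejected) |
          (.data$true_sign != 0 & .data$rejected &
             (!strict_direction | .data$direction == .data$true_sign))
      )
    )
  if (!any(per_set$false_null_set)) {
    abort("`power_setwise()` is undefined: no false-null sets in `truth`.")
  }
  sum(per_set$false_null_set & per_set$all_correct) / sum(per_set$false_null_set)
}

#' Evaluate a decision report against the ground truth
#'
#' Convenience wrapper computing all error and power summaries at once:
#' `R`, `V`, `S`, the per-replication OFDR and mdFDR ratios, and both power
#' definitions. Powers are `NA` when their denominator is empty (no false
#' nulls, or no false-null sets).
#'
#' @inheritParams power_individual
#' @return A one-row tibble with columns `R`, `V`, `S`, `ofdr`, `mdfdr`,
#'   `power_i`, `power_ii`.
#' @export
evaluate_decisions <- function(report, truth, strict_direction = TRUE) {
  cnt <- count_errors(report, truth)
  joined <- join_report_truth(report, truth)
  has_false_null <- any(joined$true_sign != 0)
  tibble(
    R = cnt$R, V = cnt$V, S = cnt$S,
    ofdr = ofdr(cnt$R, cnt$V),
    mdfdr = mdfdr(cnt$R, cnt$V, cnt$S),
    power_i = if (has_false_null) {
      power_individual(report, truth, strict_direction)
    } else NA_real_,
    power_ii = if (has_false_null) {
      power_setwise(report, truth, strict_direction)
    } else NA_real_
  )
}

join_report_truth <- function(report, truth) {
  if (inherits(report, "hset_test")) report <- tidy(report)
  needed <- c("set_id", "hypothesis_id", "rejected", "direction", "set_rejected")
  if (!all(needed %in% names(report))) {
    abort(paste0(
      "`report` must be an `hset_test` object or have columns ",
      paste0("`", needed, "`", collapse = ", "), "."
    ))
  }
  if (!all(c("set_id", "hypothesis_id", "true_sign") %in% names(truth))) {
    abort("`truth` must have columns `set_id`, `hypothesis_id`, `true_sign`.")
  }
  if (nrow(report) != nrow(truth)) {
    abort("`report` and `truth` must describe the same hypotheses.")
  }
  joined <- left_join(
    report, select(truth, "set_id", "hypothesis_id", "true_sign"),
    by = c("set_id", "hypothesis_id")
  )
  if (anyNA(joined$true_sign)) {
    abort("`truth` does not cover every hypothesis in `report`.")
  }
  joined
}
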