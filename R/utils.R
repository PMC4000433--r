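check_pvalues <- function(p, arg = "p") {
  if (!is.numeric(p) || length(p) < 1L) {
    abort(sprintf("`%s` must be a non-empty numeric vector of p-values.", arg))
  }
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    abort(sprintf("All entries of `%s` must be p-values in [0, 1].", arg))
  }
  invisible(p)
}

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be a single number in (0, 1).")
  }
  invisible(alpha)
}

# validate the long-format hypothesis-set table used throughout the package
check_hset_data <- function(data) {
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame with columns `set_id` and `p_value`.")
  }
  missing_cols <- setdiff(c("set_id", "p_value"), names(data))
  if (length(missing_cols)) {
    abort(paste0(
      "`data` is missing required column(s): ",
      paste0("`", missing_cols, "`", collapse = ", "), "."
    ))
  }
  if (nrow(data) < 1L) abort("`data` must contain at least one hypothesis.")
  check_pvalues(data$p_value, arg = "data$p_value")
  if (!"statistic_sign" %in% names(data)) {
    data$statistic_sign <- 0
  }
  if (!all(data$statistic_sign %in% c(-1, 0, 1))) {
    abort("`statistic_sign` must only contain -1, 0 or 1.")
  }
  if (!"hypothesis_id" %in% names(data)) {
    data <- data %>%
      group_by(.data$set_id) %>%
      mutate(hypothesis_id = row_number()) %>%
      ungroup()
  }
  dup <- data %>%
    count(.data$set_id, .data$hypothesis_id) %>%
    filter(.data$n > 1L)
  if (nrow(dup)) {
    abort("`set_id` x `hypothesis_id` combinations must be unique.")
  }
  data
}
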