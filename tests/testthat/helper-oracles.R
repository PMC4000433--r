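# Independent reference implementations used as oracles.

# BH / FWER rejections via stats::p.adjust (independent of the package's
# own step-up/step-down code paths)
oracle_bh_reject <- function(p, alpha) stats::p.adjust(p, "BH") <= alpha

oracle_fwer_reject <- function(p, level, method) {
  stats::p.adjust(p, method) <= level
}

# literal transcription of the set-level error definitions: loop over sets
# and hypotheses, no vectorized shortcuts
brute_count_errors <- function(report_tidy, truth) {
  sets <- unique(report_tidy$set_id)
  V <- 0L; S <- 0L; R <- 0L
  for (s in sets) {
    rep_s <- report_tidy[report_tidy$set_id == s, ]
    tru_s <- truth[truth$set_id == s, ]
    tru_s <- tru_s[match(rep_s$hypothesis_id, tru_s$hypothesis_id), ]
    if (!rep_s$set_rejected[1]) next
    R <- R + 1L
    set_all_null <- all(tru_s$true_sign == 0)
    true_null_rejected <- any(rep_s$rejected & tru_s$true_sign == 0)
    if (set_all_null || true_null_rejected) {
      V <- V + 1L
    } else {
      dir_error <- any(rep_s$rejected & tru_s$true_sign != 0 &
                         rep_s$direction != tru_s$true_sign)
      if (dir_error) S <- S + 1L
    }
  }
  list(R = R, V = V, S = S)
}

# random hypothesis-set collection in long format, with matching truth;
# n_range = c(k, k) gives the constant-size case
random_collection <- function(m, n_range = c(1L, 6L), p_signal = 0.3) {
  rows <- lapply(seq_len(m), function(i) {
    sizes <- seq(n_range[1], n_range[2])
    n <- sizes[sample.int(length(sizes), 1L)]
    false_null <- stats::runif(n) < p_signal
    true_sign <- ifelse(false_null, sample(c(-1, 1), n, replace = TRUE), 0)
    p <- ifelse(false_null, stats::rbeta(n, 0.2, 6), stats::runif(n))
    stat_sign <- ifelse(
      false_null & stats::runif(n) < 0.9, true_sign,
      sample(c(-1, 1), n, replace = TRUE)
    )
    tibble::tibble(
      set_id = paste0("s", i), hypothesis_id = seq_len(n),
      p_value = p, statistic_sign = stat_sign, true_sign = true_sign
    )
  })
  out <- dplyr::bind_rows(rows)
  list(
    data = out[, c("set_id", "hypothesis_id", "p_value", "statistic_sign")],
    truth = out[, c("set_id", "hypothesis_id", "true_sign")]
  )
}

# small expression dataset with known structure for the front-end tests
make_expression_fixture <- function(n_genes = 30, categories = c("0", "10", "30"),
                                    reps = 3, n_signal = 10, effect = 3,
                                    seed = 42) {
  set.seed(seed)
  n_samp <- length(categories) * reps
  vals <- matrix(rnorm(n_genes * n_samp), n_genes, n_samp)
  rownames(vals) <- sprintf("g%03d", seq_len(n_genes))
  colnames(vals) <- paste0("s", seq_len(n_samp))
  cat_of <- rep(categories, each = reps)
  # signal genes monotonically induced across categories
  for (g in seq_len(n_signal)) {
    vals[g, ] <- vals[g, ] + effect * (match(cat_of, categories) - 1)
  }
  expression_dataset(vals, cat_of, category_levels = categories)
}
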