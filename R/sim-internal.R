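# Vectorized matrix implementations used by the Monte-Carlo runner.
# P, SGN, TS are q x m matrices (rows = within-set hypotheses, columns =
# sets); these mirror hset_test()/evaluate_decisions() for constant set
# size, and the test suite asserts the two paths agree.

col_sort <- function(P) {
  matrix(P[order(col(P), P)], nrow(P), ncol(P))
}

col_min <- function(P) {
  do.call(pmin, asplit(P, 1))
}

two_step_matrix <- function(P, SGN, alpha, method) {
  q <- nrow(P)
  m <- ncol(P)
  Ps <- col_sort(P)
  p0 <- if (method == "hochberg") {
    pmin(1, col_min(Ps * (q + 1 - seq_len(q))))
  } else {
    pmin(1, q * Ps[1L, ])
  }
  bh <- bh_step_up(p0, alpha)
  R <- bh$R
  set_rejected <- bh$rejected
  rej <- matrix(FALSE, q, m)
  if (R > 0L) {
    level <- R * alpha / m
    if (method == "bonferroni") {
      rej <- P <= level / q
    } else {
      thr <- level / (q + 1 - seq_len(q))   # recycles down each column
      ok <- Ps <= thr
      r_i <- if (method == "holm") {
        # position before the first failure, cumulated down the rows
        colSums(do.call(rbind, Reduce(`&`, asplit(ok, 1), accumulate = TRUE)))
      } else {
        # last row where the step-up condition holds
        do.call(pmax, asplit(ok * seq_len(q), 1))
      }
      cutoff <- rep(-1, m)
      pos <- r_i > 0
      cutoff[pos] <- Ps[r_i[pos] + (which(pos) - 1L) * q]
      rej <- P <= rep(cutoff, each = q)
    }
    rej <- rej & rep(set_rejected, each = q)
  } else {
    set_rejected <- rep(FALSE, m)
  }
  list(rej = rej, dir = sign(SGN) * rej, set_rejected = set_rejected,
       screening_p = p0, R = R)
}

simple_bh_matrix <- function(P, SGN, alpha) {
  q <- nrow(P)
  m <- ncol(P)
  bh <- bh_step_up(as.vector(P), alpha)
  rej <- matrix(bh$rejected, q, m)
  set_rejected <- colSums(rej) > 0L
  list(rej = rej, dir = sign(SGN) * rej, set_rejected = set_rejected,
       screening_p = rep(NA_real_, m), R = as.integer(sum(set_rejected)))
}

# one-replication error/power summary; TS = matrix of true signs
eval_matrix <- function(res, TS, strict_direction = TRUE) {
  rej <- res$rej
  dir <- res$dir
  sr <- res$set_rejected
  false_null <- TS != 0
  all_null_set <- colSums(false_null) == 0L
  false_rej_set <- colSums(rej & !false_null) > 0L
  v <- sr & (all_null_set | false_rej_set)
  dir_err_set <- colSums(rej & false_null & dir != TS) > 0L
  s <- sr & !v & dir_err_set
  R <- sum(sr); V <- sum(v); S <- sum(s)

  n_false <- sum(false_null)
  power_i <- if (n_false > 0L) {
    hit <- if (strict_direction) rej & false_null & dir == TS else rej & false_null
    sum(hit) / n_false
  } else NA_real_
  fns <- !all_null_set
  power_ii <- if (any(fns)) {
    correct_hyp <- (!false_null & !rej) |
      (false_null & rej & (if (strict_direction) dir == TS else TRUE))
    sum(fns & colSums(!correct_hyp) == 0L) / sum(fns)
  } else NA_real_

  c(R = R, V = V, S = S,
    ofdr = V / max(R, 1), mdfdr = (V + S) / max(R, 1),
    power_i = power_i, power_ii = power_ii)
}
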