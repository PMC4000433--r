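#' Draw standardized effect sizes for a time-course simulation
#'
#' Generates the matrix of standardized successive differences
#' \eqn{\delta_{ij} = (\mu_{j+1,i} - \mu_{ji})/\sqrt 2} for `m` genes and
#' `q` successive comparisons. `m0` genes (chosen uniformly at random) are
#' true-null with a zero effect vector; the remaining `m - m0` false-null
#' genes are partitioned among the mixture components in the given
#' proportions (largest-remainder apportionment, any leftover assigned at
#' random), and each of their `q` components is drawn i.i.d. uniform from
#' the component's interval. The default mixture — 50% near-null effects in
#' (-0.75, 0.75), 25% strong negative in (-4.25, -2.75), 25% strong
#' positive in (2.75, 4.25) — mimics a time-course microarray experiment
#' with a mass of weak changes and symmetric strong responders.
#'
#' Uses the current R random number generator state; call `set.seed()`
#' first for reproducibility.
#'
#' @param m Number of genes (hypothesis sets).
#' @param m0 Number of true-null genes, `0 <= m0 <= m`.
#' @param q Number of successive comparisons per gene.
#' @param mixture Proportions over the effect intervals; must sum to 1.
#' @param intervals List of `(lower, upper)` pairs, one per mixture
#'   component.
#'
#' @return A list with
#'   \describe{
#'     \item{delta}{`q x m` numeric matrix of standardized effects;}
#'     \item{truth}{tibble with `set_id`, `hypothesis_id`, `true_sign`,
#'       suitable for [evaluate_decisions()].}
#'   }
#' @export
draw_effects <- function(m, m0, q = 5,
                         mixture = c(0.5, 0.25, 0.25),
                         intervals = list(c(-0.75, 0.75),
                                          c(-4.25, -2.75),
                                          c(2.75, 4.25))) {
  delta <- draw_effects_matrix(m, m0, q, mixture, intervals)
  list(delta = delta, truth = truth_from_delta(delta))
}

draw_effects_matrix <- function(m, m0, q, mixture, intervals) {
  stopifnot(m >= 1, m0 >= 0, m0 <= m, q >= 1)
  if (length(mixture) != length(intervals)) {
    abort("`mixture` and `intervals` must have the same length.")
  }
  if (abs(sum(mixture) - 1) > 1e-8 || any(mixture < 0)) {
    abort("`mixture` proportions must be non-negative and sum to 1.")
  }
  delta <- matrix(0, q, m)
  k <- m - m0
  if (k > 0L) {
    false_idx <- if (k == m) sample.int(m) else sample.int(m, k)
    sizes <- largest_remainder(k, mixture)
    grp <- rep.int(seq_along(sizes), sizes)
    for (g in seq_along(intervals)) {
      genes <- false_idx[grp == g]
      if (length(genes)) {
        delta[, genes] <- runif(q * length(genes),
                                intervals[[g]][1], intervals[[g]][2])
      }
    }
  }
  delta
}

# integer apportionment of n into proportions; leftover seats go to the
# largest fractional remainders, ties broken at random
largest_remainder <- function(n, prop) {
  raw <- n * prop
  sizes <- floor(raw)
  left <- n - sum(sizes)
  if (left > 0L) {
    frac <- raw - sizes
    ord <- order(frac, runif(length(frac)), decreasing = TRUE)
    sizes[ord[seq_len(left)]] <- sizes[ord[seq_len(left)]] + 1L
  }
  as.integer(sizes)
}

truth_from_delta <- function(delta, gene_ids = NULL) {
  q <- nrow(delta)
  m <- ncol(delta)
  if (is.null(gene_ids)) gene_ids <- seq_len(m)
  tibble(
    set_id = rep(gene_ids, each = q),
    hypothesis_id = rep(seq_len(q), times = m),
    true_sign = as.vector(sign(delta))
  )
}

#' Draw equicorrelated normal expression data
#'
#' Simulates the expression matrix `Z` (`q + 1` time points by `m` genes)
#' with unit-variance normal margins \eqn{Z_{ji} \sim N(\mu_{ji}, 1)} and a
#' common pairwise correlation `rho` across genes within each time point;
#' time points are mutually independent. Equicorrelation is generated by a
#' single shared factor per time point,
#' \eqn{Z_j = \mu_j + \sqrt\rho\, W_j + \sqrt{1-\rho}\,\epsilon_j},
#' which is exact in distribution and O(m) per draw. The means accumulate
#' the standardized effects: \eqn{\mu_{1} = 0} and
#' \eqn{\mu_{j+1} = \mu_j + \sqrt 2\, \delta_j} (only successive
#' differences matter, so the baseline is arbitrary).
#'
#' @param delta `q x m` matrix of standardized successive differences, as
#'   from [draw_effects()].
#' @param rho Common within-time-point correlation across genes, in
#'   `[0, 1)`.
#' @return A `(q + 1) x m` numeric matrix of expression values.
#' @export
draw_expression <- function(delta, rho = 0) {
  if (!is.matrix(delta)) abort("`delta` must be a q x m matrix.")
  if (!is.numeric(rho) || length(rho) != 1L || rho < 0 || rho >= 1) {
    abort("`rho` must be a single correlation in [0, 1).")
  }
  q <- nrow(delta)
  m <- ncol(delta)
  steps <- apply(delta * sqrt(2), 2, cumsum)
  if (q == 1L) steps <- matrix(steps, 1L, m)
  mu <- rbind(0, steps)
  W <- rnorm(q + 1L)
  E <- matrix(rnorm((q + 1L) * m), q + 1L, m)
  mu + sqrt(rho) * W + sqrt(1 - rho) * E
}

#' Successive-difference z-tests on a simulated expression matrix
#'
#' For each gene `i` and each pair of successive time points, computes the
#' statistic \eqn{T_{ij} = (Z_{j+1,i} - Z_{ji})/\sqrt 2}, which is standard
#' normal under the null \eqn{\delta_{ij} = 0} (each `Z` has unit
#' variance), and the two-sided p-value \eqn{p = 2\{1 - \Phi(|T|)\}}.
#'
#' @param Z Numeric matrix of expression values, time points in rows
#'   (at least 2) and genes in columns.
#' @param gene_ids Optional identifiers for the columns of `Z`.
#' @return A tibble in the long hypothesis-set format accepted by
#'   [hset_test()]: `set_id`, `hypothesis_id`, `p_value`,
#'   `statistic_sign`, plus the `statistic` itself.
#' @export
successive_tests <- function(Z, gene_ids = NULL) {
  if (!is.matrix(Z) || nrow(Z) < 2L) {
    abort("`Z` must be a matrix with at least 2 time points (rows).")
  }
  m <- ncol(Z)
  if (is.null(gene_ids)) gene_ids <- seq_len(m)
  tt <- successive_tests_matrix(Z)
  q <- nrow(tt$T)
  tibble(
    set_id = rep(gene_ids, each = q),
    hypothesis_id = rep(seq_len(q), times = m),
    p_value = as.vector(tt$P),
    statistic_sign = as.vector(sign(tt$T)),
    statistic = as.vector(tt$T)
  )
}

successive_tests_matrix <- function(Z) {
  n <- nrow(Z)
  Tm <- (Z[-1L, , drop = FALSE] - Z[-n, , drop = FALSE]) / sqrt(2)
  P <- 2 * pnorm(abs(Tm), lower.tail = FALSE)
  list(T = Tm, P = P)
}

#' Simulate one complete time-course dataset
#'
#' Convenience wrapper tying together [draw_effects()],
#' [draw_expression()] and [successive_tests()]: one replication of the
#' generative model, returning both the long-format test table and the
#' ground truth needed to score decisions against it.
#'
#' @inheritParams draw_effects
#' @inheritParams draw_expression
#' @param seed Optional integer seed set before drawing.
#' @return A list with `data` (tibble for [hset_test()]), `truth` (tibble
#'   for [evaluate_decisions()]), `delta`, and `Z`.
#' @examples
#' sim <- simulate_timecourse(m = 50, m0 = 40, seed = 1)
#' fit <- hset_test(sim$data, alpha = 0.05, method = "holm")
#' evaluate_decisions(fit, sim$truth)
#' @export
simulate_timecourse <- function(m = 1000, m0 = 500, q = 5, rho = 0,
                                mixture = c(0.5, 0.25, 0.25),
                                intervals = list(c(-0.75, 0.75),
                                                 c(-4.25, -2.75),
                                                 c(2.75, 4.25)),
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  delta <- draw_effects_matrix(m, m0, q, mixture, intervals)
  Z <- draw_expression(delta, rho)
  list(
    data = successive_tests(Z),
    truth = truth_from_delta(delta),
    delta = delta,
    Z = Z
  )
}

#' Monte-Carlo error and power study of the set-testing procedures
#'
#' Repeatedly simulates the time-course model (`m` genes, `q` successive
#' comparisons, equicorrelation `rho` across genes, `m0` true-null genes),
#' runs each requested procedure on every replication, scores it against
#' the ground truth, and averages. All methods see the same data within a
#' replication. The defaults reproduce the reference study conditions:
#' 1000 genes, 6 time points (`q = 5`), level 0.05, effect mixture
#' 50/25/25 over `(-0.75, 0.75)`, `(-4.25, -2.75)`, `(2.75, 4.25)`, 1000
#' replications.
#'
#' @inheritParams simulate_timecourse
#' @param alpha Nominal OFDR/mdFDR level.
#' @param methods Character vector from `"bonferroni"`, `"holm"`,
#'   `"hochberg"`, `"simple_bh"`.
#' @param n_reps Number of Monte-Carlo replications.
#' @param seed Optional integer seed (one stream drives the whole
#'   experiment; identical seed and configuration give bit-identical
#'   estimates).
#' @param strict_direction Passed to the power metrics: whether a correct
#'   rejection requires the correct declared direction.
#' @param keep_reps If `TRUE`, the returned tibble carries the
#'   per-replication results as attribute `"replications"`.
#'
#' @return A tibble with one row per method: `method`, `m`, `m0`, `rho`,
#'   `alpha`, `n_reps`, the Monte-Carlo means `ofdr`, `mdfdr`, `power_i`,
#'   `power_ii`, and their standard errors `*_se` (sample SD over
#'   replications divided by `sqrt(n_reps)`).
#'
#' @examples
#' run_experiment(m = 100, m0 = 50, n_reps = 20, seed = 1,
#'                methods = c("bonferroni", "hochberg"))
#' @export
run_experiment <- function(m = 1000, m0 = 500, q = 5, rho = 0, alpha = 0.05,
                           methods = c("bonferroni", "holm", "hochberg",
                                       "simple_bh"),
                           n_reps = 1000,
                           mixture = c(0.5, 0.25, 0.25),
                           intervals = list(c(-0.75, 0.75),
                                            c(-4.25, -2.75),
                                            c(2.75, 4.25)),
                           seed = NULL, strict_direction = TRUE,
                           keep_reps = FALSE) {
  methods <- match.arg(methods, several.ok = TRUE)
  check_alpha(alpha)
  if (!is.null(seed)) set.seed(seed)
  metric_names <- c("R", "V", "S", "ofdr", "mdfdr", "power_i", "power_ii")
  out <- array(
    NA_real_, dim = c(n_reps, length(methods), length(metric_names)),
    dimnames = list(NULL, methods, metric_names)
  )
  for (r in seq_len(n_reps)) {
    delta <- draw_effects_matrix(m, m0, q, mixture, intervals)
    TS <- sign(delta)
    Z <- draw_expression(delta, rho)
    tt <- successive_tests_matrix(Z)
    for (meth in methods) {
      res <- if (meth == "simple_bh") {
        simple_bh_matrix(tt$P, tt$T, alpha)
      } else {
        two_step_matrix(tt$P, tt$T, alpha, meth)
      }
      out[r, meth, ] <- eval_matrix(res, TS, strict_direction)
    }
  }
  est <- purrr::map_dfr(methods, function(meth) {
    x <- out[, meth, , drop = TRUE]
    if (n_reps == 1L) x <- matrix(x, 1L, dimnames = list(NULL, metric_names))
    mc <- function(nm) mean(x[, nm], na.rm = TRUE)
    se <- function(nm) {
      v <- x[, nm][!is.na(x[, nm])]
      if (length(v) > 1L) sd(v) / sqrt(length(v)) else NA_real_
    }
    tibble(
      method = meth, m = m, m0 = m0, rho = rho, alpha = alpha,
      n_reps = n_reps,
      ofdr = mc("ofdr"), ofdr_se = se("ofdr"),
      mdfdr = mc("mdfdr"), mdfdr_se = se("mdfdr"),
      power_i = mc("power_i"), power_i_se = se("power_i"),
      power_ii = mc("power_ii"), power_ii_se = se("power_ii")
    )
  })
  if (keep_reps) {
    reps <- purrr::map_dfr(methods, function(meth) {
      x <- out[, meth, , drop = TRUE]
      if (n_reps == 1L) x <- matrix(x, 1L, dimnames = list(NULL, metric_names))
      as_tibble(as.data.frame(x)) %>%
        mutate(method = meth, rep = row_number(), .before = 1)
    })
    attr(est, "replications") <- reps
  }
  est
}

#' Sweep the number of true-null genes
#'
#' Runs [run_experiment()] over a grid of `m0` values (the x-axis of the
#' classic mdFDR-control figure is `m - m0`, the number of false-null
#' genes) and stacks the per-method estimates.
#'
#' @inheritParams run_experiment
#' @param m0_grid Integer vector of true-null gene counts; default 11
#'   points evenly spaced from 0 to `m`.
#' @param seed Optional integer; replication `r` of each grid point uses an
#'   independent stream derived from it.
#' @return A tibble as from [run_experiment()], one row per method and
#'   grid point, with an added `n_false_sets = m - m0` column.
#' @seealso [plot_mdfdr()], [plot_power()]
#' @export
run_m0_sweep <- function(m = 1000, m0_grid = NULL, q = 5, rho = 0,
                         alpha = 0.05,
                         methods = c("bonferroni", "holm", "hochberg",
                                     "simple_bh"),
                         n_reps = 1000, seed = NULL, ...) {
  if (is.null(m0_grid)) m0_grid <- unique(round(seq(0, m, length.out = 11)))
  if (!is.null(seed)) set.seed(seed)
  purrr::map_dfr(m0_grid, function(m0) {
    run_experiment(m = m, m0 = m0, q = q, rho = rho, alpha = alpha,
                   methods = methods, n_reps = n_reps, seed = NULL, ...)
  }) %>%
    mutate(n_false_sets = .data$m - .data$m0)
}

#' Plot mdFDR estimates from an m0 sweep
#'
#' @param sweep A tibble from [run_m0_sweep()] (possibly stacked over
#'   several `rho` values).
#' @param alpha Nominal level drawn as a horizontal reference line.
#' @return A ggplot object: mdFDR (with ±2 SE ribbons) against the number
#'   of false-null sets, one line per method, facetted by `rho` when
#'   several are present.
#' @export
plot_mdfdr <- function(sweep, alpha = 0.05) {
  p <- ggplot2::ggplot(sweep, ggplot2::aes(
    x = .data$n_false_sets, y = .data$mdfdr, colour = .data$method
  )) +
    ggplot2::geom_hline(yintercept = alpha, linetype = 2) +
    ggplot2::geom_ribbon(
      ggplot2::aes(
        ymin = .data$mdfdr - 2 * .data$mdfdr_se,
        ymax = .data$mdfdr + 2 * .data$mdfdr_se,
        fill = .data$method
      ),
      alpha = 0.15, colour = NA
    ) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "number of false-null sets", y = "mdFDR") +
    ggplot2::theme_minimal()
  if (length(unique(sweep$rho)) > 1L) {
    p <- p + ggplot2::facet_wrap(~rho, labeller = ggplot2::label_both)
  }
  p
}

#' Plot power estimates from an m0 sweep
#'
#' @inheritParams plot_mdfdr
#' @param which `"power_i"` (individual-hypothesis power) or `"power_ii"`
#'   (set-wise power).
#' @return A ggplot object.
#' @export
plot_power <- function(sweep, which = c("power_i", "power_ii")) {
  which <- match.arg(which)
  ggplot2::ggplot(sweep, ggplot2::aes(
    x = .data$n_false_sets, y = .data[[which]], colour = .data$method
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(
      x = "number of false-null sets",
      y = if (which == "power_i") "power (I): individual hypotheses"
          else "power (II): hypothesis sets"
    ) +
    ggplot2::theme_minimal()
}
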