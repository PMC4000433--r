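#' Two-step hierarchical hypothesis-set test
#'
#' Tests `m` hypothesis sets (e.g. genes, each carrying the per-contrast
#' nulls of a time-course or dose-response design) while controlling false
#' discoveries at the *set* level. Step one forms a screening p-value per set
#' and selects sets with the Benjamini-Hochberg procedure at level `alpha`;
#' step two tests the individual hypotheses inside each selected set with a
#' family-wise procedure at level \eqn{R\alpha/m}, where `R` is the number of
#' selected sets. Directions of significant effects are declared from the
#' signs of the test statistics. Under independence across sets (and the
#' dependence conditions of the second-stage procedure) this controls the
#' overall false discovery rate (OFDR) and, because Bonferroni, Holm and
#' Hochberg also control directional errors, the mixed-directional FDR
#' (mdFDR) at level `alpha`.
#'
#' The three two-step methods differ in the screening formula and second
#' stage:
#' \describe{
#'   \item{bonferroni}{screening \eqn{p_0 = n\,p_{(1)}}, Bonferroni second
#'     stage (the procedure of Guo, Sarkar and Peddada);}
#'   \item{holm}{same screening p-value, Holm step-down second stage —
#'     selects exactly the same sets as `"bonferroni"` but rejects at least
#'     as many individual hypotheses;}
#'   \item{hochberg}{screening \eqn{p_0 = \min_j (n+1-j) p_{(j)}}, Hochberg
#'     step-up second stage — uniformly most powerful of the three, but
#'     needs independence or positive dependence within a set.}
#' }
#' `method = "simple_bh"` is the one-step comparator: it pools all
#' individual p-values across sets, applies Benjamini-Hochberg at `alpha`,
#' and calls a set rejected when any of its hypotheses is rejected. It
#' controls the FDR of the pooled individual hypotheses but *not* the
#' set-level OFDR/mdFDR.
#'
#' Sets may have different numbers of hypotheses. A rejected hypothesis
#' whose test statistic is exactly zero gets no declared direction (a
#' warning is raised; this has probability zero for continuous statistics).
#'
#' @param data A data frame in long format with one row per individual
#'   hypothesis and columns `set_id`, `p_value`, and optionally
#'   `hypothesis_id` (defaults to the within-set row number) and
#'   `statistic_sign` (in `{-1, 0, 1}`; defaults to 0, i.e. no directions).
#' @param alpha Nominal OFDR/mdFDR level in `(0, 1)`.
#' @param method One of `"bonferroni"`, `"holm"`, `"hochberg"`,
#'   `"simple_bh"`.
#'
#' @return An object of class `hset_test`, a list with
#'   \describe{
#'     \item{hypotheses}{tibble with `set_id`, `hypothesis_id`, `p_value`,
#'       `statistic_sign`, `rejected`, `direction`;}
#'     \item{sets}{tibble with `set_id`, `n`, `screening_p` (`NA` for
#'       `simple_bh`), `set_rejected`;}
#'     \item{alpha, method, m, R}{the level, method, number of sets and
#'       number of rejected sets;}
#'     \item{within_set_level}{the second-stage FWER level \eqn{R\alpha/m}
#'       (`NA` for `simple_bh`).}
#'   }
#'   Use [tidy.hset_test()], [glance.hset_test()] and
#'   [autoplot.hset_test()] to extract or display results.
#'
#' @examples
#' dat <- tibble::tibble(
#'   set_id = rep(c("g1", "g2"), each = 2),
#'   p_value = c(0.001, 0.5, 0.4, 0.9),
#'   statistic_sign = c(1, -1, 1, 1)
#' )
#' fit <- hset_test(dat, alpha = 0.05, method = "bonferroni")
#' fit$sets
#' tidy(fit)
#' @export
hset_test <- function(data, alpha = 0.05,
                      method = c("bonferroni", "holm", "hochberg", "simple_bh")) {
  method <- match.arg(method)
  check_alpha(alpha)
  data <- check_hset_data(data)

  set_order <- unique(data$set_id)
  m <- length(set_order)
  # list of per-set indices, in first-appearance order
  idx <- split(seq_len(nrow(data)), factor(data$set_id, levels = set_order))
  n_per_set <- lengths(idx)

  rejected <- logical(nrow(data))
  if (method == "simple_bh") {
    bh <- bh_step_up(data$p_value, alpha)
    rejected <- bh$rejected
    set_rejected <- vapply(idx, function(i) any(rejected[i]), logical(1))
    screening_p <- rep(NA_real_, m)
    R <- as.integer(sum(set_rejected))
    level <- NA_real_
  } else {
    scr_formula <- if (method == "hochberg") "hochberg" else "bonferroni"
    screening_p <- vapply(
      idx, function(i) screening_pvalue(data$p_value[i], scr_formula),
      numeric(1)
    )
    bh <- bh_step_up(screening_p, alpha)
    set_rejected <- bh$rejected
    R <- bh$R
    level <- R * alpha / m
    if (R > 0L) {
      for (i in which(set_rejected)) {
        rows <- idx[[i]]
        rejected[rows] <- fwer_reject(data$p_value[rows], level, method)
      }
    }
  }

  direction <- ifelse(rejected, data$statistic_sign, 0)
  if (any(rejected & data$statistic_sign == 0)) {
    warn(paste(
      "Some rejected hypotheses have a zero test statistic;",
      "no direction is declared for them."
    ))
  }

  structure(
    list(
      hypotheses = tibble(
        set_id = data$set_id,
        hypothesis_id = data$hypothesis_id,
        p_value = data$p_value,
        statistic_sign = data$statistic_sign,
        rejected = rejected,
        direction = direction
      ),
      sets = tibble(
        set_id = set_order,
        n = as.integer(n_per_set),
        screening_p = unname(screening_p),
        set_rejected = unname(set_rejected)
      ),
      alpha = alpha,
      method = method,
      m = m,
      R = R,
      within_set_level = level
    ),
    class = "hset_test"
  )
}

#' @export
print.hset_test <- function(x, ...) {
  cat("Two-step hypothesis-set test (method: ", x$method, ")\n", sep = "")
  cat(sprintf(
    "  %d sets, %d hypotheses, alpha = %g\n",
    x$m, nrow(x$hypotheses), x$alpha
  ))
  cat(sprintf(
    "  sets rejected: %d; individual rejections: %d\n",
    x$R, sum(x$hypotheses$rejected)
  ))
  if (!is.na(x$within_set_level)) {
    cat(sprintf("  within-set FWER level R*alpha/m = %g\n", x$within_set_level))
  }
  invisible(x)
}

#' Tidy a two-step hypothesis-set test
#'
#' @param x An [hset_test()] result.
#' @param ... Unused.
#' @return A tibble with one row per individual hypothesis: the input
#'   columns plus `rejected`, `direction`, and the set-level `screening_p`
#'   and `set_rejected`.
#' @export
tidy.hset_test <- function(x, ...) {
  x$hypotheses %>%
    left_join(
      select(x$sets, "set_id", "screening_p", "set_rejected"),
      by = "set_id"
    )
}

#' One-row summary of a two-step hypothesis-set test
#'
#' @param x An [hset_test()] result.
#' @param ... Unused.
#' @return A one-row tibble: `m`, `n_hypotheses`, `R` (sets rejected),
#'   `n_rejected` (individual rejections), `within_set_level`, `alpha`,
#'   `method`.
#' @export
glance.hset_test <- function(x, ...) {
  tibble(
    m = x$m,
    n_hypotheses = nrow(x$hypotheses),
    R = x$R,
    n_rejected = sum(x$hypotheses$rejected),
    within_set_level = x$within_set_level,
    alpha = x$alpha,
    method = x$method
  )
}

#' Plot the screening stage of a hypothesis-set test
#'
#' Shows the sorted screening p-values (or, for `simple_bh`, the pooled
#' individual p-values) against the Benjamini-Hochberg step-up line
#' \eqn{k\alpha/m}; filled points are rejected.
#'
#' @param object An [hset_test()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hset_test <- function(object, ...) {
  if (object$method == "simple_bh") {
    df <- object$hypotheses %>%
      select(p = "p_value", "rejected") %>%
      arrange(.data$p)
  } else {
    df <- object$sets %>%
      select(p = "screening_p", rejected = "set_rejected") %>%
      arrange(.data$p)
  }
  df$rank <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$p)) +
    ggplot2::geom_abline(
      slope = object$alpha / nrow(df), intercept = 0, linetype = 2
    ) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$rejected), size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(
      x = "rank", y = "p-value",
      title = sprintf("BH screening at alpha = %g (%s)", object$alpha, object$method)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
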