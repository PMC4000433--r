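#' Screening p-value for a hypothesis set
#'
#' Combines the individual p-values of one hypothesis set into a single
#' screening p-value for the conjunction (intersection) null: the claim that
#' every individual null in the set is true. Rejecting the screening null at
#' a given level with the matching family-wise procedure guarantees at least
#' one individual rejection at the second stage.
#'
#' With ordered p-values \eqn{p_{(1)} \le \dots \le p_{(n)}},
#' `"bonferroni"` returns \eqn{n\,p_{(1)}} and `"hochberg"` returns
#' \eqn{\min_j (n+1-j)\,p_{(j)}}, both clipped to 1. The Hochberg screening
#' p-value is never larger than the Bonferroni one. The Bonferroni formula is
#' the screening step shared by the Bonferroni- and Holm-based two-step
#' procedures, which therefore always select the same sets.
#'
#' @param p Numeric vector of individual p-values in `[0, 1]` (length
#'   \eqn{n \ge 1}).
#' @param method `"bonferroni"` or `"hochberg"`.
#'
#' @return A single p-value in `[0, 1]`.
#'
#' @examples
#' screening_pvalue(c(0.01, 0.04, 0.5, 0.8, 0.9))                 # 0.05
#' screening_pvalue(c(0.02, 0.021), method = "hochberg")          # 0.021
#' @export
screening_pvalue <- function(p, method = c("bonferroni", "hochberg")) {
  method <- match.arg(method)
  check_pvalues(p)
  n <- length(p)
  p0 <- switch(method,
    bonferroni = n * min(p),
    hochberg = {
      ps <- sort(p)
      min((n + 1L - seq_len(n)) * ps)
    }
  )
  min(1, p0)
}

#' Benjamini-Hochberg step-up selection
#'
#' Applies the Benjamini-Hochberg step-up procedure at level `alpha` to a
#' vector of p-values (here, typically the `m` screening p-values, one per
#' hypothesis set). With ordered p-values \eqn{p_{(1)} \le \dots \le p_{(m)}},
#' the number of rejections is \eqn{R = \max\{k : p_{(k)} \le k\alpha/m\}}
#' (0 if no such `k`), and exactly the p-values \eqn{\le R\alpha/m} are
#' rejected; tied p-values are rejected or retained together.
#'
#' @param p0 Numeric vector of p-values in `[0, 1]`.
#' @param alpha Nominal false discovery rate level in `(0, 1)`.
#'
#' @return A list with elements
#'   \describe{
#'     \item{rejected}{logical vector aligned with `p0`,}
#'     \item{R}{number of rejections,}
#'     \item{threshold}{the rejection cut-off \eqn{R\alpha/m},}
#'     \item{alpha}{the level used.}
#'   }
#'
#' @examples
#' bh_step_up(c(0.001, 0.01, 0.02, 0.04, 0.9), alpha = 0.05)$R  # 4
#' @export
bh_step_up <- function(p0, alpha = 0.05) {
  check_pvalues(p0)
  check_alpha(alpha)
  m <- length(p0)
  ps <- sort(p0)
  ok <- which(ps <= seq_len(m) * alpha / m)
  R <- if (length(ok)) max(ok) else 0L
  threshold <- R * alpha / m
  list(
    rejected = p0 <= threshold,
    R = as.integer(R),
    threshold = threshold,
    alpha = alpha
  )
}

#' Within-set family-wise rejections at a given level
#'
#' Runs one of the classical family-wise error rate (FWER) controlling
#' procedures on the individual p-values of a single hypothesis set, at the
#' within-set level handed down by the screening stage (\eqn{R\alpha/m} in
#' the two-step procedures).
#'
#' With ordered p-values \eqn{p_{(1)} \le \dots \le p_{(n)}}:
#' \describe{
#'   \item{bonferroni}{rejects every \eqn{p_j \le \mathrm{level}/n};}
#'   \item{holm}{step-down: finds the largest `j` such that
#'     \eqn{p_{(l)} \le \mathrm{level}/(n+1-l)} for all \eqn{l \le j},
#'     then rejects every \eqn{p \le p_{(j)}};}
#'   \item{hochberg}{step-up: finds the largest `j` such that
#'     \eqn{p_{(j)} \le \mathrm{level}/(n+1-j)}, then rejects every
#'     \eqn{p \le p_{(j)}}.}
#' }
#' At equal level the rejection sets are nested:
#' Bonferroni \eqn{\subseteq} Holm \eqn{\subseteq} Hochberg. Bonferroni and
#' Holm control the FWER under arbitrary dependence; Hochberg requires
#' independence or positive dependence among the individual statistics. All
#' three also control directional errors for independent two-sided
#' t-statistics, which is what makes them valid second stages for
#' mixed-directional FDR control.
#'
#' @param p Numeric vector of p-values in `[0, 1]` for one set.
#' @param level FWER level in `(0, 1]`.
#' @param method `"bonferroni"`, `"holm"` or `"hochberg"`.
#'
#' @return Logical vector: which hypotheses are rejected.
#'
#' @examples
#' fwer_reject(c(0.002, 0.018, 0.3), level = 0.05, method = "holm")
#' @export
fwer_reject <- function(p, level, method = c("bonferroni", "holm", "hochberg")) {
  method <- match.arg(method)
  check_pvalues(p)
  if (!is.numeric(level) || length(level) != 1L || is.na(level) ||
      level <= 0 || level > 1) {
    abort("`level` must be a single number in (0, 1].")
  }
  n <- length(p)
  if (method == "bonferroni") {
    return(p <= level / n)
  }
  ps <- sort(p)
  thr <- level / (n + 1L - seq_len(n))
  ok <- ps <= thr
  r_i <- if (method == "holm") {
    # step-down: stop at the first failure
    match(FALSE, ok, nomatch = n + 1L) - 1L
  } else {
    # step-up: last success
    if (any(ok)) max(which(ok)) else 0L
  }
  if (r_i == 0L) rep(FALSE, n) else p <= ps[r_i]
}
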