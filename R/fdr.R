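#' Benjamini-Hochberg adjusted p-values
#'
#' Standard linear step-up adjustment: sort ascending, multiply
#' `p_(k)` by `m/k`, enforce monotone non-increase from the largest rank,
#' cap at 1, and return in input order.  Delegates to
#' [stats::p.adjust()] after validation; serves as the building block and
#' reference for the two-stage procedure's BH stages.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in input order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))  # all 0.03
bh_adjust <- function(p_values) {
  .check_pvalues(p_values)
  stats::p.adjust(p_values, method = "BH")
}

# Number of rejections of the two-stage step-up procedure on *sorted*
# p-values.  Stage 1 is BH step-up at level q' = q/(1+q) with m hypotheses,
# giving r1 rejections and the null estimate m0 = m - r1; stage 2 reruns
# the step-up with m0 in the denominator.  r1 = 0 accepts everything and
# r1 = m rejects everything, per the original procedure.  Because the
# rejected set of a step-up procedure is a prefix of the sorted order, the
# count fully determines the decisions.
.bky_count <- function(ps, q_target) {
  m <- length(ps)
  qp <- q_target / (1 + q_target)
  k <- seq_len(m)
  idx <- which(ps <= k * qp / m)
  r1 <- if (length(idx)) max(idx) else 0L
  if (r1 == 0L) return(0L)
  if (r1 == m) return(m)
  m0 <- m - r1
  idx <- which(ps <= k * qp / m0)
  if (length(idx)) max(idx) else 0L
}

#' Two-stage step-up FDR procedure of Benjamini, Krieger and Yekutieli
#'
#' The adaptive FDR procedure used to call differential interactors at a
#' desired FDR level `q_target`.  Stage 1 runs the Benjamini-Hochberg
#' step-up at the shrunken level `q' = q_target / (1 + q_target)`; its
#' rejection count `r1` yields the estimated number of true nulls
#' `m0 = m - r1`.  If `0 < r1 < m`, stage 2 reruns the step-up at level
#' `q'` with `m0` replacing `m` (reject rank `k` iff
#' `p_(k) <= k * q' / m0`); `r1 = 0` rejects nothing and `r1 = m` rejects
#' everything.  Tied p-values share the larger rank's threshold, the usual
#' step-up behaviour.
#'
#' q-values are computed by [q_values_by_search()]: the q-value of a
#' hypothesis is the smallest desired-FDR level (on a grid of step
#' `q_grid`) at which the procedure rejects it.  Since the rejection set is
#' nondecreasing in the level, `rejected[h]` is equivalent to
#' `q_values[h] <= q_target` whenever `q_target` is a grid multiple.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param q_target Desired FDR level in (0, 1); default 0.10.
#' @param q_grid Grid step for the q-value search (default `1e-4`); set
#'   `compute_q = FALSE` to skip the search.
#' @param compute_q Compute q-values (default `TRUE`).
#' @return An `fdr_result`: list with `m`, `q_target`, `q_prime`, `r1`,
#'   `m0_hat`, `rejected` (logical, input order) and `q_values` (input
#'   order, or `NULL`).
#' @references Benjamini, Y., Krieger, A. M. & Yekutieli, D. (2006)
#'   Adaptive linear step-up procedures that control the false discovery
#'   rate. Biometrika 93, 491-507.
#' @seealso [q_values_by_search()], [bh_adjust()]
#' @export
#' @examples
#' res <- bky_two_stage(c(0.001, 0.2, 0.9), q_target = 0.05)
#' res$rejected  # TRUE FALSE FALSE
bky_two_stage <- function(p_values, q_target = 0.10, q_grid = 1e-4,
                          compute_q = TRUE) {
  .check_pvalues(p_values)
  .assert(is.numeric(q_target) && length(q_target) == 1L &&
            q_target > 0 && q_target < 1,
          "apms_validation_error", "q_target must lie in (0, 1)")
  m <- length(p_values)
  o <- order(p_values)
  ps <- p_values[o]
  qp <- q_target / (1 + q_target)
  k <- seq_len(m)
  idx <- which(ps <= k * qp / m)
  r1 <- if (length(idx)) max(idx) else 0L
  n_rej <- .bky_count(ps, q_target)
  rejected <- logical(m)
  if (n_rej > 0L) rejected[o[seq_len(n_rej)]] <- TRUE
  qv <- if (isTRUE(compute_q)) q_values_by_search(p_values, grid = q_grid) else NULL
  structure(list(m = m,
                 q_target = q_target,
                 q_prime = qp,
                 r1 = as.integer(r1),
                 m0_hat = as.integer(m - r1),
                 n_rejected = as.integer(n_rej),
                 rejected = rejected,
                 q_values = qv),
            class = "fdr_result")
}

#' @export
print.fdr_result <- function(x, ...) {
  cat(sprintf(
    "two-stage step-up FDR: m = %d, q = %g (q' = %.4g), r1 = %d, m0 = %d, rejected = %d\n",
    x$m, x$q_target, x$q_prime, x$r1, x$m0_hat, x$n_rejected))
  invisible(x)
}

#' Search-based q-values for the two-stage procedure
#'
#' Defines the q-value of each hypothesis as the smallest desired-FDR
#' level, on a grid of step `grid` spanning (0, 1], at which the two-stage
#' step-up procedure rejects it (1 if it is never rejected on the grid).
#' Because the rejection set is a prefix of the p-value order and grows
#' monotonically with the level, the search runs as a binary search per
#' rank over the grid; the resulting q-values are monotone in p by
#' construction, and tied p-values share a q-value.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param grid Grid step (level resolution), default `1e-4`.
#' @return Numeric q-values in input order.
#' @seealso [bky_two_stage()], [bky_q_values_closed()]
#' @export
q_values_by_search <- function(p_values, grid = 1e-4) {
  .check_pvalues(p_values)
  .assert(is.numeric(grid) && length(grid) == 1L && grid > 0 && grid < 1,
          "apms_validation_error", "grid must lie in (0, 1)")
  G <- as.integer(round(1 / grid))
  m <- length(p_values)
  o <- order(p_values)
  ps <- p_values[o]
  qv_sorted <- rep(1, m)
  # highest admissible level on the grid is 1 - grid (q_target must be < 1)
  top <- G - 1L
  max_rej <- .bky_count(ps, top / G)
  lo <- 1L
  for (r in seq_len(m)) {
    if (r > max_rej) break
    l <- lo
    h <- top
    while (l < h) {
      mid <- (l + h) %/% 2L
      if (.bky_count(ps, mid / G) >= r) h <- mid else l <- mid + 1L
    }
    qv_sorted[r] <- l / G
    lo <- l
  }
  out <- numeric(m)
  out[o] <- qv_sorted
  out
}

#' Closed-form adaptive q-values (approximate variant)
#'
#' A labelled alternative q-value definition in the style of BH adjusted
#' p-values scaled by the estimated null fraction: with `m0` estimated by
#' the stage-1 pass at `q_target`, the rank-`k` value is
#' `p_(k) * m0 / k`, monotonized from the largest rank and capped at 1 --
#' i.e. `bh_adjust(p) * m0 / m`.  This closed form can differ from the
#' search-based definition of [q_values_by_search()] in the second decimal
#' because it ignores the level-dependence of `m0` and the `q/(1+q)`
#' shrinkage; the search-based definition is the one consistent with the
#' procedure's rejection decisions.
#'
#' @inheritParams bky_two_stage
#' @return Numeric q-values in input order.
#' @export
bky_q_values_closed <- function(p_values, q_target = 0.10) {
  .check_pvalues(p_values)
  m <- length(p_values)
  o <- order(p_values)
  ps <- p_values[o]
  qp <- q_target / (1 + q_target)
  k <- seq_len(m)
  idx <- which(ps <= k * qp / m)
  r1 <- if (length(idx)) max(idx) else 0L
  m0 <- m - r1
  if (m0 == 0L) return(rep(0, m))
  adj <- rev(cummin(rev(pmin(1, ps * m0 / k))))
  out <- numeric(m)
  out[o] <- adj
  out
}
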