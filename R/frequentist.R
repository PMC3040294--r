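#' Exact Poisson p-values for area counts
#'
#' Tests the per-area null `RR = 1` (the count is Poisson with mean equal to
#' the expected count) using exact Poisson tail probabilities -- no normal
#' approximation. The upper tail is `Prob(Y >= y)`, the lower `Prob(Y <= y)`,
#' and the two-sided p-value doubles the smaller tail, capped at one. The
#' doubling rule keeps the two-sided p monotone in each tail.
#'
#' @param y observed count(s), non-negative integers.
#' @param e expected count(s) under indirect standardization, positive.
#' @param sided `"two"` (default), `"upper"` or `"lower"`.
#' @return Vector of p-values in `[0, 1]`, recycled over `y` and `e`.
#' @examples
#' poisson_pvalue(0, 2, "lower")   # exp(-2)
#' poisson_pvalue(10, 5, "two")
#' @export
poisson_pvalue <- function(y, e, sided = c("two", "upper", "lower")) {
  sided <- match.arg(sided)
  if (any(!is.finite(e) | e <= 0))
    stop("expected counts must be positive", call. = FALSE)
  if (any(!is.finite(y) | y < 0))
    stop("observed counts must be non-negative", call. = FALSE)
  upper <- stats::ppois(y - 1, e, lower.tail = FALSE)
  lower <- stats::ppois(y, e)
  switch(sided,
         upper = upper,
         lower = lower,
         two = pmin(1, 2 * pmin(upper, lower)))
}

#' Bonferroni family-wise error control
#'
#' Rejects area `i` when `p_i <= alpha / m`, guaranteeing that the
#' probability of any false rejection is at most `alpha`.
#'
#' @param pvals vector of p-values.
#' @param alpha family-wise error level in (0, 1).
#' @return Integer 0/1 rejection flags aligned with `pvals`.
#' @export
bonferroni <- function(pvals, alpha = 0.05) {
  .check_pvals(pvals)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must be a single value in (0, 1)", call. = FALSE)
  as.integer(pvals <= alpha / length(pvals))
}

#' Benjamini-Hochberg step-up procedure (plain and adaptive)
#'
#' The step-up rule on ordered p-values with thresholds
#' `(k/m) * level / pi0`: find the largest rank `k` whose ordered p-value
#' is below its threshold and reject every hypothesis with a p-value at or
#' below that ordered p-value. With `pi0 = 1` this is the plain BH
#' procedure controlling the FDR at `level`; supplying an estimate of the
#' proportion of true nulls gives the adaptive variant. Rejection is
#' determined by the p-value itself, so tied p-values always share a fate.
#'
#' @param pvals vector of p-values.
#' @param level target false discovery rate in (0, 1).
#' @param pi0 proportion of true nulls in (0, 1]; default 1 (plain BH).
#' @return Integer 0/1 rejection flags aligned with `pvals`.
#' @seealso [qvalues()], which thresholds to exactly the same rejection set.
#' @export
bh_procedure <- function(pvals, level = 0.05, pi0 = 1) {
  .check_pvals(pvals)
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1)
    stop("level must be a single value in (0, 1)", call. = FALSE)
  if (!is.numeric(pi0) || length(pi0) != 1L || pi0 <= 0 || pi0 > 1)
    stop("pi0 must be in (0, 1]", call. = FALSE)
  m <- length(pvals)
  ps <- sort(pvals)
  ok <- which(ps <= seq_len(m) / m * level / pi0)
  if (!length(ok)) return(integer(m))
  as.integer(pvals <= ps[max(ok)])
}

#' Storey's estimator of the proportion of true nulls
#'
#' Counts the p-values above a tuning threshold `lambda`, where alternatives
#' are rare, and scales by the expected fraction of nulls above it:
#' `pi0_hat = #\{p > lambda\} / ((1 - lambda) m)`, capped at one. The fixed
#' `lambda = 0.5` default is the canonical choice; smoothing over a lambda
#' grid is deliberately not implemented.
#'
#' @param pvals vector of p-values.
#' @param lambda tuning threshold in (0, 1); default 0.5.
#' @return Estimated proportion of true null hypotheses in (0, 1].
#' @export
estimate_pi0 <- function(pvals, lambda = 0.5) {
  .check_pvals(pvals)
  if (!is.numeric(lambda) || length(lambda) != 1L ||
      lambda <= 0 || lambda >= 1)
    stop("lambda must be a single value in (0, 1)", call. = FALSE)
  min(1, sum(pvals > lambda) / ((1 - lambda) * length(pvals)))
}

#' Storey q-values
#'
#' The q-value of an area is the minimum positive false discovery rate
#' attainable when rejecting at its p-value or beyond:
#' `q_(i) = min over k >= i of pi0 * m * p_(k) / k`, mapped back to input
#' order. Thresholding q-values at a level rejects exactly the adaptive
#' Benjamini-Hochberg set at that level with the same `pi0`.
#'
#' @param pvals vector of p-values.
#' @param pi0 proportion of true nulls in (0, 1]; default estimate from
#'   [estimate_pi0()] at `lambda = 0.5`.
#' @return Vector of q-values aligned with `pvals`, monotone in p.
#' @export
qvalues <- function(pvals, pi0 = estimate_pi0(pvals)) {
  .check_pvals(pvals)
  if (!is.numeric(pi0) || length(pi0) != 1L || pi0 <= 0 || pi0 > 1)
    stop("pi0 must be in (0, 1]", call. = FALSE)
  m <- length(pvals)
  o <- order(pvals)
  q_sorted <- rev(cummin(rev(pi0 * m * pvals[o] / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}

.check_pvals <- function(pvals) {
  if (!length(pvals))
    stop("empty p-value vector", call. = FALSE)
  if (any(!is.finite(pvals) | pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  invisible(TRUE)
}

#' Run the full frequentist screen on an area table
#'
#' Computes SMRs, exact Poisson p-values, Storey's `pi0` estimate and
#' q-values, and the rejection flags of each multiple-testing procedure
#' (Bonferroni at `alpha`, plain BH at `fdr_level`, q-value threshold at
#' `q_threshold`).
#'
#' @param table an [area_table()].
#' @param alpha family-wise level for Bonferroni (default 0.05).
#' @param fdr_level FDR level for plain BH (default 0.05).
#' @param q_threshold q-value cut-off for flagging (default 0.2, the
#'   cut-off used for procedure comparisons).
#' @param lambda tuning threshold for [estimate_pi0()].
#' @param sided sidedness of the exact Poisson test (default two-sided).
#' @return A data frame of class `poisson_screen` with columns `area_id`,
#'   `smr`, `expected`, `p_value`, `q_value`, `reject_bonferroni`,
#'   `reject_bh`, `reject_q`; the `pi0` estimate and the thresholds are
#'   attached as attributes.
#' @examples
#' map <- generate_map(5, 5, seed = 1)
#' screen <- poisson_screen(map$table)
#' head(screen)
#' attr(screen, "pi0")
#' @export
poisson_screen <- function(table, alpha = 0.05, fdr_level = 0.05,
                           q_threshold = 0.2, lambda = 0.5,
                           sided = "two") {
  stopifnot(inherits(table, "area_table"))
  p <- poisson_pvalue(table$observed, table$expected, sided = sided)
  pi0 <- estimate_pi0(p, lambda = lambda)
  q <- qvalues(p, pi0 = pi0)
  out <- data.frame(area_id = table$area_id,
                    smr = table$observed / table$expected,
                    expected = table$expected,
                    p_value = p,
                    q_value = q,
                    reject_bonferroni = bonferroni(p, alpha),
                    reject_bh = bh_procedure(p, fdr_level),
                    reject_q = as.integer(q <= q_threshold),
                    stringsAsFactors = FALSE)
  attr(out, "pi0") <- pi0
  attr(out, "alpha") <- alpha
  attr(out, "fdr_level") <- fdr_level
  attr(out, "q_threshold") <- q_threshold
  class(out) <- c("poisson_screen", "data.frame")
  out
}

#' Exact Poisson funnel-plot control limits
#'
#' For each expected count `e` on a grid, computes conservative two-sided
#' control limits for the SMR under the null `RR = 1`: the lower limit is
#' the largest `y/e` with `Prob(Y <= y) <= alpha/2` and the upper limit the
#' smallest `y/e` with `Prob(Y >= y) <= alpha/2`, `Y ~ Poisson(e)`. Because
#' the Poisson is discrete the achieved coverage is at least nominal, and
#' the limit curves carry a sawtooth rather than narrowing strictly with
#' precision. When no count in the lower tail is rejectable the lower limit
#' is reported as 0.
#'
#' When observed p-values and a q-value threshold are supplied, a second,
#' multiplicity-adjusted pair of curves is added: the implied per-test
#' p-value cut-off (the largest observed p with q-value at or below the
#' threshold -- data-dependent by construction) replaces `alpha`. If
#' nothing survives the q threshold the adjusted curves are degenerate
#' (lower 0, upper `Inf`).
#'
#' @param e_grid positive, strictly increasing grid of expected counts.
#' @param alpha per-test two-sided level for the unadjusted curves.
#' @param pvals optional observed p-values (needed for adjusted curves).
#' @param q_threshold optional q-value threshold for the adjusted curves.
#' @param pi0 proportion of true nulls passed to [qvalues()] when
#'   converting the q threshold; defaults to [estimate_pi0()] on `pvals`.
#' @return A data frame of class `funnel_limits` with columns `expected`,
#'   `lower`, `upper`, `level` (label of the rule that produced the curve).
#' @export
funnel_limits <- function(e_grid, alpha = 0.05, pvals = NULL,
                          q_threshold = NULL,
                          pi0 = if (!is.null(pvals)) estimate_pi0(pvals)) {
  if (any(!is.finite(e_grid) | e_grid <= 0))
    stop("expected-count grid must be positive", call. = FALSE)
  if (is.unsorted(e_grid, strictly = TRUE))
    stop("expected-count grid must be strictly increasing", call. = FALSE)
  out <- .funnel_curve(e_grid, alpha)
  out$level <- sprintf("p<%g", alpha)
  if (!is.null(q_threshold)) {
    if (is.null(pvals))
      stop("adjusted funnel curves need the observed p-values", call. = FALSE)
    q <- qvalues(pvals, pi0 = pi0)
    hits <- pvals[q <= q_threshold]
    if (length(hits)) {
      adj <- .funnel_curve(e_grid, max(hits))
    } else {
      adj <- data.frame(expected = e_grid, lower = 0, upper = Inf)
    }
    adj$level <- sprintf("q<%g", q_threshold)
    out <- rbind(out, adj)
  }
  class(out) <- c("funnel_limits", "data.frame")
  out
}

# conservative discrete two-sided limits at per-test level `alpha`
.funnel_curve <- function(e_grid, alpha) {
  half <- alpha / 2
  lo <- vapply(e_grid, function(e) {
    y <- stats::qpois(half, e)
    if (stats::ppois(y, e) > half) y <- y - 1L
    if (y < 0) 0 else y / e
  }, numeric(1))
  hi <- vapply(e_grid, function(e) {
    (stats::qpois(1 - half, e) + 1L) / e
  }, numeric(1))
  data.frame(expected = e_grid, lower = lo, upper = hi)
}
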