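# brute-force pmf-summation oracle for exact Poisson tails
oracle_upper <- function(y, e) sum(dpois(y:(y + 60 * ceiling(sqrt(e) + e)), e))
oracle_two <- function(y, e) min(1, 2 * min(oracle_upper(y, e),
                                            sum(dpois(0:y, e))))

test_that("exact Poisson p-values match closed forms and the pmf oracle", {
  expect_equal(poisson_pvalue(0, 2, "upper"), 1)
  expect_equal(poisson_pvalue(0, 2, "lower"), exp(-2))
  # frozen from the pmf-summation oracle: y=10, e=5, two-sided
  expect_equal(poisson_pvalue(10, 5, "two"), 0.0636561146124096,
               tolerance = 1e-12)
  expect_equal(poisson_pvalue(10, 5, "two"), oracle_two(10, 5),
               tolerance = 1e-10)
  # vectorized over a grid, against the oracle
  set.seed(1)
  y <- rpois(20, 4); e <- runif(20, 0.5, 12)
  expect_equal(poisson_pvalue(y, e, "two"),
               mapply(oracle_two, y, e), tolerance = 1e-8)
  expect_error(poisson_pvalue(1, 0), "positive")
})

test_that("Bonferroni rejects at the alpha/m per-test threshold", {
  expect_equal(bonferroni(c(0.0001, 0.02, 0.2), 0.05), c(1L, 0L, 0L))
  expect_equal(bonferroni(rep(1, 10), 0.05), rep(0L, 10))
  # one p-value below the 0.05/287 per-test threshold, the rest above it
  p <- rep(0.06 / 287, 287); p[123] <- 0.04 / 287
  expect_equal(which(bonferroni(p, 0.05) == 1L), 123L)
  expect_error(bonferroni(numeric(0)), "empty")
})

# direct enumeration oracle for the step-up rule
oracle_bh <- function(p, level, pi0 = 1) {
  m <- length(p); o <- order(p); ps <- p[o]
  ok <- which(ps <= seq_len(m) / m * level / pi0)
  if (!length(ok)) return(integer(m))
  as.integer(p <= ps[max(ok)])
}

test_that("the BH step-up rule matches direct enumeration", {
  # frozen from the enumeration oracle: third p-value 0.04 exceeds its
  # threshold 3/4 * 0.05 = 0.0375, so exactly the first two are rejected
  expect_equal(bh_procedure(c(0.001, 0.01, 0.04, 0.8), 0.05),
               c(1L, 1L, 0L, 0L))
  expect_equal(bh_procedure(0.04, 0.05), 1L)        # m=1 is the plain test
  expect_equal(bh_procedure(c(0.3, 0.6, 0.9), 0.05), rep(0L, 3))
  # plain BH agrees with p.adjust on random vectors
  set.seed(42)
  for (i in 1:25) {
    p <- runif(60)^sample(1:3, 1)
    expect_identical(bh_procedure(p, 0.1),
                     as.integer(p.adjust(p, "BH") <= 0.1))
  }
})

test_that("Storey's pi0 estimator counts the upper tail and caps at one", {
  expect_equal(estimate_pi0(runif(10, 0.6, 1), lambda = 0.5), 1)
  p_unif <- (seq_len(100) - 0.5) / 100
  expect_equal(estimate_pi0(p_unif, 0.5), 1)
  # counting oracle: 90 uniform-grid nulls plus 10 tiny p-values
  p_mix <- c((seq_len(90) - 0.5) / 90, rep(1e-6, 10))
  expect_equal(estimate_pi0(p_mix, 0.5),
               sum(p_mix > 0.5) / (0.5 * 100))
  expect_equal(estimate_pi0(p_mix, 0.5), 0.9, tolerance = 0.02)
})

test_that("q-values minimize the pFDR bound over tail ranks", {
  expect_equal(qvalues(0.05, pi0 = 1), 0.05)
  expect_equal(qvalues(c(0.01, 0.01), pi0 = 1), c(0.01, 0.01))
  # frozen from the enumeration oracle
  expect_equal(qvalues(c(0.001, 0.02, 0.9), pi0 = 1), c(0.003, 0.03, 0.9))

  set.seed(5)
  p <- runif(200)^2
  q <- qvalues(p, pi0 = 0.8)
  # monotone in p
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  # invariant to input ordering
  perm <- sample(200)
  expect_equal(qvalues(p[perm], pi0 = 0.8), q[perm])
  # sandwich bound at every rank: pi0 p_(i) <= q_(i) <= pi0 m p_(i) / i
  o <- order(p)
  expect_true(all(q[o] <= 0.8 * 200 * p[o] / seq_len(200) + 1e-12))
  expect_true(all(q >= 0.8 * p - 1e-12))
})

test_that("thresholding q-values equals the adaptive BH step-up", {
  set.seed(99)
  for (i in 1:60) {
    p <- runif(100)^sample(1:4, 1)
    pi0 <- runif(1, 0.3, 1)
    gamma <- runif(1, 0.01, 0.3)
    q_set <- as.integer(qvalues(p, pi0 = pi0) <= gamma)
    expect_identical(q_set, bh_procedure(p, gamma, pi0 = pi0))
    expect_identical(q_set, oracle_bh(p, gamma, pi0))
  }
})

test_that("null maps keep plain BH below its FDR level and p-values uniform", {
  set.seed(314)
  n_rep <- 200
  fdp <- numeric(n_rep)
  ks_ok <- logical(n_rep)
  m <- 287
  ks_crit_1pct <- 1.63 / sqrt(m)     # asymptotic 1% critical value
  for (i in 1:n_rep) {
    e <- exp(runif(m, log(0.5), log(200)))
    y <- rpois(m, e)                  # global null
    p <- poisson_pvalue(y, e)
    fdp[i] <- {
      fl <- bh_procedure(p, 0.05)
      if (sum(fl) > 0) 1 else 0       # every rejection is false
    }
    # discrete exact tests are conservative: compare against uniform with
    # a one-sided statistic (empirical cdf should not exceed uniform much)
    ks_ok[i] <- suppressWarnings(
      ks.test(p, "punif", alternative = "greater")$statistic) < ks_crit_1pct
  }
  mc_se <- sd(fdp) / sqrt(n_rep)
  expect_lte(mean(fdp), 0.05 + 3 * mc_se)
  expect_gte(mean(ks_ok), 0.95)
})

test_that("funnel limits carry the exact conservative Poisson tails", {
  # frozen from the pmf oracle at e=10, alpha=0.05: F(3)=0.0103<=0.025<F(4),
  # P(Y>=18)=0.0143<=0.025<P(Y>=17)
  fl <- funnel_limits(10, alpha = 0.05)
  expect_equal(fl$lower, 0.3)
  expect_equal(fl$upper, 1.8)

  grid <- c(0.5, 2, 5, 20, 80, 200)
  fl <- funnel_limits(grid, alpha = 0.05)
  expect_true(all(fl$lower <= 1 & fl$upper >= 1))
  # coverage is at least nominal at every grid point
  for (j in seq_along(grid)) {
    e <- grid[j]
    expect_lte(ppois(fl$lower[j] * e, e) - dpois(0, e) * (fl$lower[j] == 0),
               0.025 + 1e-12)
    expect_lte(ppois(fl$upper[j] * e - 1, e, lower.tail = FALSE),
               0.025 + 1e-12)
  }
  # wide alpha collapses the funnel toward the reference line
  wide <- funnel_limits(50, alpha = 0.9)
  narrow <- funnel_limits(50, alpha = 0.05)
  expect_lt(wide$upper - wide$lower, narrow$upper - narrow$lower)
  # large-e normal-approximation cross-check within 5% relative error
  fl4 <- funnel_limits(1e4, alpha = 0.05)
  expect_equal(fl4$lower, 1 - 1.96 / sqrt(1e4), tolerance = 0.05)
  expect_equal(fl4$upper, 1 + 1.96 / sqrt(1e4), tolerance = 0.05)
  expect_error(funnel_limits(c(5, 2)), "increasing")
})

test_that("q-thresholded funnel curves use the implied per-test cut-off", {
  set.seed(8)
  e <- exp(runif(287, log(0.5), log(200)))
  y <- rpois(287, e); y[1:6] <- rpois(6, 3 * e[1:6])
  p <- poisson_pvalue(y, e)
  fl <- funnel_limits(c(1, 10, 100), alpha = 0.05, pvals = p,
                      q_threshold = 0.05)
  expect_setequal(unique(fl$level), c("p<0.05", "q<0.05"))
  q <- qvalues(p)
  p_cut <- max(p[q <= 0.05])
  direct <- funnel_limits(c(1, 10, 100), alpha = p_cut)
  adj <- fl[fl$level == "q<0.05", ]
  expect_equal(adj$lower, direct$lower)
  expect_equal(adj$upper, direct$upper)
  # nothing below the threshold -> degenerate widest curves
  fl0 <- funnel_limits(10, alpha = 0.05, pvals = runif(50, 0.5, 1),
                       q_threshold = 0.01)
  adj0 <- fl0[fl0$level == "q<0.01", ]
  expect_equal(adj0$lower, 0)
  expect_equal(adj0$upper, Inf)
})

test_that("the screen wrapper assembles aligned per-area results", {
  map <- generate_map(6, 6, pi0 = 0.9, effect_size = 3,
                      e_range = c(10, 100), seed = 21)
  scr <- poisson_screen(map$table, alpha = 0.05, fdr_level = 0.05,
                        q_threshold = 0.2)
  expect_equal(scr$area_id, map$table$area_id)
  expect_true(all(scr$p_value >= 0 & scr$p_value <= 1))
  expect_true(all(scr$q_value >= scr$p_value * attr(scr, "pi0") - 1e-12))
  expect_identical(scr$reject_q, as.integer(scr$q_value <= 0.2))
  # Bonferroni is never more liberal than BH at the same level
  expect_true(all(scr$reject_bonferroni <= scr$reject_bh))
})
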