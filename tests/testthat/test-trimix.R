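test_that("classification probabilities are pooled draw means of r", {
  r1 <- matrix(c(1, 1, 1, 1,
                 1, 0, 1, 0), nrow = 4)        # area 1 all-null, area 2 half
  fit <- fake_trimix(list(r1))
  cp <- classification_probs(fit)
  expect_equal(cp$prob_null, c(1, 0.5))
  expect_equal(cp$prob_divergent, c(0, 0.5))
  expect_equal(cp$prob_null + cp$prob_divergent, rep(1, 2))

  # two disagreeing chains pool to 0.5 and trip the PSRF flag
  fit2 <- fake_trimix(list(matrix(1, 50, 1), matrix(0, 50, 1)))
  expect_equal(classification_probs(fit2)$prob_null, 0.5)
  s2 <- summary(fit2)
  expect_gt(s2$psrf[["n_null"]], 1.1)
})

test_that("posterior summaries respect degenerate and pooled draws", {
  th <- matrix(1, 100, 3)
  r <- matrix(1L, 100, 3)
  fit <- fake_trimix(list(r), list(th))
  s <- summary(fit)
  expect_equal(s$areas$rr_mean, rep(1, 3))
  expect_equal(s$areas$rr_median, rep(1, 3))
  expect_equal(s$areas$rr_low, s$areas$rr_high)

  # duplicating a chain leaves every per-area summary unchanged
  set.seed(3)
  th2 <- matrix(rgamma(300, 2, 2), 100, 3)
  single <- fake_trimix(list(r), list(th2))
  double <- fake_trimix(list(r, r), list(th2, th2))
  s1 <- summary(single)$areas
  s2 <- summary(double)$areas
  expect_equal(s2$rr_mean, s1$rr_mean)
  expect_equal(s2$rr_median, s1$rr_median)
  expect_equal(s2$rr_low, s1$rr_low)
  expect_error(summary(fit, level = 1.2), "credible")
})

test_that("the Gelman-Rubin factor behaves at its known limits", {
  x <- matrix(rnorm(200), ncol = 2)
  x[, 2] <- x[, 1]
  expect_equal(gelman_rubin(x), 1, tolerance = 1e-12)
  expect_gt(gelman_rubin(cbind(rnorm(100), rnorm(100) + 100)), 10)
  set.seed(2)
  long <- matrix(rnorm(2e4), ncol = 2)
  expect_equal(gelman_rubin(long), 1, tolerance = 0.05)
  expect_error(gelman_rubin(matrix(rnorm(10), ncol = 1)), "two chains")
  expect_error(gelman_rubin(list(rnorm(5), rnorm(6))), "equal")
  # cross-check against the reference implementation in coda
  cd <- coda::gelman.diag(coda::mcmc.list(coda::mcmc(long[, 1]),
                                          coda::mcmc(long[, 2])),
                          autoburnin = FALSE)
  expect_equal(gelman_rubin(long), unname(cd$psrf[1, 1]), tolerance = 0.02)
})

test_that("beta hyperprior summaries reproduce the reference percentiles", {
  b <- beta_prior_summary(9.7, 0.3)
  expect_equal(b$mean, 0.97)
  expect_equal(unname(b$quantiles[c("10%", "50%")]), c(0.91, 0.99))
  b2 <- beta_prior_summary(9, 1)
  expect_equal(b2$mean, 0.9)
  expect_equal(unname(b2$quantiles),
               c(0.77, 0.86, 0.93, 0.97, 0.99))
  b3 <- beta_prior_summary(1, 1)
  expect_equal(b3$mean, 0.5)
  expect_equal(unname(b3$quantiles[3]), 0.5)
  expect_error(beta_prior_summary(-1, 2), "positive")
})

test_that("with the null disabled and fixed hyperparameters the PG
          posterior matches the conjugate closed form", {
  map <- generate_map(6, 5, e_range = c(2, 60), pi0 = 0.9,
                      effect_size = 2, seed = 31)
  k0 <- 2; nu0 <- 1.5
  fit <- trimix(map$table, variant = "pg", chains = 2, burnin = 200,
                store = 1500, seed = 32,
                control = trimix_control(fix_r = 0, fix_k = k0,
                                         fix_nu = nu0))
  post_mean <- unname(fitted(fit))
  shape <- k0 + map$table$observed
  rate <- nu0 + map$table$expected
  closed <- shape / rate
  n_draws <- 2 * 1500
  mc_se <- sqrt(shape) / rate / sqrt(n_draws)
  expect_true(all(abs(post_mean - closed) <= 3.5 * mc_se))
})

test_that("prior-only runs recover the Beta(c, d) mean of pi", {
  tab <- area_table(sprintf("A%02d", 1:20), rpois(20, 5), rep(5, 20))
  fit <- trimix(tab, variant = "pg", c = 9.7, d = 0.3, chains = 2,
                burnin = 200, store = 2000, seed = 33,
                control = trimix_control(prior_only = TRUE))
  pm <- pi_posterior_mean(fit)
  # each pi_i is a fresh Beta draw per iteration; MC error of the mean
  mc_se <- sqrt(0.97 * 0.03 / (2 * 2000))
  expect_true(all(abs(pm - 0.97) < 4 * mc_se + 0.01))
  # prior-only classification probability matches c/(c+d) too
  cp <- classification_probs(fit)
  expect_equal(mean(cp$prob_null), 0.97, tolerance = 0.01)
})

test_that("the ICAR full conditional has neighbour-mean location and
          count-scaled precision", {
  # 3-node path A-B-C: the middle node's conditional is
  # N((v_A + v_C)/2, precision 2 * lambda) by the pairwise-difference form
  tab <- area_table(c("A", "B", "C"), c(1, 1, 1), c(1, 1, 1))
  adj <- adjacency_map(rbind(c("A", "B"), c("B", "C")))
  idx <- trimix:::.adj_index(tab, adj)
  v <- c(-1.3, 0, 2.1)
  lambda <- 2.5
  s <- trimix:::.neighbour_sums(v, idx$edges, 3)
  fc <- trimix:::.icar_fullcond(2, s, idx$n, lambda)
  expect_equal(fc$mean, (v[1] + v[3]) / 2)
  expect_equal(fc$prec, lambda * 2)
  # moment check over 1e5 conditional draws
  set.seed(44)
  draws <- rnorm(1e5, fc$mean, 1 / sqrt(fc$prec))
  expect_equal(mean(draws), 0.4, tolerance = 4 / sqrt(1e5 * fc$prec))
  expect_equal(1 / var(draws), fc$prec, tolerance = 0.1)
  # end nodes have a single neighbour: mean equals it, precision lambda
  fc1 <- trimix:::.icar_fullcond(1, s, idx$n, lambda)
  expect_equal(fc1$mean, v[2])
  expect_equal(fc1$prec, lambda)
})

test_that("a fixed seed reproduces the draw store and chain labels are
          exchangeable", {
  map <- generate_map(5, 5, e_range = c(5, 50), pi0 = 0.95, seed = 51)
  f1 <- trimix(map$table, chains = 2, burnin = 100, store = 200, seed = 7)
  f2 <- trimix(map$table, chains = 2, burnin = 100, store = 200, seed = 7)
  expect_identical(f1$chains[[1]]$theta, f2$chains[[1]]$theta)
  expect_identical(f1$chains[[2]]$r, f2$chains[[2]]$r)
  # swapping chain labels leaves every summary unchanged
  swapped <- f1
  swapped$chains <- rev(swapped$chains)
  expect_equal(summary(swapped)$areas$rr_mean, summary(f1)$areas$rr_mean)
  expect_equal(classification_probs(swapped), classification_probs(f1))
})

test_that("null-map fits shrink relative risks toward one", {
  map <- generate_map(8, 8, e_range = c(0.5, 50), pi0 = 1, seed = 61)
  fit <- trimix(map$table, chains = 2, burnin = 1000, store = 1000,
                seed = 62)
  smr <- compute_smr(map$table)$smr
  post <- unname(fitted(fit))
  small <- map$table$expected < 10
  expect_true(all(abs(post[small] - 1) <= abs(smr[small] - 1) + 0.02))
})

test_that("increasing d never raises the expected classification
          probability", {
  map <- generate_map(5, 5, e_range = c(5, 50), pi0 = 0.9,
                      effect_size = 2.5, seed = 71)
  mean_prob <- sapply(c(0.3, 1, 3), function(dd) {
    fit <- trimix(map$table, c = 9, d = dd, chains = 2, burnin = 800,
                  store = 800, seed = 72)
    mean(classification_probs(fit)$prob_null)
  })
  expect_true(all(diff(mean_prob) < 0.02))
})

test_that("model variants validate their inputs", {
  map <- generate_map(4, 4, seed = 81)
  expect_error(trimix(map$table, variant = "bym"), "adjacency")
  expect_error(trimix(map$table, c = -1), "positive")
  expect_error(trimix(map$table, chains = 0), "chain")
  # BYM adjacency must cover every area
  partial <- adjacency_map(rbind(c("A001", "A002")),
                           area_ids = c("A001", "A002"))
  expect_error(trimix(map$table, adjacency = partial, variant = "bym"),
               "cover|area")
})

test_that("the BYM variant flags clustered divergence and stays
          reproducible", {
  map <- generate_map(8, 8, e_range = c(20, 100), pi0 = 0.92,
                      effect_model = "cluster", effect_size = 2, seed = 91)
  fit <- trimix(map$table, adjacency = map$adj, variant = "bym",
                chains = 2, burnin = 1500, store = 1500, seed = 92)
  cp <- classification_probs(fit)
  div <- map$truth$is_null == 0
  expect_gt(rank_auc(cp$prob_divergent, div), 0.9)
  fit2 <- trimix(map$table, adjacency = map$adj, variant = "bym",
                 chains = 2, burnin = 1500, store = 1500, seed = 92)
  expect_identical(fit$chains[[1]]$theta, fit2$chains[[1]]$theta)
})
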