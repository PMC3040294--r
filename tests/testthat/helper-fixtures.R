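# Small in-code fixtures shared across test files.

# three-area toy table
toy_table <- function() {
  area_table(c("A01", "A02", "A03"),
             observed = c(10, 0, 5),
             expected = c(8.2, 1.0, 5.0))
}

# write a delimited area file and return its path
write_area_file <- function(lines, file = tempfile(fileext = ".csv")) {
  writeLines(lines, file)
  file
}

# area-under-ROC of score for a 0/1 truth vector via the rank statistic
rank_auc <- function(score, positive) {
  rk <- rank(score)
  n1 <- sum(positive); n0 <- sum(!positive)
  (mean(rk[positive]) - (n1 + 1) / 2) / n0
}

# minimal hand-built trimix object carrying given r draws (one chain per
# list element), for testing summaries without running MCMC
fake_trimix <- function(r_chains, theta_chains = NULL, ids = NULL) {
  m <- ncol(r_chains[[1]])
  if (is.null(ids)) ids <- sprintf("A%02d", seq_len(m))
  tab <- area_table(ids, rep(1, m), rep(1, m))
  chains <- lapply(seq_along(r_chains), function(i) {
    r <- r_chains[[i]]
    th <- if (is.null(theta_chains)) matrix(1, nrow(r), m)
          else theta_chains[[i]]
    list(r = r, theta = th,
         pi = matrix(0.5, nrow(r), m),
         hyper = cbind(k = rep(1, nrow(r)), nu = rep(1, nrow(r)),
                       n_null = rowSums(r)))
  })
  structure(list(table = tab, adjacency = NULL, variant = "pg",
                 c = 9.7, d = 0.3, pi_sharing = "area", mu0 = 0,
                 hyper = list(rate_k = 0.1, rate_nu = 0.1),
                 control = trimix_control(), chains = chains,
                 mcmc = list(chains = length(chains),
                             burnin = 0, store = nrow(r_chains[[1]]),
                             thin = 1, seed = NULL, chain_seeds = NULL)),
            class = "trimix")
}
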