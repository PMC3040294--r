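#' Fit a tri-level Bayesian mixture model to an areal disease map
#'
#' `trimix()` fits the hierarchical mixture model that turns disease mapping
#' into a multiple-testing problem with a genuinely Bayesian answer. The
#' first level is the Poisson likelihood `Y_i ~ Poisson(E_i * theta_i)`. At
#' the second level the log relative risk is a two-component mixture: a
#' point mass at the null (`log theta_i = mu0 = 0`, pure Poisson noise) and
#' an alternative component carrying extra-Poisson variability, either
#' Poisson-Gamma (`exp(mu1_i) ~ Gamma(k, nu)`, shrinkage toward the global
#' mean) or Besag-York-Mollie (`mu1_i = u_i + v_i` with unstructured
#' heterogeneity `u` and an intrinsic CAR clustering term `v`, shrinkage
#' toward local and global means). The third level places a Bernoulli(`pi_i`)
#' prior on the null-membership indicator `r_i` with `pi_i ~ Beta(c, d)`,
#' so the posterior mean of `r_i` is the per-area classification
#' probability of belonging to the null set -- the quantity that adjusts the
#' map for multiple comparisons.
#'
#' The default `Beta(9.7, 0.3)` hyperprior encodes the belief that only a
#' few percent of areas diverge (prior mean 0.97 for the null); posterior
#' classification is known to be sensitive to this choice, and
#' [sensitivity_sweep()] automates comparing alternatives.
#'
#' Sampling is Metropolis-within-Gibbs: `r_i` from its two-point full
#' conditional (odds computed on the log scale), `pi_i` conjugately from a
#' Beta, the Poisson-Gamma rates conjugately from a Gamma (with a
#' refreshed prior draw for areas currently at the null, keeping the chain
#' irreducible), `k` and `nu` by adaptive random-walk Metropolis on the log
#' scale, and the BYM terms by per-area Metropolis (Gibbs where the
#' likelihood is inactive) with the clustering term re-centred to sum zero
#' after each sweep. Random-walk steps adapt only during burn-in, toward a
#' 0.44 componentwise acceptance rate.
#'
#' @param table an [area_table()] of observed and expected counts.
#' @param adjacency an [adjacency_map()]; required by the BYM variant,
#'   ignored by Poisson-Gamma.
#' @param variant `"pg"` (Poisson-Gamma alternative) or `"bym"`.
#' @param c,d shape parameters of the Beta hyperprior on the null
#'   probability `pi_i`. Defaults `Beta(9.7, 0.3)`: prior mean 0.97.
#' @param pi_sharing `"area"` (exchangeable area-specific `pi_i`, the
#'   default) or `"common"` (a single shared `pi`).
#' @param mu0 null log relative risk; 0 unless you have a reason.
#' @param hyper named list overriding alternative-component hyperpriors:
#'   `rate_k`, `rate_nu` (exponential rates for the Poisson-Gamma `k`,
#'   `nu`; default 0.1) and `shape_u`, `rate_u`, `shape_v`, `rate_v`
#'   (Gamma hyperpriors for the BYM precisions; default 0.5 and 5e-4).
#' @param chains number of independent chains (at least 2 to allow
#'   convergence diagnostics; default 2).
#' @param burnin iterations discarded per chain (default 100000).
#' @param store iterations stored per chain after burn-in and thinning
#'   (default 50000).
#' @param thin thinning interval (default 1).
#' @param seed integer seed; chain-specific seeds are derived from it, so
#'   a fixed seed makes the whole draw store reproducible.
#' @param control a [trimix_control()] list of sampler switches.
#' @return An object of class `trimix`; see [summary.trimix()],
#'   [classification_probs()], [fitted.trimix()], [plot.trimix()].
#' @examples
#' map <- generate_map(6, 6, e_range = c(5, 50), seed = 42)
#' fit <- trimix(map$table, chains = 2, burnin = 300, store = 300,
#'               seed = 1)
#' head(classification_probs(fit))
#' @references Besag, J., York, J., Mollie, A. (1991). Bayesian image
#'   restoration, with two applications in spatial statistics.
#'   Ann Inst Stat Math 43, 1-20.
#'
#'   Clayton, D., Kaldor, J. (1987). Empirical Bayes estimates of
#'   age-standardized relative risks for use in disease mapping.
#'   Biometrics 43, 671-681.
#'
#'   Scott, J.G., Berger, J.O. (2006). An exploration of aspects of
#'   Bayesian multiple testing. J Stat Plan Inference 136, 2144-2162.
#' @export
trimix <- function(table, adjacency = NULL, variant = c("pg", "bym"),
                   c = 9.7, d = 0.3, pi_sharing = c("area", "common"),
                   mu0 = 0, hyper = list(), chains = 2,
                   burnin = 100000, store = 50000, thin = 1,
                   seed = NULL, control = trimix_control()) {
  stopifnot(inherits(table, "area_table"))
  variant <- match.arg(variant)
  pi_sharing <- match.arg(pi_sharing)
  if (!is.numeric(c) || !is.numeric(d) || c <= 0 || d <= 0)
    stop("Beta hyperprior shapes c, d must be positive", call. = FALSE)
  if (chains < 1) stop("need at least one chain", call. = FALSE)
  if (store < 1) stop("store must be at least 1", call. = FALSE)
  if (thin < 1) stop("thin must be at least 1", call. = FALSE)
  hy <- .default_hyper(variant)
  hy[names(hyper)] <- hyper
  if (any(unlist(hy) <= 0))
    stop("hyperprior rates/shapes must be positive", call. = FALSE)

  adjidx <- NULL
  if (variant == "bym") {
    if (is.null(adjacency))
      stop("the BYM variant requires an adjacency_map covering every area",
           call. = FALSE)
    adjidx <- .adj_index(table, adjacency)
    adjidx$colors <- .greedy_coloring(adjidx$nb)
    comp <- validate_map(table, adjacency)
    adjidx$m_eff <- nrow(table) - comp$n_components
    if (any(adjidx$n == 0))
      warning("island area(s) with no neighbours: their clustering term is ",
              "fixed at zero", call. = FALSE)
  }

  if (!is.null(seed)) set.seed(seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, chains)

  runs <- vector("list", chains)
  for (ch in seq_len(chains)) {
    runs[[ch]] <- .run_chain(
      y = table$observed, e = table$expected, variant = variant,
      adjidx = adjidx, c = c, d = d, pi_sharing = pi_sharing, mu0 = mu0,
      hyper = hy, burnin = burnin, store = store, thin = thin,
      control = control, seed = chain_seeds[ch])
  }

  structure(list(table = table, adjacency = adjacency, variant = variant,
                 c = c, d = d, pi_sharing = pi_sharing, mu0 = mu0,
                 hyper = hy, control = control,
                 chains = runs,
                 mcmc = list(chains = chains, burnin = burnin,
                             store = store, thin = thin, seed = seed,
                             chain_seeds = chain_seeds),
                 call = match.call()),
            class = "trimix")
}

#' Sampler switches for [trimix()]
#'
#' Mostly useful for validation experiments: forcing the mixture indicator,
#' pinning Poisson-Gamma hyperparameters at known values, or running the
#' model prior-only (the likelihood contribution is dropped everywhere, so
#' posterior summaries must reproduce the prior).
#'
#' @param fix_r `NULL`, or a 0/1 scalar/vector forcing the null-membership
#'   indicator (0 = all areas in the alternative component).
#' @param fix_k,fix_nu `NULL`, or fixed values for the Poisson-Gamma
#'   hyperparameters (skips their Metropolis updates).
#' @param prior_only if `TRUE`, drop the likelihood (prior recovery runs).
#' @param adapt adapt random-walk step sizes during burn-in.
#' @param target_accept componentwise acceptance target for adaptation.
#' @param step_k,step_nu,step_u,step_v initial random-walk standard
#'   deviations.
#' @return A list of class `trimix_control`.
#' @export
trimix_control <- function(fix_r = NULL, fix_k = NULL, fix_nu = NULL,
                           prior_only = FALSE, adapt = TRUE,
                           target_accept = 0.44,
                           step_k = 0.3, step_nu = 0.3,
                           step_u = 0.5, step_v = 0.5) {
  structure(list(fix_r = fix_r, fix_k = fix_k, fix_nu = fix_nu,
                 prior_only = prior_only, adapt = adapt,
                 target_accept = target_accept,
                 step_k = step_k, step_nu = step_nu,
                 step_u = step_u, step_v = step_v),
            class = "trimix_control")
}

.default_hyper <- function(variant) {
  if (variant == "pg") list(rate_k = 0.1, rate_nu = 0.1)
  else list(shape_u = 0.5, rate_u = 5e-4, shape_v = 0.5, rate_v = 5e-4)
}

# greedy graph coloring: areas within a color class have no edges between
# them, so their clustering terms can be updated as one vectorized block
.greedy_coloring <- function(nb) {
  m <- length(nb)
  color <- integer(m)
  for (i in order(-lengths(nb))) {
    used <- color[nb[[i]]]
    cand <- 1L
    while (cand %in% used) cand <- cand + 1L
    color[i] <- cand
  }
  lapply(seq_len(max(color)), function(k) which(color == k))
}

# mean and precision of the intrinsic CAR full conditional for the areas
# in `idx`, given the neighbour sums `s = A v` and neighbour counts `n`
.icar_fullcond <- function(idx, s, n, lambda) {
  list(mean = s[idx] / n[idx], prec = lambda * n[idx])
}

.neighbour_sums <- function(v, edges, m) {
  s <- numeric(m)
  if (nrow(edges)) {
    add1 <- rowsum(v[edges[, 2]], edges[, 1])
    add2 <- rowsum(v[edges[, 1]], edges[, 2])
    s[as.integer(rownames(add1))] <- add1
    s[as.integer(rownames(add2))] <- s[as.integer(rownames(add2))] + add2
  }
  s
}

# One MCMC chain. Returns matrices of stored draws.
.run_chain <- function(y, e, variant, adjidx, c, d, pi_sharing, mu0,
                       hyper, burnin, store, thin, control, seed) {
  set.seed(seed)
  m <- length(y)
  theta0 <- exp(mu0)
  prior_only <- isTRUE(control$prior_only)
  fixed_r <- if (!is.null(control$fix_r))
    as.integer(rep_len(control$fix_r, m))

  # state
  r <- if (!is.null(fixed_r)) fixed_r else rep(1L, m)
  pi <- rep(c / (c + d), m)
  if (variant == "pg") {
    k <- if (!is.null(control$fix_k)) control$fix_k else 1
    nu <- if (!is.null(control$fix_nu)) control$fix_nu else 1
    g <- pmin(pmax((y + 0.5) / e, 1e-3), 1e3)
    ls_k <- log(control$step_k); ls_nu <- log(control$step_nu)
    ls_kn <- log(control$step_k)
  } else {
    u <- rep(0, m); v <- rep(0, m)
    lambda_u <- 1; lambda_v <- 1
    g <- exp(u + v)
    nbn <- adjidx$n
    island <- nbn == 0L
    edges <- adjidx$edges
    colors <- adjidx$colors
    step_u <- rep(control$step_u, m)
    step_v <- rep(control$step_v, m)
    hy <- hyper
  }

  n_total <- burnin + store * thin
  out_theta <- matrix(NA_real_, store, m)
  out_r <- matrix(NA_integer_, store, m)
  out_pi <- matrix(NA_real_, store, m)
  out_hyper <- matrix(NA_real_, store, 3)
  colnames(out_hyper) <- if (variant == "pg") c("k", "nu", "n_null")
                         else c("lambda_u", "lambda_v", "n_null")
  kept <- 0L
  gamma_adapt <- 0.05

  for (it in seq_len(n_total)) {
    adapting <- control$adapt && it <= burnin

    ## (i) null-membership indicators: two-point full conditional
    if (is.null(fixed_r)) {
      l1 <- log(pi)
      l0 <- log1p(-pi)
      if (!prior_only) {
        l1 <- l1 + stats::dpois(y, e * theta0, log = TRUE)
        l0 <- l0 + stats::dpois(y, e * g, log = TRUE)
      }
      p1 <- stats::plogis(l1 - l0)
      r <- as.integer(stats::runif(m) < p1)
    }

    ## (ii) Beta-Bernoulli layer, conjugate
    if (pi_sharing == "area") {
      pi <- stats::rbeta(m, c + r, d + 1 - r)
    } else {
      pi <- rep(stats::rbeta(1, c + sum(r), d + m - sum(r)), m)
    }
    pi <- pmin(pmax(pi, 1e-12), 1 - 1e-12)

    if (variant == "pg") {
      ## (iii) alternative relative risks: conjugate Gamma; prior refresh
      ## for areas currently at the null keeps the chain irreducible
      act <- (r == 0L) & !prior_only
      g <- stats::rgamma(m, k + y * act, nu + e * act)
      g <- pmax(g, 1e-300)
      sum_log_g <- sum(log(g)); sum_g <- sum(g)

      ## k | g, nu  (random walk on log k)
      if (is.null(control$fix_k)) {
        prop <- k * exp(exp(ls_k) * stats::rnorm(1))
        la <- m * (prop - k) * log(nu) - m * (lgamma(prop) - lgamma(k)) +
          (prop - k) * sum_log_g - hyper$rate_k * (prop - k) +
          log(prop) - log(k)
        acc <- log(stats::runif(1)) < la
        if (acc) k <- prop
        if (adapting)
          ls_k <- ls_k + gamma_adapt * ((if (acc) 1 else 0) -
                                          control$target_accept)
      }
      ## nu | g, k  (random walk on log nu)
      if (is.null(control$fix_nu)) {
        prop <- nu * exp(exp(ls_nu) * stats::rnorm(1))
        la <- m * k * (log(prop) - log(nu)) - (prop - nu) * sum_g -
          hyper$rate_nu * (prop - nu) + log(prop) - log(nu)
        acc <- log(stats::runif(1)) < la
        if (acc) nu <- prop
        if (adapting)
          ls_nu <- ls_nu + gamma_adapt * ((if (acc) 1 else 0) -
                                            control$target_accept)
      }
      ## joint scale move along the (log k, log nu) ridge: the posterior
      ## pins down the Gamma mean k/nu much harder than the scale, so
      ## componentwise walks crawl; moving both together fixes the mixing
      if (is.null(control$fix_k) && is.null(control$fix_nu)) {
        a <- exp(exp(ls_kn) * stats::rnorm(1))
        kp <- k * a; nup <- nu * a
        la <- (m * kp * log(nup) - m * lgamma(kp) + (kp - 1) * sum_log_g -
                 nup * sum_g - hyper$rate_k * kp - hyper$rate_nu * nup) -
          (m * k * log(nu) - m * lgamma(k) + (k - 1) * sum_log_g -
             nu * sum_g - hyper$rate_k * k - hyper$rate_nu * nu) +
          2 * log(a)
        acc <- log(stats::runif(1)) < la
        if (acc) { k <- kp; nu <- nup }
        if (adapting)
          ls_kn <- ls_kn + gamma_adapt * ((if (acc) 1 else 0) -
                                            control$target_accept)
      }
      theta <- ifelse(r == 1L, theta0, g)
      hyp_now <- c(k, nu, sum(r))
    } else {
      ## (iii) BYM: unstructured term u, conditionally independent given v
      lik <- (r == 0L) & !prior_only
      sd_u <- 1 / sqrt(lambda_u)
      gib <- !lik
      if (any(gib)) u[gib] <- stats::rnorm(sum(gib), 0, sd_u)
      if (any(lik)) {
        idx <- which(lik)
        prop <- u[idx] + step_u[idx] * stats::rnorm(length(idx))
        la <- stats::dpois(y[idx], e[idx] * exp(prop + v[idx]), log = TRUE) -
          stats::dpois(y[idx], e[idx] * exp(u[idx] + v[idx]), log = TRUE) +
          stats::dnorm(prop, 0, sd_u, log = TRUE) -
          stats::dnorm(u[idx], 0, sd_u, log = TRUE)
        acc <- log(stats::runif(length(idx))) < la
        u[idx[acc]] <- prop[acc]
        if (adapting)
          step_u[idx] <- step_u[idx] *
            exp(gamma_adapt * (acc - control$target_accept))
      }

      ## clustering term v: ICAR full conditional, updated by color blocks
      for (blk in colors) {
        blk <- blk[!island[blk]]
        if (!length(blk)) next
        s <- .neighbour_sums(v, edges, m)
        fc <- .icar_fullcond(blk, s, nbn, lambda_v)
        fc_sd <- 1 / sqrt(fc$prec)
        gibb <- !lik[blk]
        if (any(gibb)) {
          bidx <- blk[gibb]
          v[bidx] <- stats::rnorm(length(bidx), fc$mean[gibb], fc_sd[gibb])
        }
        if (any(!gibb)) {
          bidx <- blk[!gibb]
          mu_c <- fc$mean[!gibb]; sd_c <- fc_sd[!gibb]
          prop <- v[bidx] + step_v[bidx] * stats::rnorm(length(bidx))
          la <- stats::dpois(y[bidx], e[bidx] * exp(u[bidx] + prop),
                             log = TRUE) -
            stats::dpois(y[bidx], e[bidx] * exp(u[bidx] + v[bidx]),
                         log = TRUE) +
            stats::dnorm(prop, mu_c, sd_c, log = TRUE) -
            stats::dnorm(v[bidx], mu_c, sd_c, log = TRUE)
          acc <- log(stats::runif(length(bidx))) < la
          v[bidx[acc]] <- prop[acc]
          if (adapting)
            step_v[bidx] <- step_v[bidx] *
              exp(gamma_adapt * (acc - control$target_accept))
        }
      }
      ## identifiability: clustering term centred to sum zero, level
      ## absorbed by the unstructured term
      mv <- mean(v[!island])
      v[!island] <- v[!island] - mv
      u <- u + mv

      ## precision hyperparameters, conjugate Gamma updates
      lambda_u <- stats::rgamma(1, hy$shape_u + m / 2,
                                hy$rate_u + sum(u^2) / 2)
      if (nrow(edges)) {
        qf <- sum((v[edges[, 1]] - v[edges[, 2]])^2)
        lambda_v <- stats::rgamma(1, hy$shape_v + adjidx$m_eff / 2,
                                  hy$rate_v + qf / 2)
      }
      g <- exp(u + v)
      theta <- ifelse(r == 1L, theta0, g)
      hyp_now <- c(lambda_u, lambda_v, sum(r))
    }

    if (it > burnin && (it - burnin) %% thin == 0L) {
      kept <- kept + 1L
      out_theta[kept, ] <- theta
      out_r[kept, ] <- r
      out_pi[kept, ] <- pi
      out_hyper[kept, ] <- hyp_now
    }
  }

  list(theta = out_theta, r = out_r, pi = out_pi, hyper = out_hyper,
       seed = seed)
}
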