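#' Posterior classification and inclusion probabilities
#'
#' The classification probability of an area is the posterior probability
#' that it belongs to the null set, `Prob(r_i = 1 | Y)`, estimated as the
#' across-draw mean of the null-membership indicator pooled over chains.
#' Its complement is the posterior inclusion probability -- the probability
#' that the area diverges from the reference. Low classification
#' probabilities flag candidate divergent areas while the Beta-Bernoulli
#' layer adjusts for multiplicity.
#'
#' @param object a fitted [trimix()] model.
#' @return Data frame with columns `area_id`, `prob_null`
#'   (classification probability), `prob_divergent` (inclusion
#'   probability), aligned to the table's row order.
#' @export
classification_probs <- function(object) {
  stopifnot(inherits(object, "trimix"))
  r_all <- do.call(rbind, lapply(object$chains, `[[`, "r"))
  if (!nrow(r_all)) stop("empty posterior draw store", call. = FALSE)
  p_null <- colMeans(r_all)
  data.frame(area_id = object$table$area_id,
             prob_null = p_null,
             prob_divergent = 1 - p_null,
             stringsAsFactors = FALSE)
}

#' Posterior mean of the null-probability layer
#'
#' Across-draw mean of `pi_i`, the third-level Bernoulli parameter. Mostly
#' of diagnostic interest (e.g. prior-recovery checks); area flagging uses
#' [classification_probs()].
#'
#' @param object a fitted [trimix()] model.
#' @return Named numeric vector of posterior means of `pi_i`.
#' @export
pi_posterior_mean <- function(object) {
  stopifnot(inherits(object, "trimix"))
  pi_all <- do.call(rbind, lapply(object$chains, `[[`, "pi"))
  stats::setNames(colMeans(pi_all), object$table$area_id)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' The classic between/within-chain variance diagnostic: with `n` stored
#' draws per chain, `W` the mean within-chain variance and `B/n` the
#' variance of the chain means, the PSRF is `sqrt(((n-1)/n * W + B/n) / W)`.
#' Values near one indicate that the chains have mixed over the same
#' distribution; a common rule of thumb requires PSRF below 1.1 for every
#' monitored scalar.
#'
#' @param chains a matrix with one column per chain (rows are stored
#'   draws), or a list of equal-length numeric vectors.
#' @return The potential scale reduction factor (scalar). Chains with
#'   identical means (zero between-chain variance) give exactly 1;
#'   constant chains at different levels give `Inf`.
#' @examples
#' x <- matrix(rnorm(2000), ncol = 2)
#' gelman_rubin(x)
#' @export
gelman_rubin <- function(chains) {
  if (is.list(chains)) {
    if (length(unique(lengths(chains))) != 1L)
      stop("chains must have equal stored lengths", call. = FALSE)
    chains <- do.call(cbind, chains)
  }
  chains <- as.matrix(chains)
  if (ncol(chains) < 2L)
    stop("the Gelman-Rubin diagnostic needs at least two chains",
         call. = FALSE)
  n <- nrow(chains)
  if (n < 2L) stop("chains must contain at least two draws", call. = FALSE)
  means <- colMeans(chains)
  W <- mean(apply(chains, 2, stats::var))
  B_over_n <- stats::var(means)
  if (B_over_n == 0) return(1)        # chains indistinguishable
  if (W == 0) return(Inf)
  sqrt(((n - 1) / n * W + B_over_n) / W)
}

#' Summarize a beta hyperprior for the null probability
#'
#' The mean and percentiles of a `Beta(c, d)` distribution, the language in
#' which prior beliefs about the proportion of non-divergent areas are
#' stated. `Beta(9.7, 0.3)` has mean 0.97 -- around 3\% of areas divergent
#' -- with 10th percentile 0.91 and median 0.99; `Beta(9, 1)` relaxes the
#' mean to 0.90.
#'
#' @param c,d positive shape parameters.
#' @param probs percentile levels (default deciles/quartiles/median).
#' @param digits rounding applied to the report (default 2, the usual
#'   display convention); `NULL` for full precision.
#' @return List with `mean` and named `quantiles`.
#' @examples
#' beta_prior_summary(9.7, 0.3)
#' @export
beta_prior_summary <- function(c, d, probs = c(0.1, 0.25, 0.5, 0.75, 0.9),
                               digits = 2) {
  if (!is.numeric(c) || !is.numeric(d) || c <= 0 || d <= 0)
    stop("beta shapes must be positive", call. = FALSE)
  if (any(probs <= 0 | probs >= 1))
    stop("percentile levels must lie in (0, 1)", call. = FALSE)
  mean <- c / (c + d)
  q <- stats::qbeta(probs, c, d)
  if (!is.null(digits)) {
    mean <- round(mean, digits)
    q <- round(q, digits)
  }
  list(mean = mean,
       quantiles = stats::setNames(q, paste0(probs * 100, "%")))
}

#' @export
print.trimix <- function(x, ...) {
  cat("Tri-level Bayesian mixture model (",
      if (x$variant == "pg") "Poisson-Gamma" else "BYM",
      " alternative)\n", sep = "")
  cat(sprintf("  %d areas; Beta(%g, %g) null-probability hyperprior (%s)\n",
              nrow(x$table), x$c, x$d,
              if (x$pi_sharing == "area") "area-specific pi"
              else "common pi"))
  cat(sprintf("  %d chain(s) x %d stored draws (burn-in %d, thin %d)\n",
              x$mcmc$chains, x$mcmc$store, x$mcmc$burnin, x$mcmc$thin))
  cp <- classification_probs(x)
  cat(sprintf("  areas with classification probability <= 0.2: %d\n",
              sum(cp$prob_null <= 0.2)))
  invisible(x)
}

#' Posterior summary of a fitted tri-level mixture model
#'
#' Per-area posterior means, medians and equal-tailed credible intervals of
#' the relative risk, classification/inclusion probabilities, and the
#' Gelman-Rubin diagnostic per area and for the monitored global scalars
#' (the alternative-component hyperparameters and the number of areas at
#' the null).
#'
#' @param object a fitted [trimix()] model.
#' @param level credible level for the equal-tailed interval (default
#'   0.95).
#' @param ... unused.
#' @return An object of class `summary.trimix`: a list with `areas` (per
#'   -area data frame), `hyper` (posterior summary of globals), `psrf`
#'   (named PSRF vector for the globals), and the settings.
#' @export
summary.trimix <- function(object, level = 0.95, ...) {
  if (level <= 0 || level >= 1)
    stop("credible level must lie in (0, 1)", call. = FALSE)
  theta_all <- do.call(rbind, lapply(object$chains, `[[`, "theta"))
  lo_p <- (1 - level) / 2
  # type-1 (inverse-ECDF) quantiles: invariant under pooling identical
  # chains, appropriate for draws from a discrete empirical posterior
  qs <- apply(theta_all, 2, stats::quantile,
              probs = c(lo_p, 0.5, 1 - lo_p), names = FALSE, type = 1)
  cp <- classification_probs(object)
  psrf_theta <- rep(NA_real_, ncol(theta_all))
  if (object$mcmc$chains >= 2) {
    psrf_theta <- vapply(seq_len(ncol(theta_all)), function(j) {
      gelman_rubin(sapply(object$chains, function(ch) ch$theta[, j]))
    }, numeric(1))
  }
  areas <- data.frame(area_id = object$table$area_id,
                      rr_mean = colMeans(theta_all),
                      rr_median = qs[2, ],
                      rr_low = qs[1, ],
                      rr_high = qs[3, ],
                      prob_null = cp$prob_null,
                      prob_divergent = cp$prob_divergent,
                      psrf = psrf_theta,
                      stringsAsFactors = FALSE)
  hyper_all <- do.call(rbind, lapply(object$chains, `[[`, "hyper"))
  hyper <- data.frame(
    parameter = colnames(hyper_all),
    mean = colMeans(hyper_all),
    median = apply(hyper_all, 2, stats::median),
    low = apply(hyper_all, 2, stats::quantile, probs = lo_p, type = 1),
    high = apply(hyper_all, 2, stats::quantile, probs = 1 - lo_p,
                 type = 1),
    row.names = NULL, stringsAsFactors = FALSE)
  psrf <- rep(NA_real_, ncol(hyper_all))
  names(psrf) <- colnames(hyper_all)
  if (object$mcmc$chains >= 2) {
    psrf <- vapply(colnames(hyper_all), function(nm) {
      gelman_rubin(sapply(object$chains, function(ch) ch$hyper[, nm]))
    }, numeric(1))
  }
  structure(list(areas = areas, hyper = hyper, psrf = psrf,
                 level = level, variant = object$variant,
                 c = object$c, d = object$d,
                 n_draws = nrow(theta_all)),
            class = "summary.trimix")
}

#' @export
print.summary.trimix <- function(x, ...) {
  cat(sprintf(
    "Posterior summary (%s variant, Beta(%g, %g), %d pooled draws)\n",
    x$variant, x$c, x$d, x$n_draws))
  cat("\nGlobal parameters:\n")
  print(cbind(format(x$hyper, digits = 4),
              psrf = format(x$psrf, digits = 4)), row.names = FALSE)
  ord <- order(x$areas$prob_null)
  top <- utils::head(x$areas[ord, ], 10)
  cat("\nAreas with lowest classification probability:\n")
  print(format(top, digits = 3), row.names = FALSE)
  invisible(x)
}

#' @export
coef.trimix <- function(object, ...) {
  hyper_all <- do.call(rbind, lapply(object$chains, `[[`, "hyper"))
  keep <- setdiff(colnames(hyper_all), "n_null")
  colMeans(hyper_all[, keep, drop = FALSE])
}

#' @export
fitted.trimix <- function(object, ...) {
  theta_all <- do.call(rbind, lapply(object$chains, `[[`, "theta"))
  stats::setNames(colMeans(theta_all), object$table$area_id)
}

#' Residuals of a fitted tri-level mixture model
#'
#' @param object a fitted [trimix()] model.
#' @param type `"pearson"` (default): `(y - e * theta_hat) /
#'   sqrt(e * theta_hat)`; or `"response"`: `y - e * theta_hat`, with
#'   `theta_hat` the posterior mean relative risk.
#' @param ... unused.
#' @return Named numeric vector aligned with the area table.
#' @export
residuals.trimix <- function(object, type = c("pearson", "response"), ...) {
  type <- match.arg(type)
  mu <- object$table$expected * fitted(object)
  res <- object$table$observed - mu
  if (type == "pearson") res <- res / sqrt(mu)
  stats::setNames(res, object$table$area_id)
}

#' Funnel plot of a fitted tri-level mixture model
#'
#' SMRs against expected counts with exact Poisson control limits, with
#' areas whose classification probability falls at or below `threshold`
#' highlighted. The funnel geometry explains why raw p-values mislead on
#' heterogeneous maps: small areas spread widely around the null.
#'
#' @param x a fitted [trimix()] model.
#' @param threshold classification-probability cut-off for highlighting
#'   (default 0.2).
#' @param alpha per-test level for the funnel curves (default 0.05).
#' @param ... further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.trimix <- function(x, threshold = 0.2, alpha = 0.05, ...) {
  smr <- compute_smr(x$table)
  cp <- classification_probs(x)
  flag <- cp$prob_null <= threshold
  e_grid <- exp(seq(log(min(smr$precision)), log(max(smr$precision)),
                    length.out = 200))
  fl <- funnel_limits(e_grid, alpha = alpha)
  graphics::plot(smr$precision, smr$smr, log = "x",
                 xlab = "expected count (precision)",
                 ylab = "SMR",
                 col = ifelse(flag, "firebrick", "grey40"),
                 pch = ifelse(flag, 19, 1), ...)
  graphics::abline(h = 1, col = "grey60")
  graphics::lines(fl$expected, fl$lower, lty = 2)
  graphics::lines(fl$expected, fl$upper, lty = 2)
  invisible(x)
}

#' Sensitivity of posterior classification to the beta hyperprior
#'
#' Refits the same map under a list of `Beta(c, d)` hyperpriors with a
#' shared seed and collects the per-area classification probabilities,
#' ready for quantile-quantile comparison of their orderings: if two
#' priors produce the same ranking of areas the sorted probabilities lie
#' on a monotone curve, and rank correlations near one indicate robustness
#' to the prior choice.
#'
#' @param table an [area_table()].
#' @param priors list of length-2 numeric vectors `(c, d)`.
#' @param adjacency optional [adjacency_map()] (required for BYM).
#' @param variant,pi_sharing,hyper,chains,burnin,store,thin,control
#'   passed to [trimix()].
#' @param seed shared seed so that every prior sees identical chain
#'   randomness apart from the prior itself.
#' @return An object of class `trimix_sweep`: list with `fits` (one
#'   [trimix()] object per prior), `probs` (matrix of classification
#'   probabilities, one column per prior), `rank_cor` (Spearman
#'   correlation matrix of the probability rankings), `priors`.
#' @examples
#' map <- generate_map(5, 5, e_range = c(5, 50), seed = 7)
#' sw <- sensitivity_sweep(map$table, priors = list(c(9.7, 0.3), c(9, 1)),
#'                         chains = 2, burnin = 200, store = 200, seed = 1)
#' sw$rank_cor
#' @export
sensitivity_sweep <- function(table, priors, adjacency = NULL,
                              variant = "pg", pi_sharing = "area",
                              hyper = list(), chains = 2,
                              burnin = 100000, store = 50000, thin = 1,
                              seed = NULL, control = trimix_control()) {
  if (!length(priors)) stop("empty prior list", call. = FALSE)
  labels <- vapply(priors, function(p) sprintf("Beta(%g,%g)", p[1], p[2]),
                   character(1))
  fits <- vector("list", length(priors))
  for (i in seq_along(priors)) {
    p <- priors[[i]]
    if (length(p) != 2 || any(p <= 0))
      stop("each prior must be a positive (c, d) pair", call. = FALSE)
    fits[[i]] <- trimix(table, adjacency = adjacency, variant = variant,
                        c = p[1], d = p[2], pi_sharing = pi_sharing,
                        hyper = hyper, chains = chains, burnin = burnin,
                        store = store, thin = thin, seed = seed,
                        control = control)
  }
  probs <- sapply(fits, function(f) classification_probs(f)$prob_null)
  colnames(probs) <- labels
  rank_cor <- stats::cor(probs, method = "spearman")
  structure(list(fits = stats::setNames(fits, labels), probs = probs,
                 rank_cor = rank_cor, priors = priors),
            class = "trimix_sweep")
}

#' @export
print.trimix_sweep <- function(x, ...) {
  cat("Hyperprior sensitivity sweep over",
      length(x$priors), "Beta priors\n")
  cat("mean classification probability per prior:\n")
  print(round(colMeans(x$probs), 3))
  cat("Spearman rank correlation of per-area probabilities:\n")
  print(round(x$rank_cor, 3))
  invisible(x)
}

#' @export
plot.trimix_sweep <- function(x, reference = 1, ...) {
  ref <- sort(x$probs[, reference])
  others <- setdiff(seq_len(ncol(x$probs)), reference)
  graphics::plot(NULL, xlim = c(0, 1), ylim = c(0, 1),
                 xlab = paste("ordered probabilities,",
                              colnames(x$probs)[reference]),
                 ylab = "ordered probabilities, alternatives", ...)
  graphics::abline(0, 1, col = "grey60")
  for (j in others)
    graphics::points(ref, sort(x$probs[, j]), pch = j)
  if (length(others))
    graphics::legend("topleft", legend = colnames(x$probs)[others],
                     pch = others, bty = "n")
  invisible(x)
}
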