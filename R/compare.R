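#' Cross-tabulate two flagging procedures
#'
#' Summarizes the agreement of two per-area decision rules as the four
#' counts of a 2x2 table: `a` areas flagged by both, `b` only by the
#' first, `c` only by the second, and `n_neither` by neither.
#'
#' @param flags_1,flags_2 0/1 rejection indicators of equal length.
#' @param labels character vector of length 2 naming the procedures.
#' @return List of class `cross_tab` with `a`, `b`, `c`, `n_neither`,
#'   `m`, `labels`.
#' @examples
#' cross_tabulate(c(1, 1, 0, 0), c(1, 0, 1, 0))
#' @export
cross_tabulate <- function(flags_1, flags_2,
                           labels = c("procedure 1", "procedure 2")) {
  if (length(flags_1) != length(flags_2))
    stop("flag vectors must have equal length", call. = FALSE)
  f1 <- as.integer(flags_1); f2 <- as.integer(flags_2)
  if (any(!f1 %in% 0:1) || any(!f2 %in% 0:1))
    stop("flags must be 0/1", call. = FALSE)
  structure(list(a = sum(f1 == 1 & f2 == 1),
                 b = sum(f1 == 1 & f2 == 0),
                 c = sum(f1 == 0 & f2 == 1),
                 n_neither = sum(f1 == 0 & f2 == 0),
                 m = length(f1),
                 labels = labels),
            class = "cross_tab")
}

#' @export
print.cross_tab <- function(x, ...) {
  tab <- matrix(c(x$a, x$c, x$b, x$n_neither), 2, 2,
                dimnames = list(paste(x$labels[1], c("yes", "no")),
                                paste(x$labels[2], c("yes", "no"))))
  print(tab)
  invisible(x)
}

#' Proportion of specific agreement for the flagged category
#'
#' Fleiss' proportion of specific agreement for the positive cell of a 2x2
#' agreement table: `p_s = 2a / (2a + b + c)`. Unlike raw agreement it is
#' not inflated by the (typically huge) number of areas that neither
#' procedure flags.
#'
#' @param tab a [cross_tabulate()] result, or a list/vector with elements
#'   `a`, `b`, `c`.
#' @param percent return a percentage (default) rather than a proportion.
#' @return The proportion of specific agreement (full precision; display
#'   rounding is left to the caller).
#' @examples
#' specific_agreement(list(a = 9, b = 1, c = 2))   # 85.71...
#' @export
specific_agreement <- function(tab, percent = TRUE) {
  a <- tab[["a"]]; b <- tab[["b"]]; cc <- tab[["c"]]
  if (any(c(a, b, cc) < 0)) stop("counts must be non-negative", call. = FALSE)
  denom <- 2 * a + b + cc
  if (denom == 0)
    stop("specific agreement undefined: no area flagged by either procedure",
         call. = FALSE)
  ps <- 2 * a / denom
  if (percent) 100 * ps else ps
}

#' Exponential Q-Q data for p-values
#'
#' Under a global null, p-values are uniform and their complementary log
#' transformation `-log(p)` is Exponential(1). Plotting the ordered
#' `-log(p)` against theoretical exponential quantiles at plotting
#' positions `(i - 0.5) / m` puts a null map on the bisector; truly
#' divergent areas depart upwards in the right tail.
#'
#' @param pvals p-values in `(0, 1]`. Zeros are capped at `1e-300` with a
#'   warning (the log transform diverges).
#' @return Data frame with columns `theoretical` (Exp(1) quantiles) and
#'   `observed` (sorted `-log(p)`), ordered ascending.
#' @export
qq_exponential <- function(pvals) {
  if (!length(pvals)) stop("empty p-value vector", call. = FALSE)
  if (any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  if (any(pvals == 0)) {
    warning("p-values of 0 capped at 1e-300 before the log transform")
    pvals[pvals == 0] <- 1e-300
  }
  m <- length(pvals)
  data.frame(theoretical = stats::qexp((seq_len(m) - 0.5) / m),
             observed = sort(-log(pvals)))
}

#' Rank agreement of q-values and classification probabilities
#'
#' Pairs the sorted q-values with the sorted posterior classification
#' probabilities (a quantile-quantile comparison of the two multiplicity
#' -adjusted orderings) and reports their Spearman rank correlation. If the
#' two criteria rank the areas identically, the Q-Q points trace a
#' monotone curve and the rank correlation is 1; the coefficient is an
#' added numeric summary of what the plot shows.
#'
#' @param q per-area q-values.
#' @param probs per-area classification probabilities.
#' @return Data frame of class `rank_agreement` with columns `q` and
#'   `prob` (both sorted ascending); the Spearman correlation of the
#'   unsorted pairs is attached as attribute `rank_cor`.
#' @export
rank_agreement <- function(q, probs) {
  if (length(q) != length(probs))
    stop("q-values and probabilities must have equal length", call. = FALSE)
  out <- data.frame(q = sort(q), prob = sort(probs))
  attr(out, "rank_cor") <- stats::cor(q, probs, method = "spearman")
  class(out) <- c("rank_agreement", "data.frame")
  out
}

#' Run the full screen-fit-compare pipeline
#'
#' Executes the package end to end from a single configuration: load (or
#' simulate) a map, run the frequentist screen, fit one or both tri-level
#' mixture variants, cross-tabulate the flaggings, and write plot-ready
#' datasets (funnel grid, p-value histogram bins, Q-Q pairs) together with
#' a manifest of every setting and seed, sufficient to re-create every
#' number in the bundle.
#'
#' @param config a named list, or the path to a YAML file holding one.
#'   Recognized entries:
#'   \describe{
#'     \item{`data`}{either `list(table = <file>, adjacency = <file>,
#'       dialect = "edges"|"winbugs")` or `list(simulate = list(...))`
#'       with [generate_map()] arguments.}
#'     \item{`screen`}{[poisson_screen()] settings (`alpha`, `fdr_level`,
#'       `q_threshold`, `lambda`).}
#'     \item{`fit`}{[trimix()] settings: `variants` (subset of
#'       `c("pg", "bym")`), `c`, `d`, `pi_sharing`, `chains`, `burnin`,
#'       `store`, `thin`, `prob_threshold` (classification cut-off,
#'       default 0.2), `inclusion_threshold` (default 0.9).}
#'     \item{`seed`}{integer master seed.}
#'     \item{`output_dir`}{directory for the report files; `NULL` skips
#'       writing.}
#'   }
#' @return List of class `trimix_report`: `areas` (per-area results),
#'   `screen`, `fits`, `crosstabs` (one [cross_tabulate()] + specific
#'   agreement per variant), `funnel`, `qq_pvalues`, `qq_rank` (per
#'   variant), `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML path",
                             call. = FALSE)
  seed <- config$seed %||% 1L
  data_cfg <- config$data %||% stop("config lacks a 'data' section",
                                    call. = FALSE)
  fit_cfg <- config$fit %||% list()
  screen_cfg <- config$screen %||% list()
  variants <- fit_cfg$variants %||% "pg"

  if (!is.null(data_cfg$simulate)) {
    map <- do.call(generate_map,
                   c(data_cfg$simulate, list(seed = seed)))
    table <- map$table; adj <- map$adj
  } else {
    if (is.null(data_cfg$table))
      stop("config data section names neither 'table' nor 'simulate'",
           call. = FALSE)
    table <- read_area_table(data_cfg$table)
    adj <- NULL
    if (!is.null(data_cfg$adjacency))
      adj <- read_adjacency(data_cfg$adjacency,
                            dialect = data_cfg$dialect %||% "edges",
                            area_ids = table$area_id)
  }
  if ("bym" %in% variants && is.null(adj))
    stop("fit stage: the BYM variant needs an adjacency file ",
         "('data: adjacency:') or a simulated map", call. = FALSE)

  screen <- do.call(poisson_screen, c(list(table = table), screen_cfg))
  q_threshold <- attr(screen, "q_threshold")
  prob_threshold <- fit_cfg$prob_threshold %||% 0.2
  incl_threshold <- fit_cfg$inclusion_threshold %||% 0.9

  fit_args <- fit_cfg[intersect(names(fit_cfg),
                                c("c", "d", "pi_sharing", "hyper", "chains",
                                  "burnin", "store", "thin"))]
  fits <- list(); crosstabs <- list(); qq_rank <- list()
  areas <- data.frame(screen, check.names = FALSE)
  for (vv in variants) {
    fit <- do.call(trimix, c(list(table = table,
                                  adjacency = if (vv == "bym") adj,
                                  variant = vv, seed = seed), fit_args))
    cp <- classification_probs(fit)
    sm <- summary(fit)$areas
    areas[[paste0("rr_mean_", vv)]] <- sm$rr_mean
    areas[[paste0("prob_null_", vv)]] <- cp$prob_null
    areas[[paste0("flag_", vv)]] <-
      as.integer(cp$prob_null <= prob_threshold)
    areas[[paste0("flag_incl_", vv)]] <-
      as.integer(cp$prob_divergent >= incl_threshold)
    ct <- cross_tabulate(areas[[paste0("flag_", vv)]], screen$reject_q,
                         labels = c(sprintf("%s prob<=%g", vv,
                                            prob_threshold),
                                    sprintf("q<=%g", q_threshold)))
    crosstabs[[vv]] <- list(table = ct,
                            specific_agreement = tryCatch(
                              specific_agreement(ct),
                              error = function(e) NA_real_))
    qq_rank[[vv]] <- rank_agreement(screen$q_value, cp$prob_null)
    fits[[vv]] <- fit
  }

  e_grid <- sort(unique(table$expected))
  funnel <- funnel_limits(e_grid, alpha = attr(screen, "alpha"),
                          pvals = screen$p_value,
                          q_threshold = q_threshold)
  qq_p <- qq_exponential(screen$p_value)

  manifest <- list(
    package = "trimix",
    version = as.character(utils::packageVersion("trimix")),
    seed = seed,
    data = data_cfg, screen = c(screen_cfg,
                                list(pi0_hat = attr(screen, "pi0"))),
    fit = fit_cfg, variants = variants,
    thresholds = list(q = q_threshold, prob = prob_threshold,
                      inclusion = incl_threshold))

  out <- structure(list(areas = areas, screen = screen, fits = fits,
                        crosstabs = crosstabs, funnel = funnel,
                        qq_pvalues = qq_p, qq_rank = qq_rank,
                        manifest = manifest),
                   class = "trimix_report")
  if (!is.null(config$output_dir)) .write_report(out, config$output_dir)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$areas, file.path(dir, "areas.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(report$funnel),
                   file.path(dir, "funnel.csv"), row.names = FALSE)
  utils::write.csv(report$qq_pvalues, file.path(dir, "qq_pvalues.csv"),
                   row.names = FALSE)
  for (vv in names(report$qq_rank))
    utils::write.csv(as.data.frame(report$qq_rank[[vv]]),
                     file.path(dir, sprintf("qq_rank_%s.csv", vv)),
                     row.names = FALSE)
  ct_rows <- do.call(rbind, lapply(names(report$crosstabs), function(vv) {
    ct <- report$crosstabs[[vv]]
    data.frame(variant = vv, a = ct$table$a, b = ct$table$b,
               c = ct$table$c, n_neither = ct$table$n_neither,
               specific_agreement = ct$specific_agreement)
  }))
  if (!is.null(ct_rows))
    utils::write.csv(ct_rows, file.path(dir, "crosstabs.csv"),
                     row.names = FALSE)
  # p-value histogram bins, plot-ready
  h <- graphics::hist(report$screen$p_value, breaks = seq(0, 1, 0.05),
                      plot = FALSE)
  utils::write.csv(data.frame(mid = h$mids, count = h$counts),
                   file.path(dir, "pvalue_hist.csv"), row.names = FALSE)
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.trimix_report <- function(x, ...) {
  cat("trimix pipeline report:", nrow(x$areas), "areas;",
      "pi0_hat =", round(attr(x$screen, "pi0"), 3), "\n")
  for (vv in names(x$crosstabs)) {
    ct <- x$crosstabs[[vv]]
    cat(sprintf("  %s vs q-value: a=%d b=%d c=%d; specific agreement %s\n",
                vv, ct$table$a, ct$table$b, ct$table$c,
                if (is.na(ct$specific_agreement)) "undefined"
                else sprintf("%.0f%%", ct$specific_agreement)))
  }
  invisible(x)
}
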