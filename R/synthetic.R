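#' Rook-contiguity adjacency for a rectangular lattice
#'
#' Builds the neighbour structure of an `n_rows x n_cols` grid where two
#' cells are adjacent when they share an edge (rook moves). Optionally
#' drops trailing cells, which is how a grid is trimmed to an arbitrary
#' number of areas (e.g. 17 x 17 minus 2 cells gives 287 areas). Interior
#' cells have four neighbours, edges three, corners two -- neighbour counts
#' comparable to real municipal contiguity.
#'
#' @param n_rows,n_cols lattice dimensions (each at least 1).
#' @param drop number of trailing cells (row-major order) to remove.
#' @param ids optional character vector of cell labels (row-major order);
#'   default `"A001"...`.
#' @return An [adjacency_map()] over the retained cells.
#' @export
lattice_adjacency <- function(n_rows, n_cols, drop = 0, ids = NULL) {
  if (n_rows < 1 || n_cols < 1)
    stop("lattice dimensions must be at least 1", call. = FALSE)
  m_full <- n_rows * n_cols
  m <- m_full - drop
  if (m < 1) stop("dropping too many cells", call. = FALSE)
  if (is.null(ids)) ids <- sprintf("A%03d", seq_len(m))
  if (length(ids) != m) stop("need one id per retained cell", call. = FALSE)
  cell <- function(r, c) (r - 1L) * n_cols + c
  edges <- NULL
  right <- expand.grid(r = seq_len(n_rows), c = seq_len(n_cols - 1L))
  down <- expand.grid(r = seq_len(n_rows - 1L), c = seq_len(n_cols))
  e1 <- cbind(cell(right$r, right$c), cell(right$r, right$c + 1L))
  e2 <- cbind(cell(down$r, down$c), cell(down$r + 1L, down$c))
  edges <- rbind(e1, e2)
  keep <- edges[, 1] <= m & edges[, 2] <= m
  edges <- edges[keep, , drop = FALSE]
  adjacency_map(cbind(ids[edges[, 1]], ids[edges[, 2]]), area_ids = ids)
}

#' Generate a synthetic areal map with known truth
#'
#' Simulates the kind of map the methodology is aimed at: a few hundred
#' small areas with widely heterogeneous population sizes, almost all of
#' them at the reference risk, and a small fraction truly divergent. The
#' lattice provides a deterministic stand-in for municipal contiguity.
#'
#' Expected counts are drawn log-uniformly over `e_range` (default
#' `[0.5, 200]`), reproducing the funnel geometry of real municipal data
#' where tiny areas produce wildly unstable SMRs. A `Bernoulli(1 - pi0)`
#' draw selects the truly divergent areas (or, under
#' `effect_model = "cluster"`, one contiguous lattice patch of the same
#' expected size). Null areas have relative risk exactly 1; divergent
#' areas get `effect_size` under `"fixed"` (split half above, half below
#' 1 when `two_sided`), or a log-normal risk with standard deviation
#' `effect_size` on the log scale under `"lognormal"`. Counts are then
#' `Poisson(e_i * theta_i)`. Everything is reproducible from `seed`.
#'
#' @param n_rows,n_cols lattice dimensions.
#' @param drop trailing cells removed from the lattice (see
#'   [lattice_adjacency()]).
#' @param e_range range of expected counts (log-uniform draw).
#' @param pi0 true proportion of null areas in (0, 1]; default 0.97.
#' @param effect_model `"fixed"`, `"lognormal"` or `"cluster"`.
#' @param effect_size relative risk of divergent areas (`"fixed"`,
#'   `"cluster"`) or log-scale standard deviation (`"lognormal"`).
#' @param two_sided split fixed effects between `RR` and `1/RR`
#'   (default `TRUE`).
#' @param seed integer seed (required for reproducibility).
#' @return An object of class `synthetic_map`: list with `table`
#'   ([area_table()]), `adj` ([adjacency_map()]), `truth` (data frame
#'   `area_id`, `is_null` (1 = truly at the reference, the unknown true
#'   status indicator), `true_rr`), and `settings`.
#' @examples
#' map <- generate_map(17, 17, drop = 2, seed = 1)   # 287 areas
#' nrow(map$table)
#' sum(map$truth$is_null == 0)                       # divergent areas
#' @export
generate_map <- function(n_rows, n_cols, drop = 0,
                         e_range = c(0.5, 200), pi0 = 0.97,
                         effect_model = c("fixed", "lognormal", "cluster"),
                         effect_size = 2, two_sided = TRUE, seed = NULL) {
  effect_model <- match.arg(effect_model)
  if (!is.numeric(pi0) || pi0 <= 0 || pi0 > 1)
    stop("pi0 must lie in (0, 1]", call. = FALSE)
  if (length(e_range) != 2 || any(e_range <= 0) || e_range[1] > e_range[2])
    stop("e_range must be positive and ordered", call. = FALSE)
  if (effect_model != "lognormal" && effect_size <= 0)
    stop("effect_size must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  adj <- lattice_adjacency(n_rows, n_cols, drop = drop)
  ids <- names(adj$neighbours)
  m <- length(ids)
  e <- exp(stats::runif(m, log(e_range[1]), log(e_range[2])))

  n_div_target <- if (effect_model == "cluster")
    max(if (pi0 < 1) 1L else 0L, round((1 - pi0) * m)) else NA
  if (effect_model == "cluster") {
    divergent <- .lattice_patch(adj, ids, n_div_target)
  } else {
    divergent <- stats::runif(m) < (1 - pi0)
  }

  theta <- rep(1, m)
  nd <- sum(divergent)
  if (nd > 0) {
    theta[divergent] <- switch(effect_model,
      fixed = ,
      cluster = {
        rr <- rep(effect_size, nd)
        if (two_sided && nd > 1) {
          lower <- sample.int(nd, floor(nd / 2))
          rr[lower] <- 1 / effect_size
        }
        rr
      },
      lognormal = exp(stats::rnorm(nd, 0, effect_size)))
  }
  y <- stats::rpois(m, e * theta)
  table <- area_table(ids, y, e)
  truth <- data.frame(area_id = ids,
                      is_null = as.integer(!divergent),
                      true_rr = theta,
                      stringsAsFactors = FALSE)
  structure(list(table = table, adj = adj, truth = truth,
                 settings = list(n_rows = n_rows, n_cols = n_cols,
                                 drop = drop, e_range = e_range,
                                 pi0 = pi0, effect_model = effect_model,
                                 effect_size = effect_size,
                                 two_sided = two_sided, seed = seed)),
            class = "synthetic_map")
}

# grow one contiguous patch of `size` areas by breadth-first search from a
# random start cell
.lattice_patch <- function(adj, ids, size) {
  m <- length(ids)
  divergent <- rep(FALSE, m)
  if (size < 1) return(divergent)
  pos <- stats::setNames(seq_along(ids), ids)
  start <- sample.int(m, 1)
  queue <- ids[start]
  while (sum(divergent) < size && length(queue)) {
    cur <- queue[[1]]; queue <- queue[-1]
    if (divergent[pos[[cur]]]) next
    divergent[pos[[cur]]] <- TRUE
    nxt <- adj$neighbours[[cur]]
    queue <- c(queue, nxt[!divergent[pos[nxt]]])
  }
  divergent
}

#' @export
print.synthetic_map <- function(x, ...) {
  cat(sprintf(
    "synthetic_map: %d areas (%dx%d lattice%s), %d truly divergent (%s)\n",
    nrow(x$table), x$settings$n_rows, x$settings$n_cols,
    if (x$settings$drop) sprintf(" - %d cells", x$settings$drop) else "",
    sum(x$truth$is_null == 0), x$settings$effect_model))
  invisible(x)
}

#' False discovery proportion and sensitivity against known truth
#'
#' Given rejection flags and the true status of each area, counts the false
#' rejections `V` (areas rejected although truly null), total rejections
#' `R`, the false discovery proportion `V/R` (defined as 0 when nothing is
#' rejected), and the sensitivity (fraction of truly divergent areas that
#' were rejected).
#'
#' @param flags 0/1 rejection indicators.
#' @param is_null 0/1 true status (1 = truly null), e.g. the `is_null`
#'   column of a [generate_map()] truth table.
#' @return List of class `fdp_report`: `V`, `R`, `fdp`, `sensitivity`
#'   (`NA` when no area is truly divergent).
#' @export
evaluate_fdp <- function(flags, is_null) {
  if (length(flags) != length(is_null))
    stop("flags and truth must have equal length", call. = FALSE)
  flags <- as.integer(flags); is_null <- as.integer(is_null)
  V <- sum(is_null == 1L & flags == 1L)
  R <- sum(flags == 1L)
  n_div <- sum(is_null == 0L)
  structure(list(V = V, R = R,
                 fdp = if (R > 0) V / R else 0,
                 sensitivity = if (n_div > 0)
                   sum(is_null == 0L & flags == 1L) / n_div else NA_real_),
            class = "fdp_report")
}

#' @export
print.fdp_report <- function(x, ...) {
  cat(sprintf("rejections R = %d, false V = %d, FDP = %.3f, sensitivity = %s\n",
              x$R, x$V, x$fdp,
              if (is.na(x$sensitivity)) "NA"
              else sprintf("%.3f", x$sensitivity)))
  invisible(x)
}

#' Replicate a testing procedure over simulated maps
#'
#' Monte-Carlo estimate of the operating characteristics of a procedure:
#' generates `n_replicates` independent maps, applies the procedure, and
#' evaluates the false discovery proportion and sensitivity against the
#' known truth. The mean FDP estimates the FDR (the expectation of the FDP
#' over repeated experiments).
#'
#' @param procedure a function `function(table) -> 0/1 flags`, or one of
#'   the strings `"bh"` (plain BH at `level`), `"bonferroni"` (at
#'   `level`), `"qvalue"` (Storey q-values thresholded at `level`).
#' @param n_replicates number of simulated maps (at least 1).
#' @param level level passed to the named procedures (default 0.05).
#' @param seed integer seed; replicate seeds are derived from it.
#' @param ... map settings passed to [generate_map()] (e.g. `n_rows`,
#'   `n_cols`, `pi0`, `effect_size`).
#' @return Data frame of class `replicate_study` with one row per
#'   replicate (`V`, `R`, `fdp`, `sensitivity`); mean FDP, its Monte-Carlo
#'   standard error, and mean sensitivity are attached as attributes.
#' @examples
#' rs <- replicate_study("bh", n_replicates = 20, n_rows = 6, n_cols = 6,
#'                       pi0 = 0.95, seed = 1)
#' attr(rs, "mean_fdp")
#' @export
replicate_study <- function(procedure, n_replicates, level = 0.05,
                            seed = NULL, ...) {
  if (n_replicates < 1) stop("need at least one replicate", call. = FALSE)
  proc_fun <- if (is.function(procedure)) procedure else switch(
    match.arg(procedure, c("bh", "bonferroni", "qvalue")),
    bh = function(tab) {
      p <- poisson_pvalue(tab$observed, tab$expected)
      bh_procedure(p, level = level)
    },
    bonferroni = function(tab) {
      p <- poisson_pvalue(tab$observed, tab$expected)
      bonferroni(p, alpha = level)
    },
    qvalue = function(tab) {
      p <- poisson_pvalue(tab$observed, tab$expected)
      as.integer(qvalues(p) <= level)
    })
  if (!is.null(seed)) set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_replicates)
  rows <- vector("list", n_replicates)
  for (i in seq_len(n_replicates)) {
    map <- generate_map(..., seed = rep_seeds[i])
    rep <- evaluate_fdp(proc_fun(map$table), map$truth$is_null)
    rows[[i]] <- data.frame(replicate = i, V = rep$V, R = rep$R,
                            fdp = rep$fdp, sensitivity = rep$sensitivity)
  }
  out <- do.call(rbind, rows)
  attr(out, "mean_fdp") <- mean(out$fdp)
  attr(out, "se_fdp") <- stats::sd(out$fdp) / sqrt(n_replicates)
  attr(out, "mean_sensitivity") <- mean(out$sensitivity, na.rm = TRUE)
  class(out) <- c("replicate_study", "data.frame")
  out
}
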