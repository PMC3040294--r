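#' Spatial adjacency for areal data
#'
#' An `adjacency_map` stores, for each area, the set of its neighbours
#' (`S_i`) and the neighbour count (`n_i`). It drives the intrinsic CAR
#' prior of the BYM model variant, where each spatial effect is conditionally
#' normal around the mean of its neighbours with precision proportional to
#' the neighbour count. The structure is always symmetric and free of
#' self-loops; areas with no neighbours ("islands") are permitted and handled
#' by the sampler.
#'
#' @param edges two-column matrix or data frame of area-id pairs, one edge
#'   per row. Edges are symmetrized, so each pair needs to appear only once.
#' @param area_ids optional character vector of all area ids (e.g. from an
#'   [area_table()]); areas not touched by any edge become islands, and
#'   edges referring to ids outside this set raise an error.
#' @return An object of class `adjacency_map`: a list with `neighbours`
#'   (named list of character vectors, sorted) and `n` (named integer
#'   vector of neighbour counts).
#' @examples
#' adj <- adjacency_map(rbind(c("A", "B"), c("B", "C")))
#' adj$n  # A:1 B:2 C:1
#' @seealso [read_adjacency()], [lattice_adjacency()], [validate_map()]
#' @export
adjacency_map <- function(edges, area_ids = NULL) {
  edges <- as.matrix(edges)
  if (length(edges) && ncol(edges) != 2L)
    stop("edges must have two columns", call. = FALSE)
  storage.mode(edges) <- "character"
  if (any(edges[, 1] == edges[, 2]))
    stop("self-loop in adjacency: ",
         paste(unique(edges[edges[, 1] == edges[, 2], 1]), collapse = ", "),
         call. = FALSE)
  ids <- if (is.null(area_ids)) sort(unique(as.vector(edges)))
         else as.character(area_ids)
  unknown <- setdiff(unique(as.vector(edges)), ids)
  if (length(unknown))
    stop("adjacency refers to unknown area id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  nb <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) nb[[id]] <- character(0)
  if (nrow(edges)) {
    both <- rbind(edges, edges[, 2:1, drop = FALSE])
    sp <- split(both[, 2], factor(both[, 1], levels = ids))
    nb[] <- lapply(sp, function(x) sort(unique(x)))
  }
  structure(list(neighbours = nb,
                 n = vapply(nb, length, integer(1))),
            class = "adjacency_map")
}

#' @export
print.adjacency_map <- function(x, ...) {
  m <- length(x$neighbours)
  cat("adjacency_map:", m, "areas,", sum(x$n) / 2, "edges;",
      sum(x$n == 0), "island(s)\n")
  invisible(x)
}

#' Read spatial adjacency from a file
#'
#' Two dialects are supported. `"edges"` is a plain two-column delimited
#' file (whitespace, comma or tab) of area-id pairs, symmetrized on read.
#' `"winbugs"` is the positional `num`/`adj` vector format used by the
#' WinBUGS ecosystem: a small `key: values` text file with a `num` line
#' giving each area's neighbour count in table order and an `adj` line
#' concatenating the neighbour indices (1-based positions into the same
#' order). The WinBUGS dialect therefore requires `area_ids` to resolve
#' positions to labels, and the encoded structure must already be symmetric.
#'
#' @param file path to the adjacency file.
#' @param dialect `"edges"` or `"winbugs"`.
#' @param area_ids character vector of area ids in table order; required for
#'   the WinBUGS dialect, optional (membership check) for edge lists.
#' @return An [adjacency_map()].
#' @export
read_adjacency <- function(file, dialect = c("edges", "winbugs"),
                           area_ids = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "edges") {
    lines <- readLines(file)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (!length(lines)) return(adjacency_map(matrix(character(0), 0, 2),
                                             area_ids = area_ids))
    parts <- strsplit(lines, "[,\t ]+")
    bad <- which(lengths(parts) != 2L)
    if (length(bad))
      stop("malformed edge on line ", bad[1], call. = FALSE)
    adjacency_map(do.call(rbind, parts), area_ids = area_ids)
  } else {
    if (is.null(area_ids))
      stop("the WinBUGS num/adj dialect is positional: supply area_ids in ",
           "table order", call. = FALSE)
    kv <- .read_keyvals(file)
    for (key in c("num", "adj"))
      if (is.null(kv[[key]]))
        stop("WinBUGS adjacency file lacks a '", key, "' entry",
             call. = FALSE)
    num <- as.integer(strsplit(trimws(kv$num), "[,\t ]+")[[1]])
    adj <- as.integer(strsplit(trimws(kv$adj), "[,\t ]+")[[1]])
    m <- length(area_ids)
    if (length(num) != m)
      stop("'num' has ", length(num), " entries but the table has ", m,
           " areas", call. = FALSE)
    if (sum(num) != length(adj))
      stop("'adj' length ", length(adj), " does not match sum(num) = ",
           sum(num), call. = FALSE)
    if (any(adj < 1 | adj > m))
      stop("'adj' contains indices outside 1..", m, call. = FALSE)
    idx <- rep(seq_len(m), num)
    if (any(idx == adj))
      stop("self-loop in WinBUGS adjacency at area ", adj[idx == adj][1],
           call. = FALSE)
    # positional dialect carries no implicit symmetrization: verify it
    a <- pmin(idx, adj); b <- pmax(idx, adj)
    key <- paste(a, b)
    cnt <- table(key)
    if (any(cnt != 2L))
      stop("WinBUGS adjacency is not symmetric (e.g. pair ",
           names(cnt)[cnt != 2L][1], ")", call. = FALSE)
    keep <- idx < adj
    edges <- cbind(area_ids[idx[keep]], area_ids[adj[keep]])
    adjacency_map(edges, area_ids = area_ids)
  }
}

.read_keyvals <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  out <- list()
  key <- NULL
  for (ln in lines) {
    if (grepl("^[A-Za-z_][A-Za-z0-9_]*\\s*:", ln)) {
      key <- sub(":.*$", "", ln)
      out[[trimws(key)]] <- trimws(sub("^[^:]*:", "", ln))
    } else if (!is.null(key)) {
      out[[trimws(key)]] <- paste(out[[trimws(key)]], trimws(ln))
    }
  }
  out
}

#' Diagnose table/adjacency consistency
#'
#' Reports, without modifying either input, the features of a map that the
#' spatial model needs to know about: areas with no neighbours (islands),
#' the connected components of the adjacency graph, and any mismatch
#' between the table's area ids and the adjacency's.
#'
#' @param table an [area_table()].
#' @param adj an [adjacency_map()].
#' @return A list of class `map_diagnostics`: `islands` (ids with no
#'   neighbours, including table areas absent from the adjacency),
#'   `n_components` and `component` (membership vector over table areas),
#'   `missing_in_adjacency`, `extra_in_adjacency`.
#' @export
validate_map <- function(table, adj) {
  stopifnot(inherits(table, "area_table"), inherits(adj, "adjacency_map"))
  ids <- table$area_id
  missing <- setdiff(ids, names(adj$neighbours))
  extra <- setdiff(names(adj$neighbours), ids)
  comp <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  k <- 0L
  for (id in ids) {
    if (!is.na(comp[[id]])) next
    k <- k + 1L
    queue <- id
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      if (!is.na(comp[[cur]])) next
      comp[[cur]] <- k
      nbs <- intersect(adj$neighbours[[cur]], ids)
      queue <- c(queue, nbs[is.na(comp[nbs])])
    }
  }
  nb_count <- vapply(ids, function(id) {
    if (id %in% names(adj$neighbours))
      length(intersect(adj$neighbours[[id]], ids)) else 0L
  }, integer(1))
  structure(list(islands = ids[nb_count == 0L],
                 n_components = k,
                 component = comp,
                 missing_in_adjacency = missing,
                 extra_in_adjacency = extra),
            class = "map_diagnostics")
}

#' @export
print.map_diagnostics <- function(x, ...) {
  cat("map diagnostics:", length(x$component), "areas,",
      x$n_components, "connected component(s),",
      length(x$islands), "island(s)\n")
  if (length(x$islands))
    cat("  islands:", paste(x$islands, collapse = ", "), "\n")
  if (length(x$missing_in_adjacency))
    cat("  absent from adjacency:",
        paste(x$missing_in_adjacency, collapse = ", "), "\n")
  if (length(x$extra_in_adjacency))
    cat("  adjacency-only ids:",
        paste(x$extra_in_adjacency, collapse = ", "), "\n")
  invisible(x)
}

# Re-index an adjacency_map against the row order of an area_table,
# returning integer neighbour lists (and a flat edge matrix) for samplers.
.adj_index <- function(table, adj) {
  ids <- table$area_id
  missing <- setdiff(ids, names(adj$neighbours))
  if (length(missing))
    stop("adjacency does not cover area(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  pos <- stats::setNames(seq_along(ids), ids)
  nb <- lapply(ids, function(id) {
    unname(pos[intersect(adj$neighbours[[id]], ids)])
  })
  n <- lengths(nb)
  ii <- rep(seq_along(ids), n)
  jj <- unlist(nb, use.names = FALSE)
  keep <- ii < jj
  list(nb = nb, n = n,
       edges = cbind(ii[keep], jj[keep]))
}
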