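#' Summarization configuration
#'
#' @param mode `"single"` (remove the minimum-change edge each round) or
#'   `"multi"` (remove every candidate below the threshold each round).
#' @param threshold Relative change in the second-smallest Laplacian
#'   eigenvalue above which pruning stops (default 0.05). Interpreted as a
#'   fraction, i.e. 0.05 means a 5% relative change.
#' @param target_ratio Fraction of the initial edges to remove, in [0, 1],
#'   or `NULL`. When set, the ratio drives the loop and the threshold is
#'   not consulted.
#' @param with_data Re-estimate conditional probability tables from a
#'   supporting cohort once pruning ends?
#' @param roots Node indices/labels rooting the protective depth-first
#'   spanning forest; default all year-1 nodes of a temporal network, else
#'   node 1.
#' @param laplacian A [lap_config()] for the eigenvalue computations.
#' @param pseudo_count Smoothing for the re-estimated tables.
#' @return A list of class `summarize_config`.
#' @export
summarize_config <- function(mode = c("single", "multi"), threshold = 0.05,
                             target_ratio = NULL, with_data = FALSE,
                             roots = NULL, laplacian = NULL,
                             pseudo_count = 1) {
  mode <- match.arg(mode)
  if (!is.numeric(threshold) || threshold <= 0)
    stop("threshold must be > 0")
  if (!is.null(target_ratio) &&
      (!is.numeric(target_ratio) || target_ratio < 0 || target_ratio > 1))
    stop("target_ratio must be in [0, 1]")
  structure(list(mode = mode, threshold = threshold,
                 target_ratio = target_ratio, with_data = isTRUE(with_data),
                 roots = roots, laplacian = laplacian,
                 pseudo_count = pseudo_count),
            class = "summarize_config")
}

default_roots <- function(g) {
  pl <- parse_node_label(g$labels)
  if (!anyNA(pl$year) && any(pl$year == 1L)) which(pl$year == 1L) else 1L
}

#' Depth-first-search protected edges
#'
#' Builds a spanning forest of the undirected view of the graph by
#' depth-first search rooted at `roots` (components containing no root are
#' spanned from their smallest-index node), visiting neighbors in index
#' order. The forest's edges are protected: the summarizer never removes
#' them, which guarantees no node becomes isolated.
#'
#' @param g An [mcc_graph()].
#' @param roots Root node indices or labels (default [default_roots()]:
#'   year-1 nodes for temporal networks, else node 1).
#' @return Integer vector of protected edge row indices into `g$edges`,
#'   with attribute `tree` (data frame `from`, `to` of the DFS arcs in
#'   visit order).
#' @export
protected_edges <- function(g, roots = default_roots(g)) {
  stopifnot(inherits(g, "mcc_graph"))
  n <- n_nodes(g)
  if (n == 0L) stop("empty graph")
  roots <- resolve_nodes(roots, g$labels)
  adj <- undirected_adjacency_list(g)
  visited <- rep(FALSE, n)
  tree <- data.frame(from = integer(), to = integer())
  dfs <- function(r) {
    stack <- list(c(NA_integer_, r))
    while (length(stack)) {
      top <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      par <- top[1L]; v <- top[2L]
      if (visited[v]) next
      visited[v] <<- TRUE
      if (!is.na(par))
        tree <<- rbind(tree, data.frame(from = par, to = v))
      for (w in rev(adj[[v]])) if (!visited[w])
        stack[[length(stack) + 1L]] <- c(v, w)
    }
  }
  for (r in roots) if (!visited[r]) dfs(r)
  for (r in seq_len(n)) if (!visited[r] && length(adj[[r]])) dfs(r)
  # map undirected tree edges back to edge rows (either orientation)
  prot <- integer(0)
  for (k in seq_len(nrow(tree))) {
    a <- tree$from[k]; b <- tree$to[k]
    hit <- which((g$edges$from == a & g$edges$to == b) |
                   (g$edges$from == b & g$edges$to == a))
    prot <- c(prot, hit)
  }
  structure(sort(unique(prot)), tree = tree)
}

#' Rank removable edges by their effect on algebraic connectivity
#'
#' Scores every non-protected edge by [delta_lambda2()] (temporary
#' removal; the graph is not modified) and returns them sorted ascending,
#' ties broken lexicographically by (source, target) index.
#'
#' @param g An [mcc_graph()].
#' @param protected Integer edge row indices to exclude (see
#'   [protected_edges()]).
#' @param config A [lap_config()].
#' @return Data frame with columns `edge` (row index into `g$edges`),
#'   `from`, `to`, `delta` and `relative`, sorted ascending by `delta`.
#' @export
rank_candidates <- function(g, protected = integer(0),
                            config = default_lap_config(g)) {
  cand <- setdiff(seq_len(n_edges(g)), protected)
  if (length(cand) == 0L)
    return(data.frame(edge = integer(), from = integer(), to = integer(),
                      delta = double(), relative = logical()))
  res <- lapply(cand, function(k) {
    d <- delta_lambda2(g, c(g$edges$from[k], g$edges$to[k]), config)
    data.frame(edge = k, from = g$edges$from[k], to = g$edges$to[k],
               delta = as.numeric(d), relative = attr(d, "relative"))
  })
  out <- do.call(rbind, res)
  out[order(out$delta, out$from, out$to), , drop = FALSE]
}

#' Summarize a graphical model by spectral edge pruning
#'
#' Greedy EAGL summarization of an existing model: a depth-first spanning
#' forest is extracted once and protected, then edges whose removal least
#' changes the second-smallest Laplacian eigenvalue are pruned — one per
#' round (`mode = "single"`) or all below the threshold per round
#' (`mode = "multi"`) — until the minimum relative change exceeds the
#' threshold or the requested fraction of edges has been removed. With
#' supporting data the conditional probability tables are re-estimated on
#' the final structure; without, the remaining edge weights pass through
#' unchanged.
#'
#' @param model An [mcc_graph()], an `mcc_bn`, or an `eagl_fit`.
#' @param cohort Supporting cohort table; required iff
#'   `config$with_data`.
#' @param config A [summarize_config()]. `with_data` is implied by
#'   supplying `cohort`.
#' @return An object of class `eagl_summary`: list with `graph` (pruned),
#'   `net` (re-estimated `mcc_bn` if data were supplied, else `NULL`),
#'   `trace` (data frame: `round`, `from`, `to`, `delta`, `relative`,
#'   `lambda2_after`), `protected` (edge list of the frozen skeleton),
#'   `e0`, `removed`, `report` (see [summarization_report()]), `config`,
#'   and `warning` (e.g. when the ratio could not be met without touching
#'   protected edges).
#' @export
eagl_summarize <- function(model, cohort = NULL,
                           config = summarize_config()) {
  g <- if (inherits(model, "mcc_graph")) model
       else if (inherits(model, "mcc_bn")) model$graph
       else if (inherits(model, "eagl_fit")) model$graph
       else stop("model must be an mcc_graph, mcc_bn or eagl_fit")
  if (!is.null(cohort)) config$with_data <- TRUE
  if (config$with_data && is.null(cohort))
    stop("with_data summarization requires a cohort")
  lap <- if (is.null(config$laplacian)) default_lap_config(g)
         else config$laplacian
  roots <- if (is.null(config$roots)) default_roots(g)
           else resolve_nodes(config$roots, g$labels)
  e0 <- n_edges(g)
  if (e0 == 0L) stop("model has no edges")
  l2_0 <- lambda2(g, lap)
  prot_idx <- protected_edges(g, roots)
  prot_keys <- paste(g$edges$from[prot_idx], g$edges$to[prot_idx])

  target_p <- if (is.null(config$target_ratio)) NULL
              else floor(config$target_ratio * e0 + 1e-9)
  trace <- data.frame(round = integer(), from = integer(), to = integer(),
                      delta = double(), relative = logical(),
                      lambda2_after = double())
  warn <- NULL
  round_i <- 0L
  repeat {
    removed <- nrow(trace)
    if (!is.null(target_p) && removed >= target_p) break
    prot_now <- which(paste(g$edges$from, g$edges$to) %in% prot_keys)
    ranked <- rank_candidates(g, prot_now, lap)
    if (nrow(ranked) == 0L) {
      if (!is.null(target_p) && removed < target_p) {
        warn <- sprintf(
          "target ratio requires removing %d edges but only %d were removable without touching the protected skeleton",
          target_p, removed)
        warning(warn)
      }
      break
    }
    if (is.null(target_p) && ranked$delta[1L] > config$threshold) break
    round_i <- round_i + 1L
    take <- if (config$mode == "single") {
      1L
    } else {
      if (is.null(target_p)) {
        max(1L, sum(ranked$delta < config$threshold))
      } else {
        min(nrow(ranked), target_p - removed)
      }
    }
    if (!is.null(target_p)) take <- min(take, target_p - removed)
    for (j in seq_len(take)) {
      g <- drop_edge(g, ranked$from[j], ranked$to[j])
      trace <- rbind(trace, data.frame(
        round = round_i, from = ranked$from[j], to = ranked$to[j],
        delta = ranked$delta[j], relative = ranked$relative[j],
        lambda2_after = lambda2(g, lap)))
    }
  }
  net <- if (config$with_data)
    fit_cpts(g, cohort, pseudo_count = config$pseudo_count) else NULL
  trace$from_label <- g$labels[trace$from]
  trace$to_label <- g$labels[trace$to]
  report <- list(edges_before = e0, edges_after = n_edges(g),
                 percent_removed = round_half_up(
                   100 * (e0 - n_edges(g)) / e0, 2),
                 percent_removed_raw = 100 * (e0 - n_edges(g)) / e0,
                 lambda2_before = l2_0,
                 lambda2_after = if (n_edges(g) > 0L) lambda2(g, lap) else 0)
  structure(list(graph = g, net = net, trace = trace,
                 protected = data.frame(
                   from = attr(prot_idx, "tree")$from,
                   to = attr(prot_idx, "tree")$to),
                 e0 = e0, removed = nrow(trace), report = report,
                 config = config, laplacian = lap, roots = roots,
                 warning = warn),
            class = "eagl_summary")
}

round_half_up <- function(x, digits = 2) floor(x * 10^digits + 0.5) / 10^digits

#' Edge-accounting report of a summarization run
#'
#' @param x An `eagl_summary` (or its `trace` plus `e0`).
#' @return Named list: `edges_before`, `edges_after`, `percent_removed`
#'   (half-up rounded to 2 decimals for display), `percent_removed_raw`,
#'   `lambda2_before`, `lambda2_after`.
#' @export
summarization_report <- function(x) {
  stopifnot(inherits(x, "eagl_summary"))
  if (x$e0 == 0L) stop("report undefined for an edgeless model")
  x$report
}

#' Edge-removal percentage from raw edge counts
#'
#' `100 * (e0 - e_final) / e0`, rounded half-up to two decimals the way the
#' package displays it (e.g. 141 -> 39 edges gives 72.34).
#'
#' @param e0 Initial edge count (> 0).
#' @param e_final Remaining edge count.
#' @return A double.
#' @export
edge_removal_percent <- function(e0, e_final) {
  if (e0 <= 0) stop("e0 must be positive")
  round_half_up(100 * (e0 - e_final) / e0, 2)
}

#' @export
print.eagl_summary <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "EAGL summarization (%s mode%s)\n  edges %d -> %d (%.2f%% removed), lambda2 %.4f -> %.4f\n",
    x$config$mode,
    if (x$config$with_data) ", with data" else ", data-free",
    r$edges_before, r$edges_after, r$percent_removed,
    r$lambda2_before, r$lambda2_after))
  if (!is.null(x$warning)) cat("  note:", x$warning, "\n")
  invisible(x)
}

#' @export
summary.eagl_summary <- function(object, ...) {
  out <- c(object$report, list(removed_edges = object$trace[
    , c("round", "from_label", "to_label", "delta", "lambda2_after")]))
  class(out) <- "summary.eagl_summary"
  out
}

#' @export
print.summary.eagl_summary <- function(x, ...) {
  cat(sprintf("edges %d -> %d, removed %.2f%%\n", x$edges_before,
              x$edges_after, x$percent_removed))
  cat(sprintf("lambda2 %.6f -> %.6f\n", x$lambda2_before, x$lambda2_after))
  print(x$removed_edges, row.names = FALSE)
  invisible(x)
}

#' Plot the eigenvalue trajectory of a summarization run
#'
#' Second-smallest Laplacian eigenvalue after each removed edge (the
#' connectivity decay the stopping rule watches).
#'
#' @param x An `eagl_summary`.
#' @param ... Passed to [plot()].
#' @export
plot.eagl_summary <- function(x, ...) {
  if (nrow(x$trace) == 0L) {
    plot.new(); title("no edges removed"); return(invisible(x))
  }
  plot(seq_len(nrow(x$trace)), x$trace$lambda2_after, type = "b",
       xlab = "edges removed", ylab = expression(lambda[2]),
       main = "Connectivity decay during summarization", ...)
  invisible(x)
}
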