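# Coerce a cohort (data frame with optional patient_id, or matrix) to a
# 0/1 integer matrix with named columns.
cohort_matrix <- function(cohort) {
  if (is.matrix(cohort)) {
    X <- cohort
  } else {
    df <- as.data.frame(cohort)
    df$patient_id <- NULL
    X <- as.matrix(df)
  }
  if (is.null(colnames(X))) stop("cohort columns must be named")
  storage.mode(X) <- "integer"
  if (anyNA(X)) stop("cohort contains missing values; rows with missing ",
                     "entries are not supported")
  if (any(X != 0L & X != 1L)) {
    bad <- which(X != 0L & X != 1L, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-binary cell at row %d, column '%s'",
                 bad[1L], colnames(X)[bad[2L]]))
  }
  X
}

#' Estimate conditional probability tables for a given structure
#'
#' Additive (Laplace) smoothing:
#' \code{P(x = 1 | pa) = (N(1, pa) + pseudo_count) / (N(pa) + 2 pseudo_count)}.
#' With `pseudo_count = 0`, a parent configuration never observed is set to
#' 0.5 and flagged in the table's `flagged` column.
#'
#' @param graph A directed acyclic [mcc_graph()] whose labels name cohort
#'   columns.
#' @param cohort Binary cohort table covering every node.
#' @param pseudo_count Nonnegative smoothing constant (default 1).
#' @return An object of class `mcc_bn`: list with `graph` and `cpts` — one
#'   entry per node, each a list with `node`, `parents` (labels), and
#'   `table`: data frame with one row per parent configuration (columns
#'   `config` list of 0/1, `p1`, `n`, `flagged`). Configurations are
#'   ordered with the first parent as the fastest-varying bit.
#' @export
fit_cpts <- function(graph, cohort, pseudo_count = 1) {
  stopifnot(inherits(graph, "mcc_graph"), graph$directed)
  if (!is_dag(graph)) stop("graph must be acyclic")
  X <- cohort_matrix(cohort)
  missing_cols <- setdiff(graph$labels, colnames(X))
  if (length(missing_cols))
    stop("cohort lacks column(s): ", paste(missing_cols, collapse = ", "))
  parents <- parent_sets(graph)
  cpts <- lapply(seq_along(graph$labels), function(i) {
    pa <- parents[[i]]
    cnt <- family_counts(graph$labels[i], graph$labels[pa], X)
    Nj <- colSums(cnt)
    p1 <- (cnt[2L, ] + pseudo_count) / (Nj + 2 * pseudo_count)
    flagged <- pseudo_count == 0 & Nj == 0
    p1[flagged] <- 0.5
    k <- length(pa)
    cfg <- lapply(seq_len(2^k) - 1L, function(j)
      as.integer(intToBits(j)[seq_len(max(k, 1))][seq_len(k)]))
    list(node = graph$labels[i], parents = graph$labels[pa],
         table = data.frame(config = I(cfg), p1 = p1, n = Nj,
                            flagged = flagged))
  })
  names(cpts) <- graph$labels
  structure(list(graph = graph, cpts = cpts,
                 pseudo_count = pseudo_count), class = "mcc_bn")
}

#' @export
print.mcc_bn <- function(x, ...) {
  cat(sprintf("<mcc_bn> %d nodes, %d edges, pseudo_count = %g\n",
              n_nodes(x$graph), n_edges(x$graph), x$pseudo_count))
  invisible(x)
}

#' @export
coef.mcc_bn <- function(object, ...) {
  do.call(rbind, lapply(object$cpts, function(cp) {
    data.frame(node = cp$node,
               parents = paste(cp$parents, collapse = ","),
               config = vapply(cp$table$config, paste, character(1),
                               collapse = ""),
               p1 = cp$table$p1, row.names = NULL)
  }))
}

# P(node = value | parent values), vectorized over a named assignment.
cpt_lookup <- function(cp, assignment) {
  k <- length(cp$parents)
  idx <- if (k == 0L) 1L else
    1L + sum(assignment[cp$parents] * 2^(seq_len(k) - 1L))
  cp$table$p1[idx]
}

#' Joint probability of a full assignment
#'
#' Product of the per-node conditional probabilities (the Bayesian-network
#' decomposition of the joint distribution).
#'
#' @param net An `mcc_bn` (see [fit_cpts()]).
#' @param assignment Named 0/1 vector covering every node.
#' @return A single probability.
#' @export
joint_probability <- function(net, assignment) {
  labs <- net$graph$labels
  if (!all(labs %in% names(assignment)))
    stop("assignment must cover every node; use posterior_prob() for ",
         "partial evidence")
  assignment <- assignment[labs]
  prod(vapply(net$cpts, function(cp) {
    p1 <- cpt_lookup(cp, assignment)
    if (assignment[cp$node] == 1L) p1 else 1 - p1
  }, numeric(1)))
}

# ---- factor machinery for variable elimination --------------------------
# A factor is list(vars = integer node ids, values = numeric of length
# 2^{|vars|}), values indexed with vars[1] as the fastest-varying bit.

factor_from_cpt <- function(cp, node_index) {
  vars <- c(node_index[cp$node], node_index[cp$parents])
  k <- length(cp$parents)
  vals <- numeric(2^(k + 1))
  for (j in seq_len(2^k)) {
    p1 <- cp$table$p1[j]
    # child bit fastest: index = child + 2 * (config j - 1) + 1
    vals[2L * (j - 1L) + 1L] <- 1 - p1
    vals[2L * (j - 1L) + 2L] <- p1
  }
  list(vars = vars, values = vals)
}

factor_restrict <- function(f, var, value) {
  pos <- match(var, f$vars)
  if (is.na(pos)) return(f)
  k <- length(f$vars)
  idx <- seq_len(2^k) - 1L
  keep <- bitwAnd(idx %/% 2^(pos - 1L), 1L) == value
  list(vars = f$vars[-pos], values = f$values[keep])
}

factor_product <- function(f, g) {
  vars <- union(f$vars, g$vars)
  k <- length(vars)
  idx <- seq_len(2^k) - 1L
  bits <- vapply(seq_len(k), function(b) bitwAnd(idx %/% 2^(b - 1L), 1L),
                 integer(length(idx)))
  if (length(idx) == 1L) bits <- matrix(bits, nrow = 1L)
  sub_index <- function(h) {
    pos <- match(h$vars, vars)
    if (length(pos) == 0L) return(rep(1L, length(idx)))
    1L + as.integer(bits[, pos, drop = FALSE] %*% 2^(seq_along(pos) - 1L))
  }
  list(vars = vars, values = f$values[sub_index(f)] * g$values[sub_index(g)])
}

factor_marginalize <- function(f, var) {
  pos <- match(var, f$vars)
  if (is.na(pos)) return(f)
  k <- length(f$vars)
  idx <- seq_len(2^k) - 1L
  bit <- bitwAnd(idx %/% 2^(pos - 1L), 1L)
  # bit=0 and bit=1 subsets align on the remaining-variable index
  list(vars = f$vars[-pos],
       values = f$values[bit == 0L] + f$values[bit == 1L])
}

#' Exact posterior probability by variable elimination
#'
#' Computes \code{P(query = 1 | evidence)} exactly, eliminating hidden
#' variables in reverse topological order.
#'
#' @param net An `mcc_bn`.
#' @param evidence Named 0/1 vector (possibly empty) of observed nodes.
#' @param query Node label (not in evidence).
#' @return A single probability.
#' @export
posterior_prob <- function(net, evidence, query) {
  labs <- net$graph$labels
  node_index <- stats::setNames(seq_along(labs), labs)
  if (!query %in% labs) stop("unknown query node: ", query)
  if (query %in% names(evidence)) stop("query node is in the evidence")
  if (length(evidence) && !all(names(evidence) %in% labs))
    stop("unknown evidence node(s)")
  factors <- lapply(net$cpts, factor_from_cpt, node_index = node_index)
  for (ev in names(evidence))
    factors <- lapply(factors, factor_restrict, var = node_index[[ev]],
                      value = as.integer(evidence[[ev]]))
  topo <- topological_order(net$graph)
  hidden <- rev(topo)
  hidden <- hidden[!(labs[hidden] %in% c(query, names(evidence)))]
  for (h in hidden) {
    involved <- vapply(factors, function(f) h %in% f$vars, logical(1))
    if (!any(involved)) next
    prod_f <- Reduce(factor_product, factors[involved])
    factors <- c(factors[!involved],
                 list(factor_marginalize(prod_f, h)))
  }
  final <- Reduce(factor_product, factors)
  qpos <- node_index[[query]]
  p1 <- factor_restrict(final, qpos, 1L)$values
  p0 <- factor_restrict(final, qpos, 0L)$values
  z <- sum(p1) + sum(p0)
  if (z <= 0) stop("impossible evidence: P(evidence) = 0 under the network")
  sum(p1) / z
}

#' Year-ahead prediction scores from year-1 evidence
#'
#' For each cohort row, the exact posterior probability of the target
#' (condition, year) node given that row's year-1 condition values as
#' evidence. With `cumulative = TRUE` all years strictly before the target
#' year are used as evidence instead.
#'
#' @param net An `mcc_bn` over condition-year nodes.
#' @param cohort Cohort rows supplying the evidence columns.
#' @param condition Target condition name.
#' @param year Target year (>= 2).
#' @param cumulative Use all years `< year` as evidence (default FALSE:
#'   year 1 only).
#' @return Numeric vector of probabilities, one per row.
#' @export
predict_future <- function(net, cohort, condition, year, cumulative = FALSE) {
  if (year < 2) stop("target year must be >= 2")
  target <- paste0(condition, "_Y", year)
  labs <- net$graph$labels
  if (!target %in% labs) stop("unknown target node: ", target)
  pl <- parse_node_label(labs)
  ev_nodes <- labs[!is.na(pl$year) &
                     (if (cumulative) pl$year < year else pl$year == 1L)]
  ev_nodes <- setdiff(ev_nodes, target)
  X <- cohort_matrix(cohort)
  missing_cols <- setdiff(ev_nodes, colnames(X))
  if (length(missing_cols))
    stop("cohort lacks evidence column(s): ",
         paste(missing_cols, collapse = ", "))
  E <- X[, ev_nodes, drop = FALSE]
  key <- apply(E, 1L, paste, collapse = "")
  uniq <- !duplicated(key)
  scores_by_key <- vapply(which(uniq), function(r) {
    posterior_prob(net, stats::setNames(as.integer(E[r, ]), ev_nodes), target)
  }, numeric(1))
  names(scores_by_key) <- key[uniq]
  unname(scores_by_key[key])
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC with half-credit for tied scores.
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 outcome labels; both classes must be present.
#' @return A single number in [0, 1].
#' @examples
#' roc_auc(c(0.9, 0.4, 0.6, 0.2), c(1, 1, 0, 0))  # 0.75
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("AUC undefined: both outcome classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-validated AUC evaluation of a learning pipeline
#'
#' Shuffles patients by `seed`, splits them into `k` near-equal folds, fits
#' `pipeline` on each training set and scores year-ahead predictions on the
#' held-out fold, reporting one AUC per (condition, prediction year, fold).
#'
#' @param cohort Binary cohort table with condition-year columns.
#' @param pipeline Function `(train_cohort) -> mcc_bn` (or an object with
#'   a `$net` element, e.g. an `eagl_fit`).
#' @param k Number of folds (default 10).
#' @param seed Integer seed controlling the fold split.
#' @param setting Free-form label recorded in the output (e.g. the lambda
#'   or summarization ratio used by the pipeline).
#' @param conditions,years Targets to evaluate; default every condition and
#'   every year >= 2 found in the columns.
#' @return A data frame of class `eagl_evaluation` with columns
#'   `condition`, `year`, `setting`, `fold`, `auc` (NA, with a warning
#'   recorded in attribute `skipped`, when a fold's test outcome is
#'   single-class), plus attribute `means`: mean AUC per (condition, year).
#' @export
cross_validate <- function(cohort, pipeline, k = 10L, seed = 1L,
                           setting = NA, conditions = NULL, years = NULL) {
  X <- cohort_matrix(cohort)
  m <- nrow(X)
  if (k < 2L) stop("k must be >= 2")
  if (k > m) stop("more folds than observations")
  pl <- parse_node_label(colnames(X))
  if (anyNA(pl$year)) stop("cohort columns must be condition-year labelled")
  if (is.null(conditions)) conditions <- unique(pl$condition)
  if (is.null(years)) years <- sort(unique(pl$year[pl$year >= 2L]))
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  fold <- sample(rep(seq_len(k), length.out = m))
  rows <- list(); skipped <- character(0)
  for (f in seq_len(k)) {
    train <- X[fold != f, , drop = FALSE]
    test <- X[fold == f, , drop = FALSE]
    fit <- pipeline(train)
    net <- if (inherits(fit, "mcc_bn")) fit else fit$net
    for (cond in conditions) for (yr in years) {
      target <- paste0(cond, "_Y", yr)
      if (!target %in% colnames(test)) next
      y <- test[, target]
      auc <- if (length(unique(y)) < 2L) {
        skipped <- c(skipped, sprintf("fold %d %s", f, target))
        NA_real_
      } else {
        roc_auc(predict_future(net, test, cond, yr), y)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, year = yr, setting = setting, fold = f, auc = auc)
    }
  }
  out <- do.call(rbind, rows)
  means <- stats::aggregate(auc ~ condition + year, data = out, FUN = mean,
                            na.rm = TRUE, na.action = NULL)
  structure(out, means = means, skipped = skipped, seed = seed,
            class = c("eagl_evaluation", "data.frame"))
}
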