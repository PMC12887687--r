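# Per-window co-occurrence networks over conditions, degree centrality,
# characteristic-condition extraction with dual-control validation, and a
# score-based Bayesian-network learner over binary indicators.

#' Build an undirected co-occurrence network for one time window
#'
#' Nodes are conditions whose cumulative prevalence in the window reaches
#' `min_node_prev`; an edge joins two conditions when the number of
#' participants with both present reaches the edge threshold. Edge weights
#' are raw co-occurrence counts with their support fraction; an alternative
#' phi-coefficient edge rule is available.
#'
#' @param pm A `presence_matrix`.
#' @param min_node_prev Node prevalence floor (default 0.01).
#' @param min_edge_count Minimum co-occurrence count for an edge; default
#'   `max(5, 0.005 * n)`.
#' @param edge_method `"count"` (default) or `"phi"` (phi coefficient
#'   threshold via `min_phi` on pairs passing a minimal count of 1).
#' @param min_phi Phi threshold when `edge_method = "phi"` (default 0.1).
#' @param cohort Optional cohort label carried in the result.
#' @return Object of class `comorbidity_network`: `nodes` (condition,
#'   count, prevalence), `edges` (`u`, `v`, `count`, `support`, and `phi`
#'   when applicable), `centrality` (named vector, degree/(|V|-1)), `n`,
#'   `window`, `cohort`.
#' @export
build_cooccurrence_network <- function(pm, min_node_prev = 0.01,
                                       min_edge_count = NULL,
                                       edge_method = c("count", "phi"),
                                       min_phi = 0.1, cohort = NA_character_) {
  edge_method <- match.arg(edge_method)
  X <- presence_indicator(pm)
  n <- nrow(X)
  if (n == 0L || ncol(X) == 0L) {
    warning("empty presence matrix; returning empty network", call. = FALSE)
    return(.empty_network(pm$window, cohort, n))
  }
  if (is.null(min_edge_count)) min_edge_count <- max(5, ceiling(0.005 * n))
  cnt <- colSums(X)
  keep <- cnt / n >= min_node_prev
  X <- X[, keep, drop = FALSE]
  cnt <- cnt[keep]
  if (!ncol(X)) return(.empty_network(pm$window, cohort, n))
  co <- crossprod(X)
  diag(co) <- 0
  idx <- which(upper.tri(co) & co >= min_edge_count, arr.ind = TRUE)
  edges <- data.table::data.table(
    u = colnames(X)[idx[, 1L]], v = colnames(X)[idx[, 2L]],
    count = co[idx], support = co[idx] / n)
  if (edge_method == "phi") {
    idx <- which(upper.tri(co) & co >= 1, arr.ind = TRUE)
    a <- co[idx]
    ki <- cnt[idx[, 1L]]; kj <- cnt[idx[, 2L]]
    phi <- (n * a - ki * kj) /
      sqrt(ki * (n - ki) * kj * (n - kj))
    keep_e <- is.finite(phi) & phi >= min_phi
    edges <- data.table::data.table(
      u = colnames(X)[idx[keep_e, 1L]], v = colnames(X)[idx[keep_e, 2L]],
      count = a[keep_e], support = a[keep_e] / n, phi = phi[keep_e])
  }
  net <- structure(list(
    nodes = data.table::data.table(condition = colnames(X), count = cnt,
                                   prevalence = cnt / n),
    edges = edges, n = n, window = pm$window, cohort = cohort),
    class = "comorbidity_network")
  net$centrality <- degree_centrality(net)
  net
}

.empty_network <- function(window, cohort, n) {
  structure(list(
    nodes = data.table::data.table(condition = character(0), count = integer(0),
                                   prevalence = numeric(0)),
    edges = data.table::data.table(u = character(0), v = character(0),
                                   count = numeric(0), support = numeric(0)),
    centrality = stats::setNames(numeric(0), character(0)),
    n = n, window = window, cohort = cohort), class = "comorbidity_network")
}

#' @export
print.comorbidity_network <- function(x, ...) {
  cat(sprintf("comorbidity_network: window '%s'%s, %d nodes, %d edges (n = %d)\n",
              x$window, if (is.na(x$cohort)) "" else paste0(", cohort ", x$cohort),
              nrow(x$nodes), nrow(x$edges), x$n))
  invisible(x)
}

#' Degree centrality of a co-occurrence network
#'
#' `degree(v) / (|V| - 1)`, in `[0, 1]`; networks with fewer than two nodes
#' score 0 everywhere. Conditions scoring in `[0.5, 1]` are conventionally
#' called central.
#'
#' @param net A `comorbidity_network`.
#' @return Named numeric vector over the network's nodes.
#' @export
degree_centrality <- function(net) {
  v <- net$nodes$condition
  if (length(v) < 2L) return(stats::setNames(rep(0, length(v)), v))
  deg <- table(factor(c(net$edges$u, net$edges$v), levels = v))
  stats::setNames(as.numeric(deg) / (length(v) - 1L), v)
}

#' Identify characteristic conditions across windows
#'
#' A condition is characteristic of a cohort in a window when it is a node of
#' the cohort's window network but not of the matched-control network built
#' with identical thresholds. Its status is `new` in the chronologically
#' first window where it is characteristic and `re-occurring` thereafter.
#' When a control-disease characteristic set is supplied (conditions
#' characteristic of e.g. the hip-fracture cohort vs its own controls, any
#' window), conditions also present there are marked `validated = FALSE`.
#'
#' @param cohort_nets Named list of `comorbidity_network`s keyed by window
#'   label, in chronological order.
#' @param control_nets Matching named list for the matched controls.
#' @param disease_characteristic Character vector of conditions
#'   characteristic of the control-disease cohort (see
#'   [control_disease_characteristic_set()]), or `NULL` to skip validation.
#' @param mwu_significant Optional character vector of conditions significant
#'   in the Mann-Whitney prevalence layer; recorded as an annotation column.
#' @return `data.table`: `window`, `condition`, `status`,
#'   `in_control_disease_net`, `validated`, `mwu_overlap`.
#' @export
characteristic_conditions <- function(cohort_nets, control_nets,
                                      disease_characteristic = NULL,
                                      mwu_significant = NULL) {
  rows <- list()
  seen <- character(0)
  for (w in names(cohort_nets)) {
    if (is.null(control_nets[[w]])) {
      warning(sprintf("no control network for window '%s'; skipped", w),
              call. = FALSE)
      next
    }
    ch <- setdiff(cohort_nets[[w]]$nodes$condition,
                  control_nets[[w]]$nodes$condition)
    if (!length(ch)) next
    status <- ifelse(ch %in% seen, "re-occurring", "new")
    seen <- union(seen, ch)
    rows[[w]] <- data.table::data.table(window = w, condition = ch,
                                        status = status)
  }
  out <- data.table::rbindlist(rows)
  if (!nrow(out)) {
    return(data.table::data.table(window = character(0), condition = character(0),
                                  status = character(0),
                                  in_control_disease_net = logical(0),
                                  validated = logical(0), mwu_overlap = logical(0)))
  }
  out[, in_control_disease_net :=
        condition %in% (disease_characteristic %||% character(0))]
  out[, validated := !in_control_disease_net]
  out[, mwu_overlap := condition %in% (mwu_significant %||% character(0))]
  out[]
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Conditions characteristic of the control-disease cohort in any window
#'
#' Convenience wrapper: runs [characteristic_conditions()] for the
#' control-disease cohort against its own matched controls and returns the
#' union of characteristic conditions across windows, used to validate the
#' dementia-derived sets.
#'
#' @param disease_nets,disease_control_nets Named lists of networks by
#'   window.
#' @return Character vector of conditions.
#' @export
control_disease_characteristic_set <- function(disease_nets,
                                               disease_control_nets) {
  cc <- characteristic_conditions(disease_nets, disease_control_nets)
  unique(cc$condition)
}

#' Learn a Bayesian network over binary condition indicators
#'
#' Score-based structure learning: greedy hill climbing over single-edge
#' additions, deletions, and reversals, maximizing the BIC score of binary
#' conditional probability tables, with a parent-count cap and seeded random
#' restarts (the best-scoring restart wins). This is a standard, documented
#' structure-learning variant over the windowed presence indicators.
#'
#' @param X Binary matrix (participants x conditions) or `presence_matrix`.
#' @param max_parents Parent cap per node (default 3).
#' @param seed Integer seed for restart shuffling.
#' @param restarts Number of random-order restarts (default 2).
#' @param prevalence_floor Columns below this prevalence are dropped.
#' @return List with `edges` (`from`, `to`, `score_delta` vs the final graph
#'   without that edge), `score` (total BIC), `nodes`.
#' @export
learn_bayesian_network <- function(X, max_parents = 3L, seed = 1L,
                                   restarts = 2L, prevalence_floor = 0.01) {
  if (inherits(X, "presence_matrix")) X <- presence_indicator(X)
  X <- (X > 0) + 0L
  X <- X[, colMeans(X) >= prevalence_floor, drop = FALSE]
  p <- ncol(X)
  if (p < 2L) stop("need at least 2 columns to learn a network", call. = FALSE)
  n <- nrow(X)
  vars <- colnames(X) %||% paste0("V", seq_len(p))
  colnames(X) <- vars
  set.seed(seed)

  cache <- new.env(parent = emptyenv())
  family_score <- function(j, parents) {
    key <- paste0(j, "|", paste(sort(parents), collapse = ","))
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    if (length(parents) == 0L) {
      k <- sum(X[, j]); ll <- 0
      for (cnt in c(k, n - k)) if (cnt > 0) ll <- ll + cnt * log(cnt / n)
      npar <- 1
    } else {
      cfg <- X[, parents, drop = FALSE] %*% (2^(seq_along(parents) - 1L))
      tab <- table(cfg, X[, j])
      rows <- rowSums(tab)
      ll <- sum(ifelse(tab > 0, tab * log(tab / rows[row(tab)]), 0))
      npar <- 2^length(parents)
    }
    val <- ll - (log(n) / 2) * npar
    cache[[key]] <- val
    val
  }

  run_once <- function() {
    parents <- stats::setNames(vector("list", p), vars)
    parents[] <- list(character(0))
    fs <- vapply(vars, function(j) family_score(j, character(0)), 0)
    repeat {
      best <- NULL; best_gain <- 1e-8
      ord <- sample.int(p)
      for (i in ord) for (j in sample.int(p)) {
        if (i == j) next
        from <- vars[i]; to <- vars[j]
        has <- from %in% parents[[to]]
        if (!has) {
          # add i -> j (check cycle and parent cap)
          if (length(parents[[to]]) >= max_parents) next
          if (.reachable(parents, from = to, to = from)) next
          gain <- family_score(to, c(parents[[to]], from)) - fs[to]
          if (gain > best_gain) {
            best <- list(op = "add", from = from, to = to); best_gain <- gain
          }
        } else {
          gain <- family_score(to, setdiff(parents[[to]], from)) - fs[to]
          if (gain > best_gain) {
            best <- list(op = "del", from = from, to = to); best_gain <- gain
          }
          # reverse i -> j
          if (length(parents[[from]]) < max_parents) {
            p2 <- parents
            p2[[to]] <- setdiff(p2[[to]], from)
            if (!.reachable(p2, from = from, to = to)) {
              gain <- (family_score(to, p2[[to]]) - fs[to]) +
                (family_score(from, c(parents[[from]], to)) - fs[from])
              if (gain > best_gain) {
                best <- list(op = "rev", from = from, to = to); best_gain <- gain
              }
            }
          }
        }
      }
      if (is.null(best)) break
      if (best$op == "add") {
        parents[[best$to]] <- c(parents[[best$to]], best$from)
      } else if (best$op == "del") {
        parents[[best$to]] <- setdiff(parents[[best$to]], best$from)
      } else {
        parents[[best$to]] <- setdiff(parents[[best$to]], best$from)
        parents[[best$from]] <- c(parents[[best$from]], best$to)
      }
      fs <- vapply(vars, function(j) family_score(j, parents[[j]]), 0)
    }
    list(parents = parents, score = sum(fs), fs = fs)
  }

  fits <- lapply(seq_len(max(1L, restarts)), function(r) run_once())
  fit <- fits[[which.max(vapply(fits, `[[`, 0, "score"))]]
  edges <- data.table::rbindlist(lapply(vars, function(j) {
    if (!length(fit$parents[[j]])) return(NULL)
    data.table::data.table(from = fit$parents[[j]], to = j)
  }))
  if (nrow(edges)) {
    edges[, score_delta := vapply(seq_len(.N), function(k) {
      fit$fs[to[k]] - family_score(to[k], setdiff(fit$parents[[to[k]]], from[k]))
    }, 0)]
  } else {
    edges <- data.table::data.table(from = character(0), to = character(0),
                                    score_delta = numeric(0))
  }
  list(edges = edges[], score = fit$score, nodes = vars)
}

# Is `to` reachable from `from` following parent -> child direction? Used for
# acyclicity checks: adding from -> to creates a cycle iff from is reachable
# from to (i.e. a directed path to -> ... -> from exists).
.reachable <- function(parents, from, to) {
  children <- function(v) names(parents)[vapply(parents, function(pp) v %in% pp, TRUE)]
  frontier <- from; visited <- character(0)
  while (length(frontier)) {
    v <- frontier[1L]; frontier <- frontier[-1L]
    if (v == to) return(TRUE)
    if (v %in% visited) next
    visited <- c(visited, v)
    frontier <- c(frontier, children(v))
  }
  FALSE
}

#' Export a network as an edge-list CSV and GraphML
#'
#' @param net A `comorbidity_network`.
#' @param path_csv,path_graphml Output paths (either may be `NULL`).
#' @return Invisibly, the edge table.
#' @export
export_network <- function(net, path_csv = NULL, path_graphml = NULL) {
  if (!is.null(path_csv)) data.table::fwrite(net$edges, path_csv)
  if (!is.null(path_graphml)) {
    nodes <- net$nodes$condition
    esc <- function(x) gsub("&", "&amp;", x, fixed = TRUE)
    lines <- c(
      '<?xml version="1.0" encoding="UTF-8"?>',
      '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
      '<key id="w" for="edge" attr.name="count" attr.type="double"/>',
      '<graph edgedefault="undirected">',
      sprintf('<node id="%s"/>', esc(nodes)),
      if (nrow(net$edges)) {
        sprintf('<edge source="%s" target="%s"><data key="w">%g</data></edge>',
                esc(net$edges$u), esc(net$edges$v), net$edges$count)
      },
      "</graph>", "</graphml>")
    writeLines(lines, path_graphml)
  }
  invisible(net$edges)
}
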