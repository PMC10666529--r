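#' Convert a temporal graph to its light representation
#'
#' The light graph stores the same information with one node per unique
#' formula (carrying the formula's full intensity series) and one edge per
#' ordered formula pair, aggregating all per-transition potential and
#' predicted transformation records as edge properties. The conversion is
#' lossless: [from_light()] reconstructs the original temporal graph.
#'
#' @param g A built `temporal_graph`.
#' @return A `light_graph` object: list with `nodes` (one row per formula),
#'   `series` (formula, snapshot, normalized_intensity), `edges` (ordered
#'   formula pairs), `records` (educt, product, transition, unit, predicted,
#'   weight), and the graph metadata needed for reconstruction.
#' @export
to_light <- function(g) {
  stopifnot(inherits(g, "temporal_graph"))
  series <- .sort_df(
    g$nodes[, c("formula", "snapshot", "normalized_intensity")],
    c("formula", "snapshot"))
  po <- g$potential
  has_pred <- !is.null(g$predicted)
  has_wt <- has_pred && "weight" %in% names(g$predicted)
  pkey <- if (has_pred)
    paste(g$predicted$educt, g$predicted$product,
          g$predicted$from_snapshot, g$predicted$unit) else character()
  rkey <- paste(po$educt, po$product, po$from_snapshot, po$unit)
  records <- data.frame(
    educt = po$educt, product = po$product,
    transition = po$from_snapshot, unit = po$unit,
    predicted = rkey %in% pkey,
    weight = NA_real_, stringsAsFactors = FALSE)
  if (has_wt && nrow(g$predicted))
    records$weight[match(pkey, rkey)] <- g$predicted$weight
  records <- .sort_df(records, c("educt", "product", "transition", "unit"))
  edges <- unique(records[, c("educt", "product")])
  edges <- .sort_df(edges, c("educt", "product"))
  structure(list(
    nodes = data.frame(formula = sort(unique(series$formula)),
                       stringsAsFactors = FALSE),
    series = series,
    edges = edges,
    records = records,
    units = g$units,
    elements = g$elements,
    n_snapshots = g$n_snapshots,
    omitted_fraction = g$omitted_fraction,
    margin = g$margin,
    policy = g$policy,
    has_predictions = has_pred,
    has_weights = has_wt,
    transition_meta = g$transition_meta
  ), class = "light_graph")
}

#' Reconstruct a temporal graph from its light representation
#'
#' Inverse of [to_light()]: nodes are expanded from the intensity series,
#' SAME_AS edges are recomputed from consecutive series entries, and
#' potential/predicted edges are unfolded from the aggregated records.
#'
#' @param lg A `light_graph`.
#' @return A `temporal_graph` structurally equal to the one `lg` was built
#'   from.
#' @export
from_light <- function(lg) {
  stopifnot(inherits(lg, "light_graph"))
  s <- lg$series
  skey <- paste(s$formula, s$snapshot)
  rec <- lg$records
  bad <- !(paste(rec$educt, rec$transition) %in% skey) |
    !(paste(rec$product, rec$transition + 1L) %in% skey)
  if (any(bad))
    stop("record references a snapshot absent from the endpoint series: ",
         paste(rec$educt[bad][1], "->", rec$product[bad][1], "at transition",
               rec$transition[bad][1]), call. = FALSE)
  parsed <- parse_formula(s$formula, lg$elements)
  nodes <- data.frame(formula = parsed$formula,
                      parsed[, lg$elements, drop = FALSE],
                      snapshot = as.integer(s$snapshot),
                      normalized_intensity = s$normalized_intensity,
                      stringsAsFactors = FALSE, check.names = FALSE)
  nodes <- .sort_df(nodes, c("snapshot", "formula"))
  potential <- data.frame(
    educt = rec$educt, product = rec$product,
    from_snapshot = as.integer(rec$transition),
    to_snapshot = as.integer(rec$transition + 1L),
    unit = rec$unit, stringsAsFactors = FALSE)
  potential <- .sort_df(potential,
                        c("from_snapshot", "educt", "product", "unit"))
  predicted <- NULL
  if (isTRUE(lg$has_predictions)) {
    pr <- rec[rec$predicted, , drop = FALSE]
    predicted <- data.frame(
      educt = pr$educt, product = pr$product,
      from_snapshot = as.integer(pr$transition),
      to_snapshot = as.integer(pr$transition + 1L),
      unit = pr$unit, stringsAsFactors = FALSE)
    if (isTRUE(lg$has_weights)) predicted$weight <- pr$weight
    predicted <- .sort_df(predicted,
                          c("from_snapshot", "educt", "product", "unit"))
  }
  structure(list(
    nodes = nodes,
    same_as = .same_as_from_nodes(nodes),
    potential = potential,
    predicted = predicted,
    units = lg$units,
    elements = lg$elements,
    n_snapshots = lg$n_snapshots,
    omitted_fraction = lg$omitted_fraction,
    margin = lg$margin,
    policy = lg$policy,
    transition_meta = lg$transition_meta
  ), class = "temporal_graph")
}

#' Clustering weights of a light graph
#'
#' The clustering weight of an (undirected) formula pair is the number of
#' predicted transformation records on that pair, summed over both
#' directions and all transitions — the count of predicted chemical
#' transformations between the two molecules. Pairs connected only by
#' potential (unpredicted) records get weight 0.
#'
#' @param lg A `light_graph`.
#' @param directed If `TRUE`, keep directions separate instead of summing.
#' @return data.frame with columns `a`, `b`, `weight` (for the undirected
#'   default, `a < b` lexicographically).
#' @export
clustering_weights <- function(lg, directed = FALSE) {
  stopifnot(inherits(lg, "light_graph"))
  rec <- lg$records
  if (directed) {
    a <- rec$educt; b <- rec$product
  } else {
    a <- pmin(rec$educt, rec$product)
    b <- pmax(rec$educt, rec$product)
  }
  key <- paste(a, b, sep = "\r")
  w <- tapply(as.numeric(rec$predicted), key, sum)
  parts <- strsplit(names(w), "\r", fixed = TRUE)
  out <- data.frame(a = vapply(parts, `[`, "", 1),
                    b = vapply(parts, `[`, "", 2),
                    weight = as.numeric(w), stringsAsFactors = FALSE)
  .sort_df(out, c("a", "b"))
}

#' Weighted label propagation clustering of the light graph
#'
#' Asynchronous weighted label propagation: every node starts with a unique
#' label; in each sweep the nodes are visited in a seed-shuffled order and
#' each adopts the label whose incident clustering-weight sum is largest,
#' ties broken by the smallest label. The algorithm stops when a full sweep
#' changes no label, or after `max_iter` sweeps (then the current assignment
#' is returned with a warning). Given the same seed (or explicit `order`)
#' the result is deterministic. Nodes whose incident edges all have weight 0
#' keep their own label and end as singletons unless `include_zero_weight`
#' is set.
#'
#' @param lg A `light_graph` (with predictions, normally).
#' @param max_iter Maximum number of sweeps (>= 1).
#' @param seed Integer seed for the per-sweep visiting order; the global RNG
#'   state is left untouched.
#' @param init Optional named integer vector of initial labels (names are
#'   formulas); used e.g. to verify that converged assignments are fixed
#'   points.
#' @param order Optional fixed visiting order (permutation of node indices
#'   in sorted-formula order) used for every sweep instead of shuffling.
#' @param include_zero_weight If `TRUE`, labels can also spread across
#'   zero-weight (potential-only) edges.
#' @return A `cluster_assignment`: list with `labels` (named integer vector
#'   over formulas), `iterations`, `converged`, `seed`.
#' @export
label_propagation <- function(lg, max_iter = 100L, seed = 1L, init = NULL,
                              order = NULL, include_zero_weight = FALSE) {
  stopifnot(inherits(lg, "light_graph"))
  if (!is.numeric(max_iter) || max_iter < 1)
    stop("`max_iter` must be >= 1", call. = FALSE)
  formulas <- lg$nodes$formula
  n <- length(formulas)
  idx <- stats::setNames(seq_len(n), formulas)
  w <- clustering_weights(lg)
  if (!include_zero_weight) w <- w[w$weight > 0, , drop = FALSE]
  nbr <- vector("list", n)
  nbw <- vector("list", n)
  if (nrow(w)) {
    ia <- idx[w$a]; ib <- idx[w$b]
    for (k in seq_len(nrow(w))) {
      nbr[[ia[k]]] <- c(nbr[[ia[k]]], ib[k])
      nbw[[ia[k]]] <- c(nbw[[ia[k]]], w$weight[k])
      nbr[[ib[k]]] <- c(nbr[[ib[k]]], ia[k])
      nbw[[ib[k]]] <- c(nbw[[ib[k]]], w$weight[k])
    }
  }
  labels <- if (is.null(init)) seq_len(n) else {
    if (!all(formulas %in% names(init)))
      stop("`init` must label every light-graph node", call. = FALSE)
    as.integer(init[formulas])
  }
  runif_perm <- local({
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    set.seed(as.integer(seed))
    state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, envir = globalenv())
    function(n) {
      old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
        get(".Random.seed", globalenv()) else NULL
      assign(".Random.seed", state, envir = globalenv())
      p <- sample.int(n)
      state <<- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
        assign(".Random.seed", old, envir = globalenv())
      p
    }
  })
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    ord <- if (is.null(order)) runif_perm(n) else as.integer(order)
    changed <- 0L
    for (i in ord) {
      if (!length(nbr[[i]])) next
      sums <- tapply(nbw[[i]], labels[nbr[[i]]], sum)
      cand <- as.integer(names(sums)[sums == max(sums)])
      new <- min(cand)
      if (new != labels[i]) {
        labels[i] <- new
        changed <- changed + 1L
      }
    }
    if (changed == 0L) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("label propagation did not converge within ", max_iter,
            " sweeps; returning current assignment")
  structure(list(labels = stats::setNames(labels, formulas),
                 iterations = iter, converged = converged,
                 seed = as.integer(seed)),
            class = "cluster_assignment")
}

#' @export
print.light_graph <- function(x, ...) {
  cat("Light temporal graph\n")
  cat(sprintf("  formulas: %d over %d snapshots\n", nrow(x$nodes),
              x$n_snapshots))
  cat(sprintf("  aggregated edges: %d carrying %d transformation records (%d predicted)\n",
              nrow(x$edges), nrow(x$records), sum(x$records$predicted)))
  invisible(x)
}

#' @export
print.cluster_assignment <- function(x, ...) {
  sizes <- sort(table(x$labels), decreasing = TRUE)
  cat(sprintf("Label propagation clustering: %d clusters over %d nodes (%s after %d sweep(s), seed %d)\n",
              length(sizes), length(x$labels),
              if (x$converged) "converged" else "not converged",
              x$iterations, x$seed))
  cat("  largest clusters:", paste(utils::head(as.integer(sizes), 5),
                                   collapse = ", "), "\n")
  invisible(x)
}
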