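.graph_margin <- function(g, margin) {
  if (!is.null(margin)) return(margin)
  if (!is.null(g$margin)) g$margin else 0.05
}

#' Per-transition metrics of the temporal graph
#'
#' Node counts at both ends of each transition, the SAME_AS edge count and
#' its partition into increasing/decreasing/consistent intensity trends,
#' potential and predicted edge counts, and the mean number of predicted
#' transformations per molecule (predicted edges divided by the node count
#' at the transition start).
#'
#' @param g A `temporal_graph`; predictions may or may not be present (a
#'   graph without predictions reports zero predicted edges, never errors).
#' @param margin Error margin for trend classification; defaults to the
#'   margin stored on the graph, else 0.05.
#' @return data.frame with one row per transition.
#' @export
transition_stats <- function(g, margin = NULL) {
  stopifnot(inherits(g, "temporal_graph"))
  margin <- .graph_margin(g, margin)
  nt <- n_transitions(g)
  cls <- classify_trend(g$same_as$intensity_trend, margin)
  pred <- g$predicted
  out <- data.frame(transition = seq_len(nt))
  cnt <- function(x, t) sum(x == t)
  out$nodes_from <- vapply(out$transition, cnt, 0L, x = g$nodes$snapshot)
  out$nodes_to <- vapply(out$transition + 1L, cnt, 0L, x = g$nodes$snapshot)
  out$same_as <- vapply(out$transition, cnt, 0L, x = g$same_as$from_snapshot)
  for (cl in c("increasing", "decreasing", "consistent"))
    out[[paste0("n_", cl)]] <- vapply(out$transition, function(t)
      sum(cls == cl & g$same_as$from_snapshot == t), 0L)
  out$potential <- vapply(out$transition, cnt, 0L,
                          x = g$potential$from_snapshot)
  out$predicted <- if (is.null(pred)) 0L else
    vapply(out$transition, cnt, 0L, x = pred$from_snapshot)
  out$mean_predicted_per_molecule <-
    ifelse(out$nodes_from > 0, out$predicted / out$nodes_from, NA_real_)
  out
}

#' Out-degree distribution of predicted transformation edges
#'
#' For each transition, the histogram of outgoing predicted-edge counts over
#' the nodes at the transition start (degree 0 included, so the histogram
#' entries sum to the node count at `t`).
#'
#' @param g A `temporal_graph` with predictions.
#' @return data.frame with columns `transition`, `out_degree`, `n_nodes`.
#' @export
out_degree_distribution <- function(g) {
  stopifnot(inherits(g, "temporal_graph"))
  if (is.null(g$predicted))
    stop("run predict_transformations() first", call. = FALSE)
  res <- list()
  for (t in seq_len(n_transitions(g))) {
    nodes_t <- g$nodes$formula[g$nodes$snapshot == t]
    deg <- table(factor(g$predicted$educt[g$predicted$from_snapshot == t],
                        levels = nodes_t))
    h <- table(as.integer(deg))
    if (!length(h)) next
    res[[t]] <- data.frame(transition = t,
                           out_degree = as.integer(names(h)),
                           n_nodes = as.integer(h))
  }
  out <- do.call(rbind, res)
  row.names(out) <- NULL
  out
}

#' Transformation-unit shares of predicted transformations
#'
#' Per transition, the share of each transformation unit among all predicted
#' edges of that transition (all units of the table tabulated, zero shares
#' included, so shares sum to 1 per transition with at least one predicted
#' edge). Per unit, the average share across those transitions, the grand
#' mean over units (1/K for a full K-unit tabulation), and the relative
#' change in share from the first to the last transition carrying predicted
#' edges (in percent; flagged undefined where the first-transition share is
#' zero).
#'
#' @param g A `temporal_graph` with predicted edges in at least one
#'   transition.
#' @return List with `per_transition` (transition, unit, group, n, share),
#'   `per_unit` (unit, group, mean_share, share_first, share_last,
#'   rel_change_pct, rel_change_defined), `grand_mean`, `first_transition`,
#'   `last_transition`.
#' @export
unit_shares <- function(g) {
  stopifnot(inherits(g, "temporal_graph"))
  pred <- g$predicted
  if (is.null(pred) || !nrow(pred))
    stop("no predicted edges: run predict_transformations() first",
         call. = FALSE)
  units <- g$units
  trans <- sort(unique(pred$from_snapshot))
  tab <- table(factor(pred$from_snapshot, levels = trans),
               factor(pred$unit, levels = units$name))
  shares <- sweep(tab, 1, rowSums(tab), "/")
  per_transition <- data.frame(
    transition = rep(trans, times = nrow(units)),
    unit = rep(units$name, each = length(trans)),
    group = rep(units$group, each = length(trans)),
    n = as.integer(tab),
    share = as.numeric(shares),
    stringsAsFactors = FALSE)
  per_transition <- .sort_df(per_transition, c("transition", "unit"))
  t0 <- trans[1]; t1 <- trans[length(trans)]
  s0 <- as.numeric(shares[as.character(t0), units$name])
  s1 <- as.numeric(shares[as.character(t1), units$name])
  per_unit <- data.frame(
    unit = units$name,
    group = units$group,
    mean_share = as.numeric(colMeans(shares)[units$name]),
    share_first = s0,
    share_last = s1,
    rel_change_pct = ifelse(s0 > 0, (s1 - s0) / s0 * 100, NA_real_),
    rel_change_defined = s0 > 0,
    stringsAsFactors = FALSE)
  list(per_transition = per_transition,
       per_unit = per_unit,
       grand_mean = mean(per_unit$mean_share),
       first_transition = t0,
       last_transition = t1)
}

#' Photo addition vs photo elimination share roll-up
#'
#' Aggregates the per-transition unit shares by transformation group.
#'
#' @param x Output of [unit_shares()] or a `temporal_graph` (then
#'   [unit_shares()] is called first).
#' @return data.frame with columns `transition`, `group`, `share`.
#' @export
unit_group_shares <- function(x) {
  if (inherits(x, "temporal_graph")) x <- unit_shares(x)
  pt <- x$per_transition
  agg <- stats::aggregate(share ~ transition + group, data = pt, FUN = sum)
  .sort_df(agg, c("transition", "group"))
}

#' Relative importance of transformation units from edge weights
#'
#' Importance of a unit in a transition is its summed predicted-edge weight
#' divided by the total predicted weight of the transition — the unit's
#' contribution to the overall intensity change. Transitions with zero total
#' weight report zero importances and are flagged.
#'
#' @param g A `temporal_graph` with weighted predictions
#'   (see [compute_edge_weights()]).
#' @return data.frame with columns `transition`, `unit`, `group`,
#'   `weight_sum`, `importance`, `defined`.
#' @export
unit_importance <- function(g) {
  stopifnot(inherits(g, "temporal_graph"))
  pred <- g$predicted
  if (is.null(pred) || !"weight" %in% names(pred))
    stop("run compute_edge_weights() first", call. = FALSE)
  units <- g$units
  trans <- sort(unique(pred$from_snapshot))
  res <- list()
  for (t in trans) {
    p <- pred[pred$from_snapshot == t, ]
    ws <- vapply(units$name, function(u) sum(p$weight[p$unit == u]), 0.0)
    tot <- sum(ws)
    res[[length(res) + 1L]] <- data.frame(
      transition = t, unit = units$name, group = units$group,
      weight_sum = as.numeric(ws),
      importance = if (tot > 0) as.numeric(ws) / tot else 0,
      defined = tot > 0, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  .sort_df(out, c("transition", "unit"))
}

#' Intensity-weighted mean molecular descriptors per snapshot
#'
#' For every snapshot, the mean of each molecular descriptor over the
#' detected formulas, weighted by normalized peak intensity.
#'
#' @param g A `temporal_graph`.
#' @param fields Descriptor columns to average.
#' @return data.frame with one row per snapshot.
#' @export
weighted_descriptors <- function(g, fields = c("mw", "hc_ratio", "oc_ratio",
                                               "dbe", "ai_mod", "nosc")) {
  stopifnot(inherits(g, "temporal_graph"))
  d <- descriptors(g$nodes[, g$elements, drop = FALSE])
  out <- data.frame(snapshot = seq_len(g$n_snapshots))
  out$n_nodes <- vapply(out$snapshot, function(t)
    sum(g$nodes$snapshot == t), 0L)
  if (any(out$n_nodes == 0))
    stop("empty snapshot: ", out$snapshot[out$n_nodes == 0][1], call. = FALSE)
  for (f in fields)
    out[[f]] <- vapply(out$snapshot, function(t) {
      i <- g$nodes$snapshot == t
      stats::weighted.mean(d[[f]][i], g$nodes$normalized_intensity[i])
    }, 0.0)
  out
}

#' Characterise label-propagation clusters
#'
#' Summarises each cluster of a light-graph clustering: size, element-class
#' composition, mean molecular descriptors of the member formulas,
#' within-cluster transformation-unit shares (over predicted records whose
#' educt and product both lie in the cluster; boundary records crossing
#' clusters are counted separately), and the mean intensity trend over the
#' member predicted edges (pooling the educt and product SAME_AS trends of
#' the internal edges).
#'
#' Clusters are renumbered 1, 2, ... by decreasing size.
#'
#' @param assignment A `cluster_assignment` from [label_propagation()].
#' @param g The `temporal_graph` the light graph came from.
#' @param lg The clustered `light_graph`.
#' @return A list with `clusters` (one row per cluster), `unit_shares`
#'   (cluster, unit, n, share over internal predicted records),
#'   `n_boundary_records` (predicted records crossing cluster boundaries)
#'   and `membership` (formula -> cluster id).
#' @export
cluster_report <- function(assignment, g, lg) {
  stopifnot(inherits(assignment, "cluster_assignment"),
            inherits(g, "temporal_graph"), inherits(lg, "light_graph"))
  labs <- assignment$labels
  unknown <- setdiff(names(labs), lg$nodes$formula)
  if (length(unknown))
    stop("assignment references unknown formula: ", unknown[1], call. = FALSE)
  if (!all(lg$nodes$formula %in% names(labs)))
    stop("assignment must cover every light-graph node", call. = FALSE)
  labs <- labs[lg$nodes$formula]
  sizes <- sort(table(labs), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes), names(sizes))
  member <- stats::setNames(as.integer(relabel[as.character(labs)]),
                            names(labs))
  d <- descriptors(lg$nodes$formula, lg$elements)
  classes <- c("CHO", "CHNO", "CHOS", "CHNOS", "other")
  rec <- lg$records[lg$records$predicted, , drop = FALSE]
  rec$cl_e <- member[rec$educt]
  rec$cl_p <- member[rec$product]
  internal <- rec[rec$cl_e == rec$cl_p, , drop = FALSE]
  trend <- stats::setNames(g$same_as$intensity_trend,
                           paste(g$same_as$formula, g$same_as$from_snapshot))
  clusters <- list()
  shares <- list()
  for (k in seq_along(sizes)) {
    in_k <- member == k
    f_k <- names(member)[in_k]
    comp <- table(factor(d$element_class[in_k], levels = classes))
    ri <- internal[internal$cl_e == k, , drop = FALSE]
    tr <- c(trend[paste(ri$educt, ri$transition)],
            trend[paste(ri$product, ri$transition)])
    tr <- tr[!is.na(tr)]
    row <- data.frame(cluster = k, size = sum(in_k),
                      mean_hc = mean(d$hc_ratio[in_k]),
                      mean_oc = mean(d$oc_ratio[in_k]),
                      mean_mw = mean(d$mw[in_k]),
                      mean_ai_mod = mean(d$ai_mod[in_k]),
                      mean_nosc = mean(d$nosc[in_k]),
                      n_internal_records = nrow(ri),
                      mean_intensity_trend =
                        if (length(tr)) mean(tr) else NA_real_)
    for (cl in classes) row[[paste0("n_", cl)]] <- as.integer(comp[[cl]])
    clusters[[k]] <- row
    if (nrow(ri)) {
      utab <- table(factor(ri$unit, levels = g$units$name))
      shares[[length(shares) + 1L]] <- data.frame(
        cluster = k, unit = g$units$name,
        n = as.integer(utab),
        share = as.numeric(utab) / nrow(ri),
        stringsAsFactors = FALSE)
    }
  }
  list(clusters = do.call(rbind, clusters),
       unit_shares = if (length(shares)) do.call(rbind, shares) else
         data.frame(cluster = integer(), unit = character(), n = integer(),
                    share = numeric(), stringsAsFactors = FALSE),
       n_boundary_records = nrow(rec) - nrow(internal),
       membership = member)
}
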