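.sort_df <- function(df, cols) {
  if (nrow(df)) df <- df[do.call(order, df[cols]), , drop = FALSE]
  row.names(df) <- NULL
  df
}

.empty_same_as <- function() data.frame(
  formula = character(), from_snapshot = integer(), to_snapshot = integer(),
  intensity_trend = numeric(), stringsAsFactors = FALSE)

.empty_edges <- function() data.frame(
  educt = character(), product = character(), from_snapshot = integer(),
  to_snapshot = integer(), unit = character(), stringsAsFactors = FALSE)

# Normalize a peak table (from read_peak_tables(), simulate_snapshots(), or a
# hand-built data.frame) into the internal node table: canonical formula,
# element counts, snapshot, normalized_intensity. Zero-intensity rows mean
# "not detected" and are dropped; negative intensities are a hard error.
.normalize_peaks <- function(peaks, elements) {
  fcol <- intersect(c("molecular_formula", "formula"), names(peaks))[1]
  if (is.na(fcol))
    stop("peak table needs a 'molecular_formula' (or 'formula') column",
         call. = FALSE)
  for (col in c("snapshot", "normalized_intensity"))
    if (!col %in% names(peaks))
      stop("peak table needs a '", col, "' column", call. = FALSE)
  snap <- peaks$snapshot
  if (any(is.na(snap)) || any(snap != round(snap)))
    stop("snapshot indices must be integers", call. = FALSE)
  inten <- peaks$normalized_intensity
  if (any(is.na(inten)) || any(inten < 0))
    stop("normalized_intensity must be nonnegative and non-missing",
         call. = FALSE)
  keep <- inten > 0
  parsed <- parse_formula(as.character(peaks[[fcol]][keep]), elements)
  nodes <- data.frame(formula = parsed$formula,
                      parsed[, elements, drop = FALSE],
                      snapshot = as.integer(snap[keep]),
                      normalized_intensity = as.numeric(inten[keep]),
                      stringsAsFactors = FALSE, check.names = FALSE)
  key <- paste(nodes$formula, nodes$snapshot)
  if (anyDuplicated(key))
    stop("duplicate (formula, snapshot) rows: ", key[duplicated(key)][1],
         call. = FALSE)
  .sort_df(nodes, c("snapshot", "formula"))
}

#' SAME_AS edges: intensity trends of formulas across consecutive snapshots
#'
#' Connects every formula detected (intensity > 0) at both snapshot `t` and
#' `t + 1` and records the intensity trend, the ratio of the later to the
#' earlier normalized intensity. A formula present in only one of the two
#' snapshots yields no edge on that transition.
#'
#' @param peaks Peak table (columns `molecular_formula`/`formula`,
#'   `snapshot`, `normalized_intensity`).
#' @param elements Element set.
#' @return data.frame with columns `formula`, `from_snapshot`, `to_snapshot`,
#'   `intensity_trend`.
#' @export
compute_same_as <- function(peaks, elements = default_elements()) {
  nodes <- if (is.data.frame(peaks) && all(c("formula", "snapshot",
                                             "normalized_intensity") %in%
                                           names(peaks)) &&
               !"molecular_formula" %in% names(peaks))
    peaks else .normalize_peaks(peaks, elements)
  .same_as_from_nodes(nodes)
}

.same_as_from_nodes <- function(nodes) {
  a <- nodes[, c("formula", "snapshot", "normalized_intensity")]
  b <- a
  b$snapshot <- b$snapshot - 1L
  m <- merge(a, b, by = c("formula", "snapshot"),
             suffixes = c("_from", "_to"))
  out <- data.frame(formula = m$formula,
                    from_snapshot = as.integer(m$snapshot),
                    to_snapshot = as.integer(m$snapshot + 1L),
                    intensity_trend = m$normalized_intensity_to /
                      m$normalized_intensity_from,
                    stringsAsFactors = FALSE)
  if (!nrow(out)) return(.empty_same_as())
  .sort_df(out, c("from_snapshot", "formula"))
}

#' POTENTIAL_TRANSFORMATION edges between consecutive snapshots
#'
#' For every transition `t -> t + 1`, every formula present at `t`, and every
#' transformation unit, an edge is drawn to the formula obtained by adding
#' the unit's delta, if and only if that formula is present at `t + 1`.
#' Matching is by exact canonical formula identity. Several units linking the
#' same node pair give several parallel edges. Edges never connect nodes
#' within one snapshot or nodes more than one snapshot apart.
#'
#' @inheritParams compute_same_as
#' @param units Transformation-unit table.
#' @return data.frame with columns `educt`, `product`, `from_snapshot`,
#'   `to_snapshot`, `unit`.
#' @export
compute_potential <- function(peaks, units = default_units(),
                              elements = default_elements()) {
  nodes <- if (is.data.frame(peaks) && all(elements %in% names(peaks)) &&
               "formula" %in% names(peaks))
    peaks else .normalize_peaks(peaks, elements)
  .potential_from_nodes(nodes, units, elements)
}

.potential_from_nodes <- function(nodes, units, elements) {
  n <- if (nrow(nodes)) max(nodes$snapshot) else 0L
  cm <- as.matrix(nodes[, elements, drop = FALSE])
  res <- list()
  for (t in seq_len(max(n - 1L, 0L))) {
    ei <- which(nodes$snapshot == t)
    to_formulas <- nodes$formula[nodes$snapshot == t + 1L]
    if (!length(ei) || !length(to_formulas)) next
    E <- cm[ei, , drop = FALSE]
    for (j in seq_len(nrow(units))) {
      d <- .unit_delta(units[j, , drop = FALSE], elements)
      if (is.null(d)) next
      P <- sweep(E, 2, d, "+")
      ok <- rowSums(P < 0L) == 0L & P[, "C"] >= 1L
      if (!any(ok)) next
      prod_f <- formula_string(P[ok, , drop = FALSE])
      hit <- prod_f %in% to_formulas
      if (!any(hit)) next
      res[[length(res) + 1L]] <- data.frame(
        educt = nodes$formula[ei][ok][hit],
        product = prod_f[hit],
        from_snapshot = t,
        to_snapshot = t + 1L,
        unit = units$name[j],
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(res)) do.call(rbind, res) else .empty_edges()
  out$from_snapshot <- as.integer(out$from_snapshot)
  out$to_snapshot <- as.integer(out$to_snapshot)
  .sort_df(out, c("from_snapshot", "educt", "product", "unit"))
}

#' Build the snapshot-based temporal graph
#'
#' Assembles Molecule nodes from the peak tables, computes SAME_AS and
#' POTENTIAL_TRANSFORMATION edges, and then prunes isolated molecules: a
#' formula that takes part in no potential transformation in any transition
#' is removed with its whole intensity series, and the omitted node fraction
#' is recorded. Molecules that do take part keep all their snapshots (so the
#' SAME_AS trends needed by the prediction step remain available even on
#' snapshots where the molecule itself has no transformation edge). Pruning
#' happens once, after potential-edge computation and before any prediction.
#'
#' @inheritParams compute_potential
#' @param transition_meta Optional data.frame of per-transition metadata
#'   (e.g. cumulative irradiation dose), with a `transition` column. Carried
#'   along for reporting only; never used by the algorithms.
#' @return A `temporal_graph` object: a list with elements `nodes`,
#'   `same_as`, `potential`, `predicted` (NULL until
#'   [predict_transformations()] is run), `units`, `elements`,
#'   `n_snapshots`, `omitted_fraction`, `margin`, `policy`,
#'   `transition_meta`.
#' @examples
#' peaks <- data.frame(
#'   molecular_formula = c("C10H12O5", "C9H12O3", "C10H12O5", "C9H12O3"),
#'   snapshot = c(1, 1, 2, 2),
#'   normalized_intensity = c(0.5, 0.1, 0.4, 0.18))
#' g <- build_graph(peaks)
#' g
#' @export
build_graph <- function(peaks, units = default_units(),
                        elements = default_elements(),
                        transition_meta = NULL) {
  elements <- .check_elements(elements)
  nodes <- .normalize_peaks(peaks, elements)
  snaps <- sort(unique(nodes$snapshot))
  if (length(snaps) < 2)
    stop("at least two snapshots are required", call. = FALSE)
  n <- max(snaps)
  if (!identical(snaps, seq_len(n)))
    stop("snapshot indices must be consecutive integers starting at 1",
         call. = FALSE)
  potential <- .potential_from_nodes(nodes, units, elements)
  # Prune at the molecule (formula) level: a molecule taking part in no
  # potential transformation anywhere is omitted with its whole series;
  # molecules that do take part keep all their snapshots, so the intensity
  # trends the prediction step needs remain available.
  keep_formula <- unique(c(potential$educt, potential$product))
  keep <- nodes$formula %in% keep_formula
  omitted <- 1 - sum(keep) / length(keep)
  nodes <- nodes[keep, , drop = FALSE]
  row.names(nodes) <- NULL
  same_as <- .same_as_from_nodes(nodes)
  structure(list(
    nodes = nodes,
    same_as = same_as,
    potential = potential,
    predicted = NULL,
    units = units,
    elements = elements,
    n_snapshots = as.integer(n),
    omitted_fraction = omitted,
    margin = NULL,
    policy = NULL,
    transition_meta = transition_meta
  ), class = "temporal_graph")
}

#' Number of transitions of a temporal graph
#'
#' `n` snapshots always yield exactly `n - 1` transitions.
#'
#' @param g A `temporal_graph` or `light_graph`.
#' @return Integer.
#' @export
n_transitions <- function(g) as.integer(g$n_snapshots - 1L)

#' @export
print.temporal_graph <- function(x, ...) {
  cat("Temporal molecular graph\n")
  cat(sprintf("  snapshots: %d (%d transitions)\n", x$n_snapshots,
              n_transitions(x)))
  cat(sprintf("  nodes: %d (%.2f%% omitted as isolated)\n", nrow(x$nodes),
              100 * x$omitted_fraction))
  cat(sprintf("  SAME_AS edges: %d\n", nrow(x$same_as)))
  cat(sprintf("  potential transformation edges: %d\n", nrow(x$potential)))
  if (!is.null(x$predicted))
    cat(sprintf("  predicted transformation edges: %d (margin %.3g, policy %s%s)\n",
                nrow(x$predicted), x$margin, x$policy,
                if ("weight" %in% names(x$predicted)) ", weighted" else ""))
  invisible(x)
}
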