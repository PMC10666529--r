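# Fixture generators and independent brute-force oracles used across the
# suite. The oracles deliberately avoid the package's shift-and-join edge
# computation: they enumerate all node pairs and all units.

# Random snapshot peak tables over a pool of base formulas plus unit-derived
# products, with random per-snapshot presence and intensity. One persistent
# formula guarantees every snapshot is populated.
rand_peaks <- function(seed, n_base = 10, n_snapshots = 4,
                       units = default_units(), p_present = 0.8) {
  set.seed(seed)
  C <- sample(8:22, n_base, replace = TRUE)
  H <- pmax(2L, round(C * runif(n_base, 0.8, 1.8)))
  O <- sample(2:10, n_base, replace = TRUE)
  N <- rbinom(n_base, 2, 0.2)
  S <- rbinom(n_base, 1, 0.15)
  base <- unique(formula_string(cbind(C = C, H = H, N = as.integer(N),
                                      O = O, S = as.integer(S))))
  prods <- unlist(lapply(sample(nrow(units), 6), function(j)
    apply_unit(sample(base, min(4, length(base))), units[j, , drop = FALSE])))
  pool <- unique(c(base, prods[!is.na(prods)]))
  rows <- list()
  for (f in pool) {
    pres <- runif(n_snapshots) < p_present
    if (f == pool[1]) pres[] <- TRUE
    for (t in which(pres))
      rows[[length(rows) + 1L]] <- data.frame(
        molecular_formula = f, snapshot = t,
        normalized_intensity = round(runif(1, 0.05, 1), 4),
        stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# Random built graph, optionally with predictions and weights.
rand_graph <- function(seed, stage = c("weights", "predict", "build"),
                       policy = "strict", margin = 0.05, ...) {
  stage <- match.arg(stage)
  g <- build_graph(rand_peaks(seed, ...))
  if (stage %in% c("predict", "weights"))
    g <- predict_transformations(g, margin = margin, policy = policy)
  if (stage == "weights") g <- compute_edge_weights(g)
  g
}

# Brute-force potential edges: all (node at t) x (node at t+1) pairs x all
# units, matched by exact element-count difference.
brute_potential <- function(peaks, units = default_units(),
                            elements = default_elements()) {
  fcol <- intersect(c("molecular_formula", "formula"), names(peaks))[1]
  peaks <- peaks[peaks$normalized_intensity > 0, ]
  formulas <- unique(as.character(peaks[[fcol]]))
  parsed <- parse_formula(formulas, elements)
  cm <- as.matrix(parsed[, elements])
  rownames(cm) <- parsed$formula
  canon <- setNames(parsed$formula, formulas)
  dkey <- vapply(seq_len(nrow(units)), function(j) {
    d <- integer(length(elements))
    names(d) <- elements
    for (e in elements) {
      col <- paste0("d", e)
      if (col %in% names(units)) d[e] <- units[[col]][j]
    }
    extra <- setdiff(c("dC", "dH", "dN", "dO", "dS", "dP"),
                     paste0("d", elements))
    if (any(unlist(units[j, intersect(extra, names(units))]) != 0))
      return(NA_character_)
    paste(d, collapse = ",")
  }, "")
  res <- list()
  n <- max(peaks$snapshot)
  for (t in seq_len(n - 1)) {
    at_t <- canon[as.character(peaks[[fcol]][peaks$snapshot == t])]
    at_t1 <- canon[as.character(peaks[[fcol]][peaks$snapshot == t + 1])]
    for (a in at_t) for (b in at_t1) {
      if (a == b) next
      key <- paste(cm[b, ] - cm[a, ], collapse = ",")
      hits <- which(!is.na(dkey) & dkey == key)
      for (j in hits)
        res[[length(res) + 1L]] <- data.frame(
          educt = a, product = b, from_snapshot = t,
          to_snapshot = t + 1L, unit = units$name[j],
          stringsAsFactors = FALSE)
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(educt = character(), product = character(),
               from_snapshot = integer(), to_snapshot = integer(),
               unit = character(), stringsAsFactors = FALSE)
  out[do.call(order, out[c("from_snapshot", "educt", "product", "unit")]), ,
      drop = FALSE]
}

# Brute-force TPA: filter every potential edge by the two trend conditions,
# evaluated directly from the node intensities.
brute_predict <- function(g, margin = 0.05, policy = "strict") {
  I <- setNames(g$nodes$normalized_intensity,
                paste(g$nodes$formula, g$nodes$snapshot))
  po <- g$potential
  keep <- logical(nrow(po))
  for (i in seq_len(nrow(po))) {
    t <- po$from_snapshot[i]
    iA0 <- I[paste(po$educt[i], t)]
    iA1 <- I[paste(po$educt[i], t + 1)]
    iB0 <- I[paste(po$product[i], t)]
    iB1 <- I[paste(po$product[i], t + 1)]
    edec <- if (!is.na(iA1)) (iA1 / iA0) < 1 - margin else
      policy == "zero_fill"
    pinc <- if (!is.na(iB0)) (iB1 / iB0) > 1 + margin else
      policy == "zero_fill"
    keep[i] <- edec && pinc
  }
  po[keep, , drop = FALSE]
}

edge_keys <- function(df) {
  if (is.null(df) || !nrow(df)) return(character())
  sort(paste(df$educt, df$product, df$from_snapshot, df$unit))
}

# Synthetic light graph holding only what clustering needs; `pairs` is a
# data.frame (a, b, n_predicted).
lpa_fixture <- function(pairs, extra_nodes = character()) {
  rec <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    k <- pairs$n_predicted[i]
    data.frame(educt = pairs$a[i], product = pairs$b[i],
               transition = seq_len(max(k, 1)),
               unit = "-CO2", predicted = seq_len(max(k, 1)) <= k,
               weight = NA_real_, stringsAsFactors = FALSE)
  }))
  nodes <- sort(unique(c(pairs$a, pairs$b, extra_nodes)))
  structure(list(
    nodes = data.frame(formula = nodes, stringsAsFactors = FALSE),
    series = data.frame(formula = nodes, snapshot = 1L,
                        normalized_intensity = 1, stringsAsFactors = FALSE),
    edges = unique(rec[, c("educt", "product")]),
    records = rec, units = default_units(),
    elements = default_elements(), n_snapshots = 2L,
    omitted_fraction = 0, margin = NULL, policy = NULL,
    has_predictions = TRUE, has_weights = FALSE, transition_meta = NULL),
    class = "light_graph")
}

# Two weighted triangles joined by one weak bridge edge.
two_triangles <- function(w_in = 5, w_bridge = 1) {
  tri <- function(v) data.frame(a = v[c(1, 1, 2)], b = v[c(2, 3, 3)],
                                n_predicted = w_in,
                                stringsAsFactors = FALSE)
  pairs <- rbind(tri(c("C10H8O4", "C11H10O6", "C12H12O8")),
                 tri(c("C20H18O4", "C21H20O6", "C22H22O8")),
                 data.frame(a = "C12H12O8", b = "C20H18O4",
                            n_predicted = w_bridge, stringsAsFactors = FALSE))
  lpa_fixture(pairs)
}

# The worked two-product example: one educt feeding two products.
two_product_toy <- function() {
  data.frame(
    molecular_formula = c("C10H12O5", "C9H12O3", "C10H10O4",
                          "C10H12O5", "C9H12O3", "C10H10O4"),
    snapshot = c(1, 1, 1, 2, 2, 2),
    normalized_intensity = c(1.0, 0.10, 0.10, 0.90, 0.18, 0.14),
    stringsAsFactors = FALSE)
}
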