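test_that("light conversion aggregates transitions onto one edge per formula pair", {
  peaks <- do.call(rbind, lapply(1:5, function(t) data.frame(
    molecular_formula = c("C10H12O5", "C9H12O3"), snapshot = t,
    normalized_intensity = c(0.5 * 0.8^t, 0.1 * 1.2^t))))
  g <- compute_edge_weights(predict_transformations(build_graph(peaks)))
  lg <- to_light(g)
  expect_equal(nrow(lg$nodes), 2L)
  expect_equal(nrow(lg$edges), 1L)          # one aggregated edge A -> B
  expect_equal(nrow(lg$records), 4L)        # one record per transition
  expect_equal(sort(unique(lg$records$transition)), 1:4)
  expect_equal(sum(lg$series$formula == "C10H12O5"), 5L)
})

test_that("light and temporal representations convert without information loss", {
  for (seed in c(3, 12, 19)) for (stage in c("build", "predict", "weights")) {
    g <- rand_graph(seed, stage = stage,
                    policy = if (seed == 12) "zero_fill" else "strict")
    g2 <- from_light(to_light(g))
    expect_equal(g2$nodes, g$nodes)
    expect_equal(g2$same_as, g$same_as)
    expect_equal(g2$potential, g$potential)
    expect_equal(g2$predicted, g$predicted)
    expect_equal(g2$n_snapshots, g$n_snapshots)
    expect_equal(g2$omitted_fraction, g$omitted_fraction)
    expect_equal(g2$margin, g$margin)
    expect_equal(g2$policy, g$policy)
    # and the light graph survives its own round trip
    expect_equal(to_light(g2), to_light(g))
  }
})

test_that("light records referencing missing snapshots are a consistency error", {
  lg <- to_light(rand_graph(5, stage = "predict"))
  lg$records$transition[1] <- 99L
  expect_error(from_light(lg), "absent from the endpoint series")
})

test_that("clustering weight is the predicted-record count summed over both directions", {
  lg <- to_light(rand_graph(7, stage = "predict"))
  w <- clustering_weights(lg)
  rec <- lg$records
  for (i in seq_len(nrow(w))) {
    n_ab <- sum(rec$predicted & rec$educt == w$a[i] & rec$product == w$b[i])
    n_ba <- sum(rec$predicted & rec$educt == w$b[i] & rec$product == w$a[i])
    expect_equal(w$weight[i], n_ab + n_ba)
  }
  # potential-only pairs carry weight zero
  expect_true(all(w$weight[!paste(w$a, w$b) %in%
    paste(pmin(rec$educt[rec$predicted], rec$product[rec$predicted]),
          pmax(rec$educt[rec$predicted], rec$product[rec$predicted]))] == 0))
})

test_that("label propagation splits two weighted triangles under every visiting order", {
  lg <- two_triangles()
  n <- nrow(lg$nodes)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  tri1 <- c("C10H8O4", "C11H10O6", "C12H12O8")
  for (ord in perms(seq_len(n))) {
    a <- label_propagation(lg, order = ord)
    labs <- a$labels
    expect_equal(length(unique(labs)), 2L)
    expect_equal(length(unique(labs[tri1])), 1L)
    expect_equal(length(unique(labs[setdiff(names(labs), tri1)])), 1L)
    expect_false(labs[[tri1[1]]] == labs[["C20H18O4"]])
  }
})

test_that("label propagation is deterministic given the seed and converges to a fixed point", {
  lg <- to_light(predict_transformations(build_graph(rand_peaks(23))))
  a1 <- label_propagation(lg, seed = 42)
  a2 <- label_propagation(lg, seed = 42)
  expect_identical(a1$labels, a2$labels)
  expect_true(a1$converged)
  # a converged assignment is a fixed point under any further visiting order
  for (seed in c(1, 99)) {
    a3 <- label_propagation(lg, seed = seed, init = a1$labels)
    expect_identical(a3$labels, a1$labels)
    expect_equal(a3$iterations, 1L)
  }
  # the global RNG stream is untouched
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(label_propagation(lg, seed = 7)); after <- runif(1)
  expect_identical(before, after)
})

test_that("nodes without predicted records end as singletons", {
  lg <- lpa_fixture(data.frame(a = c("C10H8O4", "C10H8O4"),
                               b = c("C11H10O6", "C12H12O8"),
                               n_predicted = c(3, 0)),
                    extra_nodes = "C30H40O10")
  a <- label_propagation(lg)
  labs <- a$labels
  expect_equal(labs[["C10H8O4"]], labs[["C11H10O6"]])
  expect_equal(unname(table(labs)[as.character(labs[["C12H12O8"]])]), 1L,
               ignore_attr = TRUE)
  expect_equal(unname(table(labs)[as.character(labs[["C30H40O10"]])]), 1L,
               ignore_attr = TRUE)
  # ... unless zero-weight adoption is switched on
  az <- label_propagation(lg, include_zero_weight = TRUE)
  expect_equal(az$labels[["C12H12O8"]], az$labels[["C10H8O4"]])
})

test_that("an independent label-propagation implementation agrees on the triangle fixture", {
  lg <- two_triangles()
  w <- clustering_weights(lg)
  w <- w[w$weight > 0, ]
  ig <- igraph::graph_from_data_frame(w[, c("a", "b")], directed = FALSE,
                                      vertices = lg$nodes$formula)
  set.seed(5)
  cm <- igraph::cluster_label_prop(ig, weights = w$weight)
  ours <- label_propagation(lg, seed = 5)$labels[lg$nodes$formula]
  theirs <- igraph::membership(cm)[lg$nodes$formula]
  # same partition, labels up to renaming
  expect_equal(length(unique(theirs)), 2L)
  expect_equal(outer(ours, ours, "=="), outer(theirs, theirs, "=="),
               ignore_attr = TRUE)
})
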