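test_that("trend classification applies the error margin with strict inequalities", {
  expect_equal(classify_trend(c(0.80, 1.03, 1.05, 0.95, 1.2), 0.05),
               c("decreasing", "consistent", "consistent", "consistent",
                 "increasing"))
  expect_equal(classify_trend(0.9499, 0.05), "decreasing")
  expect_equal(classify_trend(1.0501, 0.05), "increasing")
  expect_error(classify_trend(0, 0.05), "positive")
  expect_error(classify_trend(-0.5, 0.05), "positive")
  expect_error(classify_trend(1, 1), "margin")
  expect_error(classify_trend(1, -0.1), "margin")
})

test_that("the TPA predicts the worked single-edge example with weight 0.09", {
  peaks <- data.frame(
    molecular_formula = rep(c("C10H12O5", "C9H12O3"), 2),
    snapshot = c(1, 1, 2, 2),
    normalized_intensity = c(0.50, 0.10, 0.40, 0.18))
  g <- compute_edge_weights(predict_transformations(build_graph(peaks)))
  expect_equal(nrow(g$predicted), 1L)
  expect_equal(g$predicted$educt, "C10H12O5")
  expect_equal(g$predicted$product, "C9H12O3")
  expect_equal(g$predicted$unit, "-CO2")
  expect_equal(g$predicted$weight, 0.09)

  # product inside the margin: no prediction
  peaks$normalized_intensity[4] <- 0.102
  g2 <- predict_transformations(build_graph(peaks))
  expect_equal(nrow(g2$predicted), 0L)

  # educt increasing: candidate removed
  peaks$normalized_intensity <- c(0.50, 0.10, 0.60, 0.18)
  g3 <- predict_transformations(build_graph(peaks))
  expect_equal(nrow(g3$predicted), 0L)
})

test_that("one educt feeding two products apportions its loss equally", {
  g <- compute_edge_weights(predict_transformations(
    build_graph(two_product_toy())))
  pr <- g$predicted
  expect_equal(nrow(pr), 2L)
  expect_equal(pr$weight[pr$product == "C9H12O3"], 0.065)   # gain 0.08
  expect_equal(pr$weight[pr$product == "C10H10O4"], 0.045)  # gain 0.04
})

test_that("missing-node policies differ exactly on appearing/disappearing formulas", {
  # educt disappears after t = 1; product appears at t = 2
  peaks <- data.frame(
    molecular_formula = c("C10H12O5", "C7H8O2", "C9H12O3", "C7H8O2"),
    snapshot = c(1, 1, 2, 2),
    normalized_intensity = c(0.50, 0.10, 0.18, 0.10))
  gs <- predict_transformations(build_graph(peaks), policy = "strict")
  expect_equal(nrow(gs$predicted), 0L)
  gz <- predict_transformations(build_graph(peaks), policy = "zero_fill")
  expect_equal(nrow(gz$predicted), 1L)
  expect_equal(gz$predicted$educt, "C10H12O5")
  expect_equal(gz$predicted$product, "C9H12O3")
  gz <- compute_edge_weights(gz)
  # full loss (0.50) and full gain (0.18), degrees 1
  expect_equal(gz$predicted$weight, 0.5 * (0.50 + 0.18))
  expect_error(predict_transformations(build_graph(peaks), policy = "both"))
})

test_that("prediction matches the brute-force trend filter on random graphs", {
  for (seed in c(4, 8, 15)) for (policy in c("strict", "zero_fill")) {
    g <- rand_graph(seed, stage = "build")
    got <- predict_transformations(g, 0.05, policy)$predicted
    want <- brute_predict(g, 0.05, policy)
    expect_equal(edge_keys(got), edge_keys(want))
  }
})

test_that("predictions are a subset of potential edges and grow as the margin shrinks", {
  g <- rand_graph(21, stage = "build")
  for (policy in c("strict", "zero_fill")) {
    prev <- NULL
    for (m in c(0.5, 0.2, 0.05, 0)) {
      keys <- edge_keys(predict_transformations(g, m, policy)$predicted)
      expect_true(all(keys %in% edge_keys(g$potential)))
      if (!is.null(prev)) expect_true(all(prev %in% keys))
      prev <- keys
    }
  }
})

test_that("per-transition weights conserve half of total loss plus gain", {
  for (seed in c(6, 17)) for (policy in c("strict", "zero_fill")) {
    g <- compute_edge_weights(predict_transformations(
      rand_graph(seed, stage = "build"), policy = policy))
    pr <- g$predicted
    if (!nrow(pr)) next
    I <- setNames(g$nodes$normalized_intensity,
                  paste(g$nodes$formula, g$nodes$snapshot))
    for (t in unique(pr$from_snapshot)) {
      p <- pr[pr$from_snapshot == t, ]
      educts <- unique(p$educt)
      prods <- unique(p$product)
      loss <- sum(vapply(educts, function(f) {
        i1 <- I[paste(f, t + 1)]
        I[paste(f, t)] - ifelse(is.na(i1), 0, i1)
      }, 0.0))
      gain <- sum(vapply(prods, function(f) {
        i0 <- I[paste(f, t)]
        I[paste(f, t + 1)] - ifelse(is.na(i0), 0, i0)
      }, 0.0))
      expect_equal(sum(p$weight), 0.5 * (loss + gain), tolerance = 1e-12)
    }
  }
})

test_that("prediction is invariant under input row order", {
  peaks <- rand_peaks(31)
  g1 <- predict_transformations(build_graph(peaks))
  set.seed(1)
  g2 <- predict_transformations(build_graph(peaks[sample(nrow(peaks)), ]))
  expect_equal(g1$predicted, g2$predicted)
})
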