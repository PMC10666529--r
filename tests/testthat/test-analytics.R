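toy_graph <- function() {
  compute_edge_weights(predict_transformations(build_graph(
    two_product_toy())))
}

test_that("transition statistics match hand counts on the worked toy", {
  st <- transition_stats(toy_graph())
  expect_equal(nrow(st), 1L)
  expect_equal(st$nodes_from, 3L)
  expect_equal(st$nodes_to, 3L)
  expect_equal(st$same_as, 3L)
  expect_equal(st$n_decreasing, 1L)   # the educt
  expect_equal(st$n_increasing, 2L)   # both products
  expect_equal(st$n_consistent, 0L)
  # A -CO2-> B, A -H2O-> C, and the hydration C +H2O-> A
  expect_equal(st$potential, 3L)
  expect_equal(st$predicted, 2L)
  expect_equal(st$mean_predicted_per_molecule, 2 / 3)
})

test_that("a graph without predictions reports zero predicted edges, never errors", {
  g <- build_graph(two_product_toy())
  st <- transition_stats(g)
  expect_equal(st$predicted, 0L)
  expect_equal(st$potential, 3L)
})

test_that("out-degree histogram entries sum to the node count at the transition start", {
  g <- rand_graph(9, stage = "predict")
  od <- out_degree_distribution(g)
  st <- transition_stats(g)
  for (t in unique(od$transition)) {
    expect_equal(sum(od$n_nodes[od$transition == t]),
                 st$nodes_from[st$transition == t])
    expect_equal(sum((od$out_degree * od$n_nodes)[od$transition == t]),
                 st$predicted[st$transition == t])
  }
})

test_that("unit shares are a normalized tabulation with grand mean 1/K", {
  sh <- unit_shares(toy_graph())
  pt <- sh$per_transition
  expect_equal(nrow(pt), 22L)              # all units tabulated, zeros kept
  expect_equal(sum(pt$share), 1)
  expect_equal(pt$share[pt$unit == "-CO2"], 0.5)
  expect_equal(pt$share[pt$unit == "-H2O"], 0.5)
  expect_equal(sh$grand_mean, 1 / 22)
  expect_error(unit_shares(build_graph(two_product_toy())), "predicted")
})

test_that("share trends flag units absent from the first transition as undefined", {
  # -CO2 acts on both transitions, -H2O only on the second
  peaks <- data.frame(
    molecular_formula = c("C10H12O5", "C9H12O3", "C10H10O4",
                          "C10H12O5", "C9H12O3", "C10H10O4",
                          "C10H12O5", "C9H12O3", "C10H10O4"),
    snapshot = rep(1:3, each = 3),
    normalized_intensity = c(1.00, 0.10, 0.40,
                             0.80, 0.18, 0.40,
                             0.60, 0.30, 0.55))
  g <- predict_transformations(build_graph(peaks))
  expect_equal(sort(unique(paste(g$predicted$unit,
                                 g$predicted$from_snapshot))),
               c("-CO2 1", "-CO2 2", "-H2O 2"))
  sh <- unit_shares(g)
  pu <- sh$per_unit
  expect_true(pu$rel_change_defined[pu$unit == "-CO2"])
  expect_equal(pu$rel_change_pct[pu$unit == "-CO2"], -50)  # 1 -> 1/2
  expect_false(pu$rel_change_defined[pu$unit == "-H2O"])
  expect_true(is.na(pu$rel_change_pct[pu$unit == "-H2O"]))
  # per-transition shares each sum to one
  for (t in unique(sh$per_transition$transition))
    expect_equal(sum(sh$per_transition$share[
      sh$per_transition$transition == t]), 1)
})

test_that("group roll-up sums unit shares into photo addition vs elimination", {
  gr <- unit_group_shares(toy_graph())
  expect_equal(gr$share[gr$group == "photo_elimination"], 1)
  expect_equal(gr$share[gr$group == "photo_addition"], 0)
})

test_that("unit importance normalizes predicted-edge weight sums", {
  im <- unit_importance(toy_graph())
  expect_equal(im$importance[im$unit == "-CO2"], 0.065 / 0.11,
               tolerance = 1e-12)
  expect_equal(im$importance[im$unit == "-H2O"], 0.045 / 0.11,
               tolerance = 1e-12)
  expect_equal(sum(im$importance), 1)
  expect_true(all(im$defined))
})

test_that("intensity-weighted descriptors reduce to known means", {
  f1 <- "C10H12O5"; f2 <- "C10H10O4"  # linked by -H2O, so nothing is pruned
  peaks <- data.frame(molecular_formula = c(f1, f2, f1, f2),
                      snapshot = c(1, 1, 2, 2),
                      normalized_intensity = c(0.75, 0.25, 0.5, 0.5))
  g <- build_graph(peaks)
  wd <- weighted_descriptors(g)
  m1 <- monoisotopic_mass(f1); m2 <- monoisotopic_mass(f2)
  expect_equal(wd$mw[1], 0.75 * m1 + 0.25 * m2)
  expect_equal(wd$mw[2], (m1 + m2) / 2)  # uniform weights: plain mean
  d <- descriptors(c(f1, f2))
  expect_equal(wd$hc_ratio[2], mean(d$hc_ratio))
})

test_that("cluster reports tabulate sizes, composition and internal unit shares", {
  g <- toy_graph()
  lg <- to_light(g)
  a <- label_propagation(lg, seed = 2)
  rep <- cluster_report(a, g, lg)
  expect_equal(sum(rep$clusters$size), nrow(lg$nodes))
  # the toy collapses into one cluster of its three CHO formulas
  expect_equal(nrow(rep$clusters), 1L)
  expect_equal(rep$clusters$n_CHO, 3L)
  expect_equal(rep$clusters$n_CHNO, 0L)
  expect_equal(rep$clusters$n_internal_records, 2L)
  # pooled educt/product trends: (0.9 + 1.8 + 0.9 + 1.4) / 4
  expect_equal(rep$clusters$mean_intensity_trend, 1.25)
  us <- rep$unit_shares
  expect_equal(sum(us$share[us$cluster == 1]), 1)
  expect_equal(us$share[us$unit == "-CO2" & us$cluster == 1], 0.5)
  expect_equal(rep$n_boundary_records, 0L)
  bad <- a; bad$labels <- c(bad$labels, ZZZ = 1L)
  names(bad$labels)[length(bad$labels)] <- "C99H99O9"
  expect_error(cluster_report(bad, g, lg), "unknown formula")
})

test_that("symmetric loss and gain give cluster mean trends of exactly one", {
  peaks <- data.frame(
    molecular_formula = rep(c("C10H12O5", "C9H12O3"), 2),
    snapshot = c(1, 1, 2, 2),
    normalized_intensity = c(1.0, 0.5, 0.8, 0.6))  # trends 0.8 and 1.2
  g <- predict_transformations(build_graph(peaks))
  lg <- to_light(g)
  rep <- cluster_report(label_propagation(lg), g, lg)
  expect_equal(rep$clusters$mean_intensity_trend[1], 1, tolerance = 1e-9)
})
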