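# Config used for recovery checks: one active unit, transfers large enough
# that every transfer moves educt and product beyond the 5 % margin, products
# pre-seeded at low intensity so both ends exist on every snapshot.
recovery_config <- function(seed = 1, sigma = 0, n_snapshots = 5,
                            rates = c("-CO2" = 0.51)) {
  sim_config(n_formulas = 30, n_snapshots = n_snapshots, rates = rates,
             sigma = sigma, seed = seed, product_intensity_frac = 0.05)
}

test_that("simulation is byte-identical given the same seed", {
  s1 <- simulate_snapshots(recovery_config(seed = 4, sigma = 0.2))
  s2 <- simulate_snapshots(recovery_config(seed = 4, sigma = 0.2))
  expect_identical(s1$peaks, s2$peaks)
  expect_identical(s1$truth, s2$truth)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_peak_tables(s1$peaks, f1)
  write_peak_tables(s2$peaks, f2)
  expect_identical(readLines(f1), readLines(f2))
  s3 <- simulate_snapshots(recovery_config(seed = 5, sigma = 0.2))
  expect_false(identical(s1$peaks, s3$peaks))
})

test_that("noise-free intensity totals are conserved across transitions", {
  sim <- simulate_snapshots(recovery_config(seed = 2))
  tot <- tapply(sim$peaks$normalized_intensity, sim$peaks$snapshot, sum)
  expect_true(all(abs(tot - tot[1]) < 1e-12 * tot[1]))
  # the mineralization sink removes intensity monotonically
  cfg <- sim_config(n_formulas = 20, n_snapshots = 4, seed = 2,
                    mineralization_rate = 0.2)
  simm <- simulate_snapshots(cfg)
  totm <- tapply(simm$peaks$normalized_intensity, simm$peaks$snapshot, sum)
  expect_true(all(diff(totm) < 0))
})

test_that("every ground-truth record satisfies the TPA predicate when transfers exceed the margin", {
  sim <- simulate_snapshots(recovery_config(seed = 6))
  sa <- compute_same_as(sim$peaks)
  trend <- setNames(sa$intensity_trend, paste(sa$formula, sa$from_snapshot))
  et <- trend[paste(sim$truth$educt, sim$truth$transition)]
  pt <- trend[paste(sim$truth$product, sim$truth$transition)]
  expect_true(all(et < 0.95))
  expect_true(all(pt > 1.05))
})

test_that("the TPA recovers all ground-truth transformations on noise-free data", {
  sim <- simulate_snapshots(recovery_config(seed = 3))
  g <- predict_transformations(build_graph(sim$peaks), policy = "strict")
  ev <- evaluate_recovery(g, sim$truth)
  expect_equal(ev$overall$recall, 1.0)
  expect_equal(ev$overall$fn, 0L)
  expect_true(all(ev$per_transition$recall == 1))
})

test_that("zero rates leave all trends at one and no predicted edges", {
  sim <- simulate_snapshots(recovery_config(seed = 3,
                                            rates = c("-CO2" = 0)))
  expect_equal(nrow(sim$truth), 0L)
  sa <- compute_same_as(sim$peaks)
  expect_true(all(sa$intensity_trend == 1))
  g <- predict_transformations(build_graph(sim$peaks))
  expect_equal(nrow(g$predicted), 0L)
})

test_that("recall never increases with the margin or with noise (fixed seed)", {
  sim <- simulate_snapshots(recovery_config(seed = 8, sigma = 0.1))
  g <- build_graph(sim$peaks)
  rec <- vapply(c(0, 0.05, 0.2, 0.5), function(m)
    evaluate_recovery(predict_transformations(g, m), sim$truth)$overall$recall,
    0.0)
  expect_true(all(diff(rec) <= 0))
  rec_noise <- vapply(c(0, 0.3, 0.8), function(s) {
    simn <- simulate_snapshots(recovery_config(seed = 8, sigma = s))
    evaluate_recovery(predict_transformations(build_graph(simn$peaks)),
                      simn$truth)$overall$recall
  }, 0.0)
  expect_true(all(diff(rec_noise) <= 0))
})

test_that("recovery evaluation counts hits, misses and spurious edges", {
  truth <- data.frame(
    educt = c("A1", "A2", "A3", "A4"), product = c("B1", "B2", "B3", "B4"),
    unit = "-CO2", transition = 1L, amount = 0.1)
  pred <- data.frame(
    educt = c("A1", "A2", "A3", "A9"), product = c("B1", "B2", "B3", "B9"),
    unit = "-CO2", from_snapshot = 1L)
  ev <- evaluate_recovery(pred, truth)
  expect_equal(ev$overall$precision, 0.75)
  expect_equal(ev$overall$recall, 0.75)
  expect_equal(sort(unique(ev$confusion$status)),
               c("hit", "missed", "spurious"))
  empty <- evaluate_recovery(pred[0, ], truth)
  expect_equal(empty$overall$recall, 0)
  expect_true(is.na(empty$overall$precision))
})

test_that("simulator configuration is validated", {
  expect_error(sim_config(n_snapshots = 1), "n_snapshots")
  expect_error(sim_config(rates = c(0.3)), "named")
  expect_error(sim_config(rates = c("-CO2" = 0.3, "NOPE" = 0.1)), "named")
  expect_error(sim_config(sigma = -1), "nonnegative")
  expect_error(sim_config(rates = c("-CO2" = 50, "-H2O" = 50)),
               "below 1")
  expect_error(sim_config(doses = c(1, 1)), "length")
})
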