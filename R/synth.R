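#' Configuration for the synthetic snapshot simulator
#'
#' The simulator emulates a photodegradation time series: a pool of seed
#' formulas with log-uniform initial intensities decays by first-order
#' transfer kinetics along a set of active transformation units, with an
#' optional per-transition dose multiplier modulating the rates, optional
#' mineralization (intensity leaving the system), and multiplicative
#' log-normal measurement noise on the emitted tables.
#'
#' @param n_formulas Number of seed (precursor) formulas.
#' @param n_snapshots Number of snapshots `n >= 2`; transfers act on the
#'   `n - 1` transitions.
#' @param rates Named nonnegative vector of first-order rate constants per
#'   active transformation unit (names must exist in `units`). Per
#'   transition the transferred fraction is `1 - exp(-rate * dose)`.
#' @param doses Per-transition dose multipliers (length `n_snapshots - 1`);
#'   default all 1. A dose of 0 switches a transition off.
#' @param sigma Multiplicative log-normal noise level (sdlog) applied to the
#'   emitted intensities; 0 for noise-free tables.
#' @param seed Integer random seed; the simulation is fully deterministic
#'   given the seed.
#' @param c_range,o_range Integer ranges to sample carbon and oxygen counts.
#' @param h_per_c Range of the H/C ratio used to sample hydrogen counts.
#' @param n_max,s_max Maximum sampled nitrogen / sulfur counts.
#' @param product_intensity_frac Initial intensity of each reachable product
#'   formula, as a fraction of its (largest) educt's initial intensity, so
#'   products are detectable from the first snapshot.
#' @param mineralization_rate First-order rate of intensity loss from the
#'   system; 0 (default) keeps total intensity exactly conserved.
#' @param products_react If `FALSE` (default) only seed formulas act as
#'   educts and reaction products merely accumulate, keeping educt and
#'   product trends unambiguous; if `TRUE` every present formula reacts.
#' @param units Transformation-unit table.
#' @param elements Element set.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_formulas = 60, n_snapshots = 13,
                       rates = c("-CO2" = 0.35, "-H2O" = 0.30, "+O" = 0.25),
                       doses = NULL, sigma = 0, seed = 1,
                       c_range = c(12, 30), h_per_c = c(0.8, 1.8),
                       o_range = c(3, 14), n_max = 2, s_max = 1,
                       product_intensity_frac = 0.05,
                       mineralization_rate = 0, products_react = FALSE,
                       units = default_units(),
                       elements = default_elements()) {
  if (n_snapshots < 2) stop("n_snapshots must be >= 2", call. = FALSE)
  if (is.null(doses)) doses <- rep(1, n_snapshots - 1)
  if (length(doses) != n_snapshots - 1)
    stop("`doses` must have length n_snapshots - 1", call. = FALSE)
  if (any(doses < 0) || any(rates < 0) || sigma < 0)
    stop("rates, doses and sigma must be nonnegative", call. = FALSE)
  if (is.null(names(rates)) || !all(names(rates) %in% units$name))
    stop("`rates` must be named by units present in the unit table",
         call. = FALSE)
  frac_tot <- vapply(doses, function(d) sum(1 - exp(-rates * d)), 0.0)
  if (any(frac_tot > 0.999))
    stop("total transferred fraction per transition must stay below 1; ",
         "lower the rates or doses", call. = FALSE)
  structure(list(n_formulas = n_formulas, n_snapshots = as.integer(n_snapshots),
                 rates = rates, doses = doses, sigma = sigma,
                 seed = as.integer(seed), c_range = c_range,
                 h_per_c = h_per_c, o_range = o_range, n_max = n_max,
                 s_max = s_max,
                 product_intensity_frac = product_intensity_frac,
                 mineralization_rate = mineralization_rate,
                 products_react = products_react, units = units,
                 elements = elements), class = "sim_config")
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

.sample_seed_formulas <- function(cfg) {
  el <- cfg$elements
  out <- character(0)
  guard <- 0L
  while (length(out) < cfg$n_formulas && guard < 200L) {
    guard <- guard + 1L
    k <- cfg$n_formulas * 2L
    C <- sample(cfg$c_range[1]:cfg$c_range[2], k, replace = TRUE)
    H <- pmax(1L, round(C * stats::runif(k, cfg$h_per_c[1], cfg$h_per_c[2])))
    O <- sample(cfg$o_range[1]:cfg$o_range[2], k, replace = TRUE)
    N <- if ("N" %in% el) stats::rbinom(k, cfg$n_max, 0.25) else 0L
    S <- if ("S" %in% el) stats::rbinom(k, cfg$s_max, 0.2) else 0L
    cm <- cbind(C = C, H = H, N = as.integer(N), O = O, S = as.integer(S))
    cm <- cm[, intersect(c("C", "H", "N", "O", "S", "P"), el), drop = FALSE]
    out <- unique(c(out, formula_string(cm)))
  }
  utils::head(out, cfg$n_formulas)
}

#' Simulate snapshot peak tables with known ground truth
#'
#' Samples seed formulas and intensities, propagates them through
#' first-order transformation kinetics along the active units, and emits
#' peak tables in the standard format together with a ground-truth table of
#' every (educt, product, unit, transition) transfer. With
#' `products_react = FALSE` (default) product formulas overlapping the seed
#' pool are excluded so each ground-truth record moves its educt strictly
#' down and its product strictly up.
#'
#' @param cfg A [sim_config()].
#' @return List with `peaks` (peak table data.frame), `truth` (educt,
#'   product, unit, transition, amount), and `config`.
#' @export
simulate_snapshots <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  .with_seed(cfg$seed, {
    el <- cfg$elements
    seeds <- .sample_seed_formulas(cfg)
    active <- cfg$units[match(names(cfg$rates), cfg$units$name), ,
                        drop = FALSE]
    # enumerate reactions from the seed pool
    rx <- list()
    for (j in seq_len(nrow(active))) {
      prod <- apply_unit(seeds, active[j, , drop = FALSE], elements = el)
      ok <- !is.na(prod)
      if (!cfg$products_react) ok <- ok & !(prod %in% seeds)
      if (any(ok))
        rx[[length(rx) + 1L]] <- data.frame(
          educt = seeds[ok], product = prod[ok],
          unit = active$name[j], rate = cfg$rates[[active$name[j]]],
          stringsAsFactors = FALSE)
    }
    rx <- if (length(rx)) do.call(rbind, rx) else
      data.frame(educt = character(), product = character(),
                 unit = character(), rate = numeric(),
                 stringsAsFactors = FALSE)
    if (!nrow(rx))
      warning("no feasible reactions under this configuration")
    formulas <- sort(unique(c(seeds, rx$product)))
    n <- cfg$n_snapshots
    M <- matrix(0, nrow = length(formulas), ncol = n,
                dimnames = list(formulas, NULL))
    M[seeds, 1] <- 10^stats::runif(length(seeds), -1, 0)
    new_prod <- setdiff(rx$product, seeds)
    for (p in new_prod) {
      e_max <- max(M[rx$educt[rx$product == p], 1])
      M[p, 1] <- cfg$product_intensity_frac * e_max
    }
    truth <- list()
    for (t in seq_len(n - 1L)) {
      M[, t + 1] <- M[, t]
      d <- cfg$doses[t]
      if (nrow(rx) && d > 0) {
        frac <- 1 - exp(-rx$rate * d)
        amount <- frac * M[rx$educt, t]
        take <- amount > 0
        if (any(take)) {
          for (k in which(take)) {
            M[rx$educt[k], t + 1] <- M[rx$educt[k], t + 1] - amount[k]
            M[rx$product[k], t + 1] <- M[rx$product[k], t + 1] + amount[k]
          }
          truth[[t]] <- data.frame(
            educt = rx$educt[take], product = rx$product[take],
            unit = rx$unit[take], transition = t,
            amount = amount[take], stringsAsFactors = FALSE)
        }
      }
      if (cfg$mineralization_rate > 0)
        M[, t + 1] <- M[, t + 1] * exp(-cfg$mineralization_rate * d)
    }
    obs <- M
    if (cfg$sigma > 0)
      obs <- obs * matrix(stats::rlnorm(length(M), 0, cfg$sigma),
                          nrow = nrow(M))
    present <- which(obs > 0, arr.ind = TRUE)
    parsed <- parse_formula(rownames(M)[present[, 1]], el)
    peaks <- data.frame(molecular_formula = parsed$formula,
                        parsed[, el, drop = FALSE],
                        snapshot = as.integer(present[, 2]),
                        normalized_intensity = obs[present],
                        stringsAsFactors = FALSE, check.names = FALSE)
    peaks <- .sort_df(peaks, c("snapshot", "molecular_formula"))
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(educt = character(), product = character(),
                 unit = character(), transition = integer(),
                 amount = numeric(), stringsAsFactors = FALSE)
    truth <- .sort_df(truth, c("transition", "educt", "product", "unit"))
    list(peaks = peaks, truth = truth, config = cfg)
  })
}

#' Precision and recall of predicted transformations against ground truth
#'
#' Matches predicted edges and ground-truth records on exact
#' (educt, product, unit, transition) tuples and reports precision and
#' recall per transition and overall, with a confusion listing.
#'
#' @param predicted A `temporal_graph` with predictions, or a data.frame
#'   with columns `educt`, `product`, `unit` and `from_snapshot` (or
#'   `transition`).
#' @param truth Ground-truth data.frame as returned by
#'   [simulate_snapshots()].
#' @return List with `overall` (precision, recall, tp, fp, fn),
#'   `per_transition`, and `confusion` (tuples labelled hit / missed /
#'   spurious).
#' @export
evaluate_recovery <- function(predicted, truth) {
  if (inherits(predicted, "temporal_graph")) {
    if (is.null(predicted$predicted))
      stop("graph has no predictions", call. = FALSE)
    predicted <- predicted$predicted
  }
  tcol <- intersect(c("from_snapshot", "transition"), names(predicted))[1]
  pk <- unique(paste(predicted$educt, predicted$product, predicted$unit,
                     predicted[[tcol]], sep = "\r"))
  tk <- unique(paste(truth$educt, truth$product, truth$unit,
                     truth$transition, sep = "\r"))
  hit <- intersect(pk, tk)
  spurious <- setdiff(pk, tk)
  missed <- setdiff(tk, pk)
  pr_rec <- function(p, t, h) {
    c(precision = if (length(p)) length(h) / length(p) else NA_real_,
      recall = if (length(t)) length(h) / length(t) else NA_real_)
  }
  split_key <- function(keys, status) {
    if (!length(keys)) return(NULL)
    parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
    data.frame(educt = parts[, 1], product = parts[, 2], unit = parts[, 3],
               transition = as.integer(parts[, 4]), status = status,
               stringsAsFactors = FALSE)
  }
  confusion <- do.call(rbind, Filter(Negate(is.null), list(
    split_key(hit, "hit"), split_key(missed, "missed"),
    split_key(spurious, "spurious"))))
  if (is.null(confusion))
    confusion <- data.frame(educt = character(), product = character(),
                            unit = character(), transition = integer(),
                            status = character(), stringsAsFactors = FALSE)
  trans <- sort(unique(c(confusion$transition)))
  per_transition <- do.call(rbind, lapply(trans, function(t) {
    ck <- confusion[confusion$transition == t, ]
    tp <- sum(ck$status == "hit")
    fp <- sum(ck$status == "spurious")
    fn <- sum(ck$status == "missed")
    data.frame(transition = t, tp = tp, fp = fp, fn = fn,
               precision = if (tp + fp) tp / (tp + fp) else NA_real_,
               recall = if (tp + fn) tp / (tp + fn) else NA_real_)
  }))
  ov <- pr_rec(pk, tk, hit)
  list(overall = data.frame(precision = ov[["precision"]],
                            recall = ov[["recall"]],
                            tp = length(hit), fp = length(spurious),
                            fn = length(missed)),
       per_transition = per_transition,
       confusion = .sort_df(confusion,
                            c("transition", "educt", "product", "unit")))
  }
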