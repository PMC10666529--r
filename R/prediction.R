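#' Classify an intensity trend against the measurement error margin
#'
#' The trend is the ratio of later to earlier normalized intensity. A trend
#' strictly below `1 - margin` is `decreasing`, strictly above `1 + margin`
#' is `increasing`, and anything inside the closed band (boundaries
#' included) is `consistent`: a change must exceed the error margin before
#' it is acted upon.
#'
#' @param trend Positive numeric vector of intensity ratios.
#' @param margin Error margin `m` in `[0, 1)`; default 0.05 (5 %).
#' @return Character vector in `{"increasing", "decreasing", "consistent"}`.
#' @examples
#' classify_trend(c(0.8, 1.03, 1.05, 1.2))
#' @export
classify_trend <- function(trend, margin = 0.05) {
  .check_margin(margin)
  if (any(!is.finite(trend) | trend <= 0))
    stop("intensity trends must be positive and finite", call. = FALSE)
  ifelse(trend < 1 - margin, "decreasing",
         ifelse(trend > 1 + margin, "increasing", "consistent"))
}

.check_margin <- function(margin) {
  if (!is.numeric(margin) || length(margin) != 1 || is.na(margin) ||
      margin < 0 || margin >= 1)
    stop("`margin` must be a single number in [0, 1)", call. = FALSE)
}

# Trend class lookup per (formula, transition), honoring the missing-node
# policy. Returns classes for the given keys; NA where no SAME_AS edge exists
# and the policy is strict.
.trend_class_lookup <- function(same_as, margin) {
  stats::setNames(classify_trend(same_as$intensity_trend, margin),
                  paste(same_as$formula, same_as$from_snapshot))
}

#' Predict likely chemical transformations (TPA)
#'
#' The transformation prediction algorithm selects the subset of potential
#' transformation edges consistent with the observed intensity dynamics:
#' an edge `educt@t -> product@t+1` is predicted if and only if the educt's
#' SAME_AS trend over that transition is decreasing and the product's is
#' increasing, both beyond the error margin. The predicate is edge-local, so
#' the result is independent of iteration order.
#'
#' Formulas that appear or disappear between snapshots have no SAME_AS edge
#' on the transition. Under `policy = "strict"` such nodes never qualify;
#' under `policy = "zero_fill"` a product absent at `t` counts as increasing
#' and an educt absent at `t + 1` counts as decreasing, so newly formed and
#' fully consumed (transient) compounds can take part.
#'
#' @param g A built `temporal_graph`.
#' @param margin Error margin, see [classify_trend()].
#' @param policy `"strict"` (default) or `"zero_fill"`.
#' @return `g` with a `predicted` edge table (subset of `g$potential`) and
#'   `margin`/`policy` recorded.
#' @export
predict_transformations <- function(g, margin = 0.05,
                                    policy = c("strict", "zero_fill")) {
  stopifnot(inherits(g, "temporal_graph"))
  policy <- match.arg(policy)
  .check_margin(margin)
  po <- g$potential
  cls <- .trend_class_lookup(g$same_as, margin)
  e_cls <- unname(cls[paste(po$educt, po$from_snapshot)])
  p_cls <- unname(cls[paste(po$product, po$from_snapshot)])
  if (policy == "zero_fill") {
    e_cls[is.na(e_cls)] <- "decreasing"
    p_cls[is.na(p_cls)] <- "increasing"
  }
  keep <- !is.na(e_cls) & !is.na(p_cls) &
    e_cls == "decreasing" & p_cls == "increasing"
  pred <- po[keep, , drop = FALSE]
  g$predicted <- .sort_df(pred, c("from_snapshot", "educt", "product", "unit"))
  g$margin <- margin
  g$policy <- policy
  g
}

#' Weight predicted transformation edges
#'
#' Each predicted edge `A@t -> B@t+1` is weighted by equal apportionment of
#' the educt's intensity loss over its outgoing predicted edges and the
#' product's intensity gain over its incoming predicted edges on that
#' transition:
#' `weight = 0.5 * (loss_A / outdeg(A, t) + gain_B / indeg(B, t + 1))`,
#' with `loss_A = I_A(t) - I_A(t+1)` (all of `I_A(t)` when the educt
#' disappears under the zero-fill policy) and
#' `gain_B = I_B(t+1) - I_B(t)` (all of `I_B(t+1)` when the product is new).
#' Per transition the weights therefore sum to half the total participating
#' loss plus gain, a conservation law asserted by the test suite.
#'
#' @param g A `temporal_graph` after [predict_transformations()].
#' @return `g` with a `weight` column on the predicted edges.
#' @export
compute_edge_weights <- function(g) {
  stopifnot(inherits(g, "temporal_graph"))
  if (is.null(g$predicted))
    stop("run predict_transformations() first", call. = FALSE)
  pr <- g$predicted
  if (!nrow(pr)) {
    pr$weight <- numeric(0)
    g$predicted <- pr
    return(g)
  }
  I <- stats::setNames(g$nodes$normalized_intensity,
                       paste(g$nodes$formula, g$nodes$snapshot))
  iA0 <- unname(I[paste(pr$educt, pr$from_snapshot)])
  iA1 <- unname(I[paste(pr$educt, pr$to_snapshot)])
  iB1 <- unname(I[paste(pr$product, pr$to_snapshot)])
  iB0 <- unname(I[paste(pr$product, pr$from_snapshot)])
  loss <- iA0 - ifelse(is.na(iA1), 0, iA1)
  gain <- iB1 - ifelse(is.na(iB0), 0, iB0)
  okey <- paste(pr$educt, pr$from_snapshot)
  ikey <- paste(pr$product, pr$to_snapshot)
  outdeg <- as.numeric(table(okey)[okey])
  indeg <- as.numeric(table(ikey)[ikey])
  pr$weight <- 0.5 * (loss / outdeg + gain / indeg)
  g$predicted <- pr
  g
}
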