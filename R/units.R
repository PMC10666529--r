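.UNIT_DELTA_COLS <- c("dC", "dH", "dN", "dO", "dS", "dP")

.pkg_env <- new.env(parent = emptyenv())

#' Load a transformation-unit table
#'
#' A transformation unit is a named signed elemental delta (e.g. "-CO2" for
#' decarboxylation) representing the net formula change of a reaction. Units
#' are grouped by the sign of their monoisotopic mass delta into
#' `photo_addition` (mass gain) and `photo_elimination` (mass loss); forward
#' and reverse reactions are distinct units and no reverse is generated
#' automatically. Units are matched by exact integer element differences,
#' never by mass tolerance.
#'
#' @param path CSV file with columns `name,dC,dH,dN,dO,dS` and optionally
#'   `dP`; deltas are signed integers.
#' @return A `unit_table` data.frame with columns `name`, the delta columns,
#'   `mass_delta` (Da) and `group`.
#' @seealso [default_units()] for the built-in table.
#' @export
load_units <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = TRUE)
  if (!"name" %in% names(df))
    stop("unit table must have a 'name' column", call. = FALSE)
  need <- setdiff(.UNIT_DELTA_COLS, c("dP"))
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("unit table missing delta column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"dP" %in% names(df)) df$dP <- 0L
  df <- df[, c("name", .UNIT_DELTA_COLS)]
  as_unit_table(df)
}

#' Construct a unit table from a data.frame
#'
#' Validates a data.frame of named signed elemental deltas and computes the
#' mass delta and photo addition/elimination group of each unit.
#'
#' @param df data.frame with `name` and delta columns `dC,dH,dN,dO,dS[,dP]`.
#' @return A `unit_table` data.frame.
#' @export
as_unit_table <- function(df) {
  if (!"dP" %in% names(df)) df$dP <- 0L
  for (col in .UNIT_DELTA_COLS) {
    v <- df[[col]]
    if (is.null(v)) stop("missing delta column ", col, call. = FALSE)
    if (!is.numeric(v) || any(is.na(v)) || any(v != round(v))) {
      bad <- which(!is.finite(v) | v != round(v))[1]
      stop(sprintf("non-integer delta in column %s, row %d", col,
                   if (is.na(bad)) 1L else bad), call. = FALSE)
    }
    df[[col]] <- as.integer(round(v))
  }
  dm <- as.matrix(df[, .UNIT_DELTA_COLS])
  zero <- rowSums(dm != 0L) == 0L
  if (any(zero))
    stop("all-zero delta in unit table row ", which(zero)[1], call. = FALSE)
  if (anyDuplicated(df$name))
    stop("duplicate unit name: ", df$name[duplicated(df$name)][1],
         call. = FALSE)
  key <- apply(dm, 1, paste, collapse = ",")
  if (anyDuplicated(key))
    stop("two units share the same delta vector (rows ",
         paste(which(key == key[duplicated(key)][1]), collapse = ", "), ")",
         call. = FALSE)
  colnames(dm) <- sub("^d", "", .UNIT_DELTA_COLS)
  df$mass_delta <- as.numeric(dm %*% .MONOISOTOPIC[colnames(dm)])
  if (any(abs(df$mass_delta) < 1e-9))
    stop("unit with zero mass delta: ",
         df$name[abs(df$mass_delta) < 1e-9][1], call. = FALSE)
  df$group <- ifelse(df$mass_delta > 0, "photo_addition", "photo_elimination")
  row.names(df) <- NULL
  class(df) <- c("unit_table", "data.frame")
  df
}

#' Built-in photochemical transformation-unit table
#'
#' The packaged default of 22 photochemical transformation units covering the
#' elimination of small stable fragments (CO2, CO, H2O, H2, CH2, CH2O,
#' HCOOH, ketene, acetic acid, CH4, SO3, H2SO4, NH3, reverse nitration) and
#' the additions driving photo-oxidation (+O, +O2, -H2+O, hydrogenation,
#' hydration, nitration, oxidative deamination). The table is a synthetic
#' compilation assembled from transformation units commonly reported for DOM
#' photochemistry; replace it with a lab-specific table via [load_units()].
#'
#' @return A `unit_table` data.frame with 22 rows.
#' @export
default_units <- function() {
  if (is.null(.pkg_env$default_units)) {
    path <- system.file("extdata", "transformation_units_synthetic.csv",
                        package = "domgraph", mustWork = TRUE)
    .pkg_env$default_units <- load_units(path)
  }
  .pkg_env$default_units
}

# Signed delta of one unit over a target element set, or NULL when the unit
# moves an element outside that set (then it can never apply).
.unit_delta <- function(unit, elements) {
  d <- stats::setNames(as.integer(unit[1, .UNIT_DELTA_COLS]),
                       sub("^d", "", .UNIT_DELTA_COLS))
  if (any(d[setdiff(names(d), elements)] != 0L)) return(NULL)
  d[elements]
}

.get_unit <- function(units, unit) {
  if (is.character(unit)) {
    i <- match(unit, units$name)
    if (is.na(i)) stop("unknown unit name: ", unit, call. = FALSE)
    units[i, , drop = FALSE]
  } else unit
}

#' Apply a transformation unit to molecular formulas
#'
#' Adds the unit's signed elemental delta to each formula. Infeasible results
#' (any negative element count, or carbon dropping to zero) are reported as
#' `NA`, not as errors: infeasibility is an ordinary value during edge
#' enumeration.
#'
#' @param mf Character vector of formulas (or count table).
#' @param unit A single-row `unit_table` slice, or a unit name looked up in
#'   `units`.
#' @param units Unit table used when `unit` is a name.
#' @param elements Element set.
#' @return Character vector of product formulas, `NA` where infeasible.
#' @examples
#' apply_unit("C10H12O5", "-CO2") # "C9H12O3"
#' @export
apply_unit <- function(mf, unit, units = default_units(),
                       elements = default_elements()) {
  elements <- .check_elements(elements)
  unit <- .get_unit(units, unit)
  cm <- .as_count_matrix(mf, elements)
  d <- .unit_delta(unit, elements)
  if (is.null(d)) return(rep(NA_character_, nrow(cm)))
  res <- sweep(cm, 2, d, "+")
  ok <- rowSums(res < 0L) == 0L & res[, "C"] >= 1L
  out <- rep(NA_character_, nrow(res))
  if (any(ok)) out[ok] <- formula_string(res[ok, , drop = FALSE])
  out
}

#' Transformation units matching an educt/product formula pair
#'
#' Returns every unit in the table whose delta equals the exact element-count
#' difference `product - educt`. Direction is encoded per unit: a pair is
#' matched by "+CO2" only if the table carries that unit, never by reversing
#' "-CO2".
#'
#' @param educt,product Single formula strings.
#' @param units Unit table.
#' @param elements Element set.
#' @return `unit_table` subset (possibly empty) of matching units.
#' @examples
#' match_delta("C10H12O5", "C9H12O3")$name # "-CO2"
#' @export
match_delta <- function(educt, product, units = default_units(),
                        elements = default_elements()) {
  elements <- .check_elements(elements)
  e <- .as_count_matrix(educt, elements)[1, ]
  p <- .as_count_matrix(product, elements)[1, ]
  delta <- p - e
  hits <- vapply(seq_len(nrow(units)), function(j) {
    d <- .unit_delta(units[j, , drop = FALSE], elements)
    !is.null(d) && all(d == delta)
  }, logical(1))
  units[hits, , drop = FALSE]
}
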