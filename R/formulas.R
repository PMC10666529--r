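# Monoisotopic atomic masses (Da), IUPAC values. Single source of truth for
# all mass arithmetic in the package; six or more decimals everywhere.
.MONOISOTOPIC <- c(
  C = 12.0,
  H = 1.00782503207,
  N = 14.0030740048,
  O = 15.9949146196,
  S = 31.97207100,
  P = 30.97376163
)

#' Default element set for molecular formulas
#'
#' Formulas are represented over a fixed element set. The default covers the
#' CHNOS space typical of dissolved organic matter formula assignment;
#' phosphorus can be enabled by passing `c(default_elements(), "P")` wherever
#' an `elements` argument is accepted. Symbols outside the configured set are
#' rejected, never silently dropped.
#'
#' @return Character vector of element symbols.
#' @export
default_elements <- function() c("C", "H", "N", "O", "S")

.supported_elements <- function() names(.MONOISOTOPIC)

.check_elements <- function(elements) {
  if (!is.character(elements) || length(elements) < 1)
    stop("`elements` must be a non-empty character vector", call. = FALSE)
  bad <- setdiff(elements, .supported_elements())
  if (length(bad))
    stop("unsupported element(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (!"C" %in% elements)
    stop("the element set must contain C", call. = FALSE)
  elements
}

# Hill order: C first, H second, remaining symbols alphabetical.
.hill_order <- function(elements) {
  c(intersect(c("C", "H"), elements), sort(setdiff(elements, c("C", "H"))))
}

.parse_one <- function(s, elements) {
  if (is.na(s) || !nzchar(s))
    stop("empty molecular formula string", call. = FALSE)
  toks <- regmatches(s, gregexpr("[A-Z][a-z]*[0-9]*", s))[[1]]
  if (paste(toks, collapse = "") != s)
    stop(sprintf("cannot parse formula '%s': unexpected characters", s),
         call. = FALSE)
  sym <- sub("[0-9]*$", "", toks)
  num <- sub("^[A-Za-z]+", "", toks)
  bad <- !(sym %in% elements)
  if (any(bad))
    stop(sprintf("unknown element symbol '%s' in formula '%s'",
                 sym[bad][1], s), call. = FALSE)
  if (anyDuplicated(sym))
    stop(sprintf("duplicate element '%s' in formula '%s'",
                 sym[duplicated(sym)][1], s), call. = FALSE)
  cnt <- suppressWarnings(as.integer(ifelse(num == "", "1", num)))
  ok <- !is.na(cnt) & cnt > 0
  if (!all(ok))
    stop(sprintf("invalid count in token '%s' of formula '%s'",
                 toks[!ok][1], s), call. = FALSE)
  out <- stats::setNames(integer(length(elements)), elements)
  out[sym] <- cnt
  if (out[["C"]] < 1)
    stop(sprintf("formula '%s' contains no carbon", s), call. = FALSE)
  out
}

#' Parse molecular formula strings
#'
#' Parses Hill-notation style formula strings ("C10H12O5") into integer
#' element counts over a configured element set and returns the canonical
#' (Hill order) string alongside. A bare symbol has an implicit count of 1.
#' Unknown symbols, zero or negative counts, duplicated symbols, and empty
#' strings are errors naming the offending token.
#'
#' @param text Character vector of formula strings.
#' @param elements Element set, see [default_elements()].
#' @return A data.frame with columns `formula` (canonical string) and one
#'   integer count column per element.
#' @examples
#' parse_formula(c("C10H12O5", "C6H6"))
#' @export
parse_formula <- function(text, elements = default_elements()) {
  elements <- .check_elements(elements)
  if (!is.character(text)) stop("`text` must be character", call. = FALSE)
  counts <- matrix(0L, nrow = length(text), ncol = length(elements),
                   dimnames = list(NULL, elements))
  for (i in seq_along(text)) counts[i, ] <- .parse_one(text[[i]], elements)
  out <- data.frame(formula = formula_string(counts, elements),
                    counts, stringsAsFactors = FALSE, check.names = FALSE)
  row.names(out) <- NULL
  out
}

#' Canonical (Hill order) formula string from element counts
#'
#' @param counts Matrix or data.frame of element counts with element-named
#'   columns, or a single named vector.
#' @param elements Element set; defaults to the count columns.
#' @return Character vector of canonical formula strings.
#' @export
formula_string <- function(counts, elements = NULL) {
  counts <- .as_count_matrix(counts, elements)
  ord <- .hill_order(colnames(counts))
  counts <- counts[, ord, drop = FALSE]
  apply(counts, 1, function(ct) {
    nz <- ct > 0
    paste0(ifelse(ct[nz] == 1L, ord[nz], paste0(ord[nz], ct[nz])),
           collapse = "")
  })
}

# Coerce formula strings / count tables / named vectors to a count matrix.
.as_count_matrix <- function(x, elements = NULL) {
  if (is.character(x)) {
    elements <- .check_elements(if (is.null(elements)) default_elements()
                                else elements)
    return(as.matrix(parse_formula(x, elements)[, elements, drop = FALSE]))
  }
  if (is.numeric(x) && !is.matrix(x)) x <- t(as.matrix(x))
  if (is.data.frame(x)) {
    if (is.null(elements))
      elements <- intersect(.supported_elements(), names(x))
    x <- as.matrix(x[, elements, drop = FALSE])
  } else if (is.matrix(x)) {
    if (!is.null(elements)) x <- x[, elements, drop = FALSE]
  } else {
    stop("cannot interpret element counts", call. = FALSE)
  }
  if (is.null(colnames(x)) || !all(colnames(x) %in% .supported_elements()))
    stop("element counts must have element-symbol column names", call. = FALSE)
  storage.mode(x) <- "integer"
  x
}

#' Monoisotopic mass of element count vectors
#'
#' Linear in the counts; signed vectors are allowed so the mass of a
#' transformation delta (possibly negative) is well defined.
#'
#' @param counts Element counts: a named vector, count matrix/data.frame, or
#'   character vector of formulas.
#' @param elements Optional element subset to use.
#' @return Numeric vector of masses in Da.
#' @examples
#' monoisotopic_mass(c(C = 1, O = 2)) # CO2
#' @export
monoisotopic_mass <- function(counts, elements = NULL) {
  m <- .as_count_matrix(counts, elements)
  as.numeric(m %*% .MONOISOTOPIC[colnames(m)])
}

#' Molecular descriptors from formula composition
#'
#' Computes the standard formula-level descriptors used to characterise
#' complex organic mixtures: elemental ratios H/C and O/C, molecular weight
#' (monoisotopic), double-bond equivalents, the aromaticity index in both its
#' modified (0.5 O, default reported) and plain variants, the nominal
#' oxidation state of carbon, and the heteroatom element class.
#'
#' Definitions (counts per formula): DBE = 1 + C - H/2 + N/2;
#' AImod = (1 + C - 0.5 O - S - 0.5 H) / (C - 0.5 O - N - S - P) and
#' AI = (1 + C - O - S - 0.5 H) / (C - O - N - S - P), both set to 0 when the
#' denominator is <= 0 so descriptor tables never hold undefined entries;
#' NOSC = 4 - (4 C + H - 3 N - 2 O - 2 S) / C. The element class is CHO,
#' CHNO, CHOS or CHNOS according to which of N and S are present (O required),
#' and "other" otherwise.
#'
#' @param x Character vector of formulas or a data.frame/matrix of counts.
#' @param elements Element set used when `x` is character.
#' @return data.frame with columns `formula`, `hc_ratio`, `oc_ratio`, `mw`,
#'   `dbe`, `ai_mod`, `ai`, `nosc`, `element_class`.
#' @examples
#' descriptors("C6H12O6")$nosc  # 0: carbohydrate-like oxidation state
#' @export
descriptors <- function(x, elements = default_elements()) {
  m <- .as_count_matrix(x, if (is.character(x)) elements else NULL)
  gc <- function(e) if (e %in% colnames(m)) as.numeric(m[, e]) else
    numeric(nrow(m))
  C <- gc("C"); H <- gc("H"); N <- gc("N"); O <- gc("O")
  S <- gc("S"); P <- gc("P")
  if (any(C < 1)) stop("descriptors require C >= 1", call. = FALSE)
  if (any(m < 0)) stop("descriptors require nonnegative counts", call. = FALSE)
  den_mod <- C - 0.5 * O - N - S - P
  den_pln <- C - O - N - S - P
  ai_mod <- ifelse(den_mod > 0, (1 + C - 0.5 * O - S - 0.5 * H) / den_mod, 0)
  ai <- ifelse(den_pln > 0, (1 + C - O - S - 0.5 * H) / den_pln, 0)
  cls <- rep("other", nrow(m))
  cls[O > 0 & N == 0 & S == 0 & P == 0] <- "CHO"
  cls[O > 0 & N > 0 & S == 0 & P == 0] <- "CHNO"
  cls[O > 0 & N == 0 & S > 0 & P == 0] <- "CHOS"
  cls[O > 0 & N > 0 & S > 0 & P == 0] <- "CHNOS"
  out <- data.frame(
    formula = formula_string(m),
    hc_ratio = H / C,
    oc_ratio = O / C,
    mw = monoisotopic_mass(m),
    dbe = 1 + C - H / 2 + N / 2,
    ai_mod = ai_mod,
    ai = ai,
    nosc = 4 - (4 * C + H - 3 * N - 2 * O - 2 * S) / C,
    element_class = cls,
    stringsAsFactors = FALSE
  )
  row.names(out) <- NULL
  out
}
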