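.PEAK_COLS <- c("molecular_formula", "C", "H", "N", "O", "S", "snapshot",
                "normalized_intensity")

# Full-precision numeric-to-text: values written by the exporters must
# round-trip exactly through as.numeric().
.num_chr <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- NA_character_
  out
}

#' Read snapshot peak tables
#'
#' Reads one or more CSV peak tables (either a single file holding all
#' snapshots or one file per snapshot) with the documented schema
#' `molecular_formula,C,H,N,O,S,snapshot,normalized_intensity`. Every row's
#' element columns are cross-checked against the parsed formula string, and
#' duplicate (formula, snapshot) rows or non-consecutive snapshot indices
#' are rejected with the offending location. Extra columns (e.g. per-sample
#' metadata) are passed through.
#'
#' @param paths Character vector of CSV file paths.
#' @param elements Element set.
#' @return Validated data.frame with canonical formula strings.
#' @export
read_peak_tables <- function(paths, elements = default_elements()) {
  elements <- .check_elements(elements)
  dfs <- lapply(paths, function(p) {
    df <- utils::read.csv(p, stringsAsFactors = FALSE, check.names = FALSE)
    miss <- setdiff(.PEAK_COLS, names(df))
    if (length(miss))
      stop("file ", p, ": missing column(s) ", paste(miss, collapse = ", "),
           call. = FALSE)
    df$.file <- p
    df$.row <- seq_len(nrow(df)) + 1L  # header is line 1
    df
  })
  df <- do.call(rbind, dfs)
  parsed <- parse_formula(as.character(df$molecular_formula), elements)
  for (e in intersect(c("C", "H", "N", "O", "S"), elements)) {
    bad <- which(as.integer(df[[e]]) != parsed[[e]])
    if (length(bad))
      stop(sprintf("file %s line %d: column %s (%s) contradicts formula '%s'",
                   df$.file[bad[1]], df$.row[bad[1]], e, df[[e]][bad[1]],
                   df$molecular_formula[bad[1]]), call. = FALSE)
  }
  df$molecular_formula <- parsed$formula
  key <- paste(df$molecular_formula, df$snapshot)
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1]
    stop(sprintf("duplicate (formula, snapshot) row: %s at file %s line %d",
                 key[i], df$.file[i], df$.row[i]), call. = FALSE)
  }
  snaps <- sort(unique(as.integer(df$snapshot)))
  if (!identical(snaps, seq_len(max(snaps))))
    stop("snapshot indices must be consecutive integers starting at 1; got ",
         paste(snaps, collapse = ", "), call. = FALSE)
  df$.file <- NULL
  df$.row <- NULL
  row.names(df) <- NULL
  df
}

#' Write a peak table in the standard schema
#'
#' @param peaks Peak table data.frame.
#' @param path Output CSV path.
#' @param elements Element set.
#' @return `path`, invisibly.
#' @export
write_peak_tables <- function(peaks, path, elements = default_elements()) {
  fcol <- intersect(c("molecular_formula", "formula"), names(peaks))[1]
  parsed <- parse_formula(as.character(peaks[[fcol]]), elements)
  out <- data.frame(molecular_formula = parsed$formula,
                    stringsAsFactors = FALSE)
  for (e in c("C", "H", "N", "O", "S"))
    out[[e]] <- if (e %in% elements) parsed[[e]] else 0L
  out$snapshot <- as.integer(peaks$snapshot)
  out$normalized_intensity <- .num_chr(peaks$normalized_intensity)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.units_to_plain <- function(units) units[, c("name", .UNIT_DELTA_COLS)]

.meta_list <- function(g, kind) {
  list(kind = kind,
       n_snapshots = g$n_snapshots,
       omitted_fraction = g$omitted_fraction,
       margin = if (is.null(g$margin)) NA else g$margin,
       policy = if (is.null(g$policy)) NA else g$policy,
       elements = g$elements,
       has_predictions = if (kind == "light") isTRUE(g$has_predictions) else
         !is.null(g$predicted),
       has_weights = if (kind == "light") isTRUE(g$has_weights) else
         (!is.null(g$predicted) && "weight" %in% names(g$predicted)))
}

.apply_meta <- function(g, meta) {
  g$n_snapshots <- as.integer(meta$n_snapshots)
  g$omitted_fraction <- as.numeric(meta$omitted_fraction)
  g$margin <- if (is.null(meta$margin) || is.na(meta$margin)) NULL else
    as.numeric(meta$margin)
  g$policy <- if (is.null(meta$policy) || is.na(meta$policy)) NULL else
    as.character(meta$policy)
  g$elements <- as.character(meta$elements)
  g
}

#' Export a temporal or light graph
#'
#' Writes the graph under `dir` in one of three formats: `graphml` (typed
#' node/edge attributes, via igraph), `node_edge_tables` (delimited node and
#' edge tables plus a JSON metadata document, suitable for bulk
#' graph-database import), or `cypher_script` (a text script of
#' graph-creation statements; temporal graphs only). Every format written by
#' this package can be read back with [import_graph()].
#'
#' @param g A `temporal_graph` or `light_graph`.
#' @param dir Output directory (created if needed).
#' @param format One of `"graphml"`, `"node_edge_tables"`,
#'   `"cypher_script"`.
#' @return Character vector of the files written, invisibly.
#' @export
export_graph <- function(g, dir,
                         format = c("graphml", "node_edge_tables",
                                    "cypher_script")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  light <- inherits(g, "light_graph")
  if (!light && !inherits(g, "temporal_graph"))
    stop("`g` must be a temporal_graph or light_graph", call. = FALSE)
  switch(format,
         graphml = .export_graphml(g, dir, light),
         node_edge_tables = .export_tables(g, dir, light),
         cypher_script = .export_cypher(g, dir, light))
}

#' Import a graph written by [export_graph()]
#'
#' @param dir Directory previously written by [export_graph()].
#' @param format Format the graph was written in.
#' @return A `temporal_graph` or `light_graph`.
#' @export
import_graph <- function(dir,
                         format = c("graphml", "node_edge_tables",
                                    "cypher_script")) {
  format <- match.arg(format)
  switch(format,
         graphml = .import_graphml(dir),
         node_edge_tables = .import_tables(dir),
         cypher_script = .import_cypher(dir))
}

## ---- graphml ----------------------------------------------------------

.export_graphml <- function(g, dir, light) {
  path <- file.path(dir, "graph.graphml")
  if (light) {
    series_json <- vapply(g$nodes$formula, function(f) {
      s <- g$series[g$series$formula == f, c("snapshot",
                                             "normalized_intensity")]
      as.character(jsonlite::toJSON(s, digits = NA))
    }, "")
    vs <- data.frame(name = g$nodes$formula, series = unname(series_json),
                     stringsAsFactors = FALSE)
    rec_json <- vapply(seq_len(nrow(g$edges)), function(i) {
      r <- g$records[g$records$educt == g$edges$educt[i] &
                       g$records$product == g$edges$product[i],
                     c("transition", "unit", "predicted", "weight")]
      as.character(jsonlite::toJSON(r, digits = NA, na = "null"))
    }, "")
    es <- data.frame(from = g$edges$educt, to = g$edges$product,
                     records = rec_json, stringsAsFactors = FALSE)
    ig <- igraph::graph_from_data_frame(es, directed = TRUE, vertices = vs)
  } else {
    vs <- data.frame(name = paste0(g$nodes$formula, "@", g$nodes$snapshot),
                     formula = g$nodes$formula,
                     snapshot = g$nodes$snapshot,
                     normalized_intensity = g$nodes$normalized_intensity,
                     stringsAsFactors = FALSE)
    blank <- function(n, fill = NA_real_) rep(fill, n)
    sa <- g$same_as
    es1 <- data.frame(from = paste0(sa$formula, "@", sa$from_snapshot),
                      to = paste0(sa$formula, "@", sa$to_snapshot),
                      type = "SAME_AS", unit = "",
                      intensity_trend = sa$intensity_trend,
                      weight = blank(nrow(sa)), stringsAsFactors = FALSE)
    po <- g$potential
    es2 <- data.frame(from = paste0(po$educt, "@", po$from_snapshot),
                      to = paste0(po$product, "@", po$to_snapshot),
                      type = "POTENTIAL_TRANSFORMATION", unit = po$unit,
                      intensity_trend = blank(nrow(po)),
                      weight = blank(nrow(po)), stringsAsFactors = FALSE)
    es <- rbind(es1, es2)
    if (!is.null(g$predicted)) {
      pr <- g$predicted
      es3 <- data.frame(from = paste0(pr$educt, "@", pr$from_snapshot),
                        to = paste0(pr$product, "@", pr$to_snapshot),
                        type = "PREDICTED_TRANSFORMATION", unit = pr$unit,
                        intensity_trend = blank(nrow(pr)),
                        weight = if ("weight" %in% names(pr)) pr$weight else
                          blank(nrow(pr)),
                        stringsAsFactors = FALSE)
      es <- rbind(es, es3)
    }
    ig <- igraph::graph_from_data_frame(es, directed = TRUE, vertices = vs)
  }
  meta <- .meta_list(g, if (light) "light" else "temporal")
  ig <- igraph::set_graph_attr(ig, "meta_json",
                               as.character(jsonlite::toJSON(meta,
                                                             digits = NA,
                                                             na = "null")))
  ig <- igraph::set_graph_attr(ig, "units_json",
                               as.character(jsonlite::toJSON(
                                 .units_to_plain(g$units), digits = NA)))
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}

.import_graphml <- function(dir) {
  path <- if (dir.exists(dir)) file.path(dir, "graph.graphml") else dir
  ig <- igraph::read_graph(path, format = "graphml")
  meta <- jsonlite::fromJSON(igraph::graph_attr(ig, "meta_json"))
  units <- as_unit_table(jsonlite::fromJSON(
    igraph::graph_attr(ig, "units_json")))
  if (meta$kind == "light") {
    formulas <- igraph::V(ig)$name
    series <- do.call(rbind, lapply(seq_along(formulas), function(i) {
      s <- jsonlite::fromJSON(igraph::V(ig)$series[i])
      data.frame(formula = formulas[i], snapshot = as.integer(s$snapshot),
                 normalized_intensity = as.numeric(s$normalized_intensity),
                 stringsAsFactors = FALSE)
    }))
    el <- igraph::as_data_frame(ig, what = "edges")
    records <- do.call(rbind, lapply(seq_len(nrow(el)), function(i) {
      r <- jsonlite::fromJSON(el$records[i])
      data.frame(educt = el$from[i], product = el$to[i],
                 transition = as.integer(r$transition), unit = r$unit,
                 predicted = as.logical(r$predicted),
                 weight = as.numeric(r$weight), stringsAsFactors = FALSE)
    }))
    lg <- structure(list(
      nodes = data.frame(formula = sort(formulas), stringsAsFactors = FALSE),
      series = .sort_df(series, c("formula", "snapshot")),
      edges = .sort_df(unique(records[, c("educt", "product")]),
                       c("educt", "product")),
      records = .sort_df(records, c("educt", "product", "transition",
                                    "unit")),
      units = units, has_predictions = isTRUE(meta$has_predictions),
      has_weights = isTRUE(meta$has_weights), transition_meta = NULL),
      class = "light_graph")
    return(.apply_meta(lg, meta))
  }
  vd <- igraph::as_data_frame(ig, what = "vertices")
  ed <- igraph::as_data_frame(ig, what = "edges")
  peaks <- data.frame(molecular_formula = vd$formula,
                      snapshot = as.integer(vd$snapshot),
                      normalized_intensity = vd$normalized_intensity,
                      stringsAsFactors = FALSE)
  .graph_from_parts(peaks, ed_split = split(ed, ed$type), units = units,
                    meta = meta)
}

# Assemble a temporal_graph from vertex peaks + edges split by type.
.graph_from_parts <- function(peaks, ed_split, units, meta) {
  elements <- as.character(meta$elements)
  parsed <- parse_formula(peaks$molecular_formula, elements)
  nodes <- data.frame(formula = parsed$formula,
                      parsed[, elements, drop = FALSE],
                      snapshot = peaks$snapshot,
                      normalized_intensity = peaks$normalized_intensity,
                      stringsAsFactors = FALSE, check.names = FALSE)
  nodes <- .sort_df(nodes, c("snapshot", "formula"))
  strip <- function(x) sub("@[0-9]+$", "", x)
  snap_of <- function(x) as.integer(sub("^.*@", "", x))
  mk_edges <- function(d, weighted) {
    if (is.null(d) || !nrow(d)) {
      out <- .empty_edges()
      if (weighted) out$weight <- numeric(0)
      return(out)
    }
    out <- data.frame(educt = strip(d$from), product = strip(d$to),
                      from_snapshot = snap_of(d$from),
                      to_snapshot = snap_of(d$to), unit = d$unit,
                      stringsAsFactors = FALSE)
    if (weighted) out$weight <- as.numeric(d$weight)
    .sort_df(out, c("from_snapshot", "educt", "product", "unit"))
  }
  sa <- ed_split[["SAME_AS"]]
  same_as <- if (is.null(sa) || !nrow(sa)) .empty_same_as() else .sort_df(
    data.frame(formula = strip(sa$from), from_snapshot = snap_of(sa$from),
               to_snapshot = snap_of(sa$to),
               intensity_trend = as.numeric(sa$intensity_trend),
               stringsAsFactors = FALSE), c("from_snapshot", "formula"))
  predicted <- NULL
  if (isTRUE(meta$has_predictions))
    predicted <- mk_edges(ed_split[["PREDICTED_TRANSFORMATION"]],
                          isTRUE(meta$has_weights))
  g <- structure(list(nodes = nodes, same_as = same_as,
                      potential = mk_edges(
                        ed_split[["POTENTIAL_TRANSFORMATION"]], FALSE),
                      predicted = predicted, units = units,
                      elements = elements, n_snapshots = NA_integer_,
                      omitted_fraction = NA_real_, margin = NULL,
                      policy = NULL, transition_meta = NULL),
                 class = "temporal_graph")
  .apply_meta(g, meta)
}

## ---- node/edge tables -------------------------------------------------

.export_tables <- function(g, dir, light) {
  meta <- .meta_list(g, if (light) "light" else "temporal")
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  utils::write.csv(.units_to_plain(g$units), file.path(dir, "units.csv"),
                   row.names = FALSE, quote = FALSE)
  if (light) {
    s <- g$series
    s$normalized_intensity <- .num_chr(s$normalized_intensity)
    utils::write.csv(s, file.path(dir, "series.csv"), row.names = FALSE)
    r <- g$records
    r$weight <- .num_chr(r$weight)
    utils::write.csv(r, file.path(dir, "records.csv"), row.names = FALSE)
    return(invisible(file.path(dir, c("meta.json", "units.csv",
                                      "series.csv", "records.csv"))))
  }
  nd <- g$nodes[, c("formula", "snapshot", "normalized_intensity")]
  nd$normalized_intensity <- .num_chr(nd$normalized_intensity)
  utils::write.csv(nd, file.path(dir, "nodes.csv"), row.names = FALSE)
  sa <- g$same_as
  ed1 <- data.frame(type = "SAME_AS", educt = sa$formula,
                    product = sa$formula, from_snapshot = sa$from_snapshot,
                    to_snapshot = sa$to_snapshot, unit = NA_character_,
                    intensity_trend = .num_chr(sa$intensity_trend),
                    weight = NA_character_, stringsAsFactors = FALSE)
  po <- g$potential
  ed2 <- data.frame(type = "POTENTIAL_TRANSFORMATION", educt = po$educt,
                    product = po$product, from_snapshot = po$from_snapshot,
                    to_snapshot = po$to_snapshot, unit = po$unit,
                    intensity_trend = NA_character_, weight = NA_character_,
                    stringsAsFactors = FALSE)
  ed <- rbind(ed1, ed2)
  if (!is.null(g$predicted)) {
    pr <- g$predicted
    ed <- rbind(ed, data.frame(
      type = "PREDICTED_TRANSFORMATION", educt = pr$educt,
      product = pr$product, from_snapshot = pr$from_snapshot,
      to_snapshot = pr$to_snapshot, unit = pr$unit,
      intensity_trend = NA_character_,
      weight = if ("weight" %in% names(pr)) .num_chr(pr$weight) else
        NA_character_,
      stringsAsFactors = FALSE))
  }
  utils::write.csv(ed, file.path(dir, "edges.csv"), row.names = FALSE)
  invisible(file.path(dir, c("meta.json", "units.csv", "nodes.csv",
                             "edges.csv")))
}

.import_tables <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "meta.json"))
  units <- load_units(file.path(dir, "units.csv"))
  if (meta$kind == "light") {
    s <- utils::read.csv(file.path(dir, "series.csv"),
                         stringsAsFactors = FALSE)
    r <- utils::read.csv(file.path(dir, "records.csv"),
                         stringsAsFactors = FALSE)
    lg <- structure(list(
      nodes = data.frame(formula = sort(unique(s$formula)),
                         stringsAsFactors = FALSE),
      series = .sort_df(data.frame(formula = s$formula,
                                   snapshot = as.integer(s$snapshot),
                                   normalized_intensity =
                                     as.numeric(s$normalized_intensity),
                                   stringsAsFactors = FALSE),
                        c("formula", "snapshot")),
      edges = .sort_df(unique(r[, c("educt", "product")]),
                       c("educt", "product")),
      records = .sort_df(data.frame(educt = r$educt, product = r$product,
                                    transition = as.integer(r$transition),
                                    unit = r$unit,
                                    predicted = as.logical(r$predicted),
                                    weight = as.numeric(r$weight),
                                    stringsAsFactors = FALSE),
                         c("educt", "product", "transition", "unit")),
      units = units, has_predictions = isTRUE(meta$has_predictions),
      has_weights = isTRUE(meta$has_weights), transition_meta = NULL),
      class = "light_graph")
    return(.apply_meta(lg, meta))
  }
  nd <- utils::read.csv(file.path(dir, "nodes.csv"),
                        stringsAsFactors = FALSE)
  ed <- utils::read.csv(file.path(dir, "edges.csv"),
                        stringsAsFactors = FALSE)
  peaks <- data.frame(molecular_formula = nd$formula,
                      snapshot = as.integer(nd$snapshot),
                      normalized_intensity =
                        as.numeric(nd$normalized_intensity),
                      stringsAsFactors = FALSE)
  ed$from <- paste0(ed$educt, "@", ed$from_snapshot)
  ed$to <- paste0(ed$product, "@", ed$to_snapshot)
  ed$weight <- suppressWarnings(as.numeric(ed$weight))
  ed$intensity_trend <- suppressWarnings(as.numeric(ed$intensity_trend))
  .graph_from_parts(peaks, split(ed, ed$type), units, meta)
}

## ---- cypher script ----------------------------------------------------

.export_cypher <- function(g, dir, light) {
  if (light)
    stop("cypher_script export is defined for temporal graphs; convert with from_light() first",
         call. = FALSE)
  path <- file.path(dir, "graph.cypher")
  meta <- .meta_list(g, "temporal")
  lines <- c(
    "// temporal molecular graph creation script",
    paste0("// meta ", as.character(jsonlite::toJSON(meta, auto_unbox = TRUE,
                                                     digits = NA,
                                                     na = "null"))),
    paste0("// units ", as.character(jsonlite::toJSON(
      .units_to_plain(g$units), digits = NA))),
    sprintf("CREATE (:Molecule {formula: \"%s\", snapshot: %d, normalized_intensity: %s});",
            g$nodes$formula, g$nodes$snapshot,
            .num_chr(g$nodes$normalized_intensity)))
  rel <- function(e_f, e_t, p_f, p_t, type, props) {
    sprintf("MATCH (a:Molecule {formula: \"%s\", snapshot: %d}), (b:Molecule {formula: \"%s\", snapshot: %d}) CREATE (a)-[:%s {%s}]->(b);",
            e_f, e_t, p_f, p_t, type, props)
  }
  sa <- g$same_as
  lines <- c(lines, rel(sa$formula, sa$from_snapshot, sa$formula,
                        sa$to_snapshot, "SAME_AS",
                        sprintf("intensity_trend: %s",
                                .num_chr(sa$intensity_trend))))
  po <- g$potential
  lines <- c(lines, rel(po$educt, po$from_snapshot, po$product,
                        po$to_snapshot, "POTENTIAL_TRANSFORMATION",
                        sprintf("transformation_unit: \"%s\"", po$unit)))
  if (!is.null(g$predicted)) {
    pr <- g$predicted
    props <- if ("weight" %in% names(pr))
      sprintf("transformation_unit: \"%s\", weight: %s", pr$unit,
              .num_chr(pr$weight))
    else sprintf("transformation_unit: \"%s\"", pr$unit)
    lines <- c(lines, rel(pr$educt, pr$from_snapshot, pr$product,
                          pr$to_snapshot, "PREDICTED_TRANSFORMATION", props))
  }
  writeLines(lines, path)
  invisible(path)
}

# Parses exactly the script format written by .export_cypher (documented
# contract; not a general Cypher parser).
.import_cypher <- function(dir) {
  path <- if (dir.exists(dir)) file.path(dir, "graph.cypher") else dir
  lines <- readLines(path)
  meta <- jsonlite::fromJSON(sub("^// meta ", "",
                                 grep("^// meta ", lines, value = TRUE)[1]))
  units <- as_unit_table(jsonlite::fromJSON(
    sub("^// units ", "", grep("^// units ", lines, value = TRUE)[1])))
  node_re <- "^CREATE \\(:Molecule \\{formula: \"([^\"]+)\", snapshot: ([0-9]+), normalized_intensity: ([^}]+)\\}\\);$"
  nl <- grep(node_re, lines, value = TRUE)
  peaks <- data.frame(molecular_formula = sub(node_re, "\\1", nl),
                      snapshot = as.integer(sub(node_re, "\\2", nl)),
                      normalized_intensity =
                        as.numeric(sub(node_re, "\\3", nl)),
                      stringsAsFactors = FALSE)
  edge_re <- "^MATCH \\(a:Molecule \\{formula: \"([^\"]+)\", snapshot: ([0-9]+)\\}\\), \\(b:Molecule \\{formula: \"([^\"]+)\", snapshot: ([0-9]+)\\}\\) CREATE \\(a\\)-\\[:([A-Z_]+) \\{(.*)\\}\\]->\\(b\\);$"
  el <- grep(edge_re, lines, value = TRUE)
  prop <- function(props, key, quoted) {
    re <- if (quoted) paste0(key, ": \"([^\"]+)\"") else
      paste0(key, ": ([^,}]+)")
    m <- regmatches(props, regexec(re, props))
    vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, "")
  }
  ed <- data.frame(from = paste0(sub(edge_re, "\\1", el), "@",
                                 sub(edge_re, "\\2", el)),
                   to = paste0(sub(edge_re, "\\3", el), "@",
                               sub(edge_re, "\\4", el)),
                   type = sub(edge_re, "\\5", el),
                   stringsAsFactors = FALSE)
  props <- sub(edge_re, "\\6", el)
  ed$unit <- prop(props, "transformation_unit", TRUE)
  ed$intensity_trend <- as.numeric(prop(props, "intensity_trend", FALSE))
  ed$weight <- as.numeric(prop(props, "weight", FALSE))
  .graph_from_parts(peaks, split(ed, ed$type), units, meta)
}

## ---- run report -------------------------------------------------------

#' Write a structured run report
#'
#' One JSON document per run, recording the package version, graph
#' dimensions, error margin, missing-node policy, clustering seed, and the
#' checksum of the transformation-unit table, plus any extra fields.
#'
#' @param path Output JSON path.
#' @param g A `temporal_graph`.
#' @param assignment Optional `cluster_assignment`.
#' @param extra Optional named list merged into the report.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(path, g, assignment = NULL, extra = list()) {
  stopifnot(inherits(g, "temporal_graph"))
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  utils::write.csv(.units_to_plain(g$units), tmp, row.names = FALSE)
  report <- c(list(
    package = "domgraph",
    version = as.character(utils::packageVersion("domgraph")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    n_snapshots = g$n_snapshots,
    n_nodes = nrow(g$nodes),
    n_same_as = nrow(g$same_as),
    n_potential = nrow(g$potential),
    n_predicted = if (is.null(g$predicted)) NA else nrow(g$predicted),
    omitted_fraction = g$omitted_fraction,
    margin = if (is.null(g$margin)) NA else g$margin,
    policy = if (is.null(g$policy)) NA else g$policy,
    units_md5 = unname(tools::md5sum(tmp)),
    lpa_seed = if (is.null(assignment)) NA else assignment$seed,
    lpa_converged = if (is.null(assignment)) NA else assignment$converged
  ), extra)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
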