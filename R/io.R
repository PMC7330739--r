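#' Read and write patient-year cohort tables
#'
#' Cohort CSV format: header `patient_id, <COND>_Y1, ..., <COND>_YT`,
#' values strictly 0/1. Reading validates binariness (errors name the
#' offending cell) and that every non-id column parses as a
#' condition-year label.
#'
#' @param path File path.
#' @return `read_cohort()`: a `cohort_table` data frame.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  cols <- setdiff(names(df), "patient_id")
  pl <- parse_node_label(cols)
  if (anyNA(pl$year))
    stop("column '", cols[which(is.na(pl$year))[1L]],
         "' does not parse as <CONDITION>_Y<k>")
  X <- cohort_matrix(df)
  out <- data.frame(
    patient_id = if ("patient_id" %in% names(df)) df$patient_id
                 else seq_len(nrow(df)),
    X, check.names = FALSE)
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' @rdname read_cohort
#' @param cohort A cohort table.
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort)
  if (!"patient_id" %in% names(df))
    df <- data.frame(patient_id = seq_len(nrow(df)), df,
                     check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write graphs as edge-list TSV or GraphML
#'
#' The edge-list format has columns `source`, `target`, `weight` (weight
#' optional, default 1), tab-separated, with `#`-prefixed comment lines
#' ignored; directedness and any nodes that happen to be isolated are
#' recorded in `#%` header comments so that round-trips are lossless.
#' GraphML files carry the same information in the standard XML schema.
#'
#' @param path File path.
#' @param format `"edgelist"` or `"graphml"`; default guessed from the
#'   file extension.
#' @return `read_graph()`: an [mcc_graph()].
#' @export
read_graph <- function(path, format = guess_format(path)) {
  switch(match.arg(format, c("edgelist", "graphml")),
         edgelist = read_edgelist(path),
         graphml = read_graphml(path))
}

#' @rdname read_graph
#' @param g An [mcc_graph()].
#' @export
write_graph <- function(g, path, format = guess_format(path)) {
  stopifnot(inherits(g, "mcc_graph"))
  switch(match.arg(format, c("edgelist", "graphml")),
         edgelist = write_edgelist(g, path),
         graphml = write_graphml(g, path))
  invisible(path)
}

guess_format <- function(path) {
  if (grepl("\\.graphml$", path, ignore.case = TRUE)) "graphml"
  else "edgelist"
}

read_edgelist <- function(path) {
  lines <- readLines(path)
  directed <- !any(grepl("^#%\\s*undirected", lines))
  iso <- character(0)
  iso_line <- grep("^#%\\s*isolated:", lines, value = TRUE)
  if (length(iso_line))
    iso <- strsplit(sub("^#%\\s*isolated:\\s*", "", iso_line[1L]),
                    "\\s+")[[1L]]
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) return(mcc_graph(iso, directed = directed))
  parts <- strsplit(lines, "\t")
  header <- tolower(trimws(parts[[1L]]))
  has_header <- identical(header[1:2], c("source", "target"))
  if (has_header) parts <- parts[-1L]
  src <- vapply(parts, `[`, character(1), 1L)
  tgt <- vapply(parts, `[`, character(1), 2L)
  w <- vapply(parts, function(p)
    if (length(p) >= 3L && nzchar(p[3L])) as.numeric(p[3L]) else 1.0,
    numeric(1))
  labels <- unique(c(src, tgt, iso))
  if (anyDuplicated(paste(src, tgt))) stop("duplicate edge in ", path)
  mcc_graph(labels, data.frame(from = src, to = tgt, weight = w),
            directed = directed)
}

write_edgelist <- function(g, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste0("#% ", if (g$directed) "directed" else "undirected"),
             con)
  deg <- tabulate(c(g$edges$from, g$edges$to), n_nodes(g))
  iso <- g$labels[deg == 0L]
  if (length(iso))
    writeLines(paste("#% isolated:", paste(iso, collapse = " ")), con)
  writeLines("source\ttarget\tweight", con)
  if (n_edges(g) > 0L)
    writeLines(sprintf("%s\t%s\t%s", g$labels[g$edges$from],
                       g$labels[g$edges$to],
                       format(g$edges$weight, digits = 15,
                              scientific = FALSE, trim = TRUE)), con)
}

read_graphml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(g = "http://graphml.graphdrawing.org/xmlns")
  graph <- xml2::xml_find_first(doc, ".//g:graph", ns)
  directed <- !identical(xml2::xml_attr(graph, "edgedefault"), "undirected")
  nodes <- xml2::xml_find_all(graph, ".//g:node", ns)
  labels <- xml2::xml_attr(nodes, "id")
  edges <- xml2::xml_find_all(graph, ".//g:edge", ns)
  if (length(edges) == 0L) return(mcc_graph(labels, directed = directed))
  src <- xml2::xml_attr(edges, "source")
  tgt <- xml2::xml_attr(edges, "target")
  w <- vapply(edges, function(e) {
    d <- xml2::xml_find_first(e, ".//g:data[@key='weight']", ns)
    if (inherits(d, "xml_missing")) 1.0 else as.numeric(xml2::xml_text(d))
  }, numeric(1))
  mcc_graph(labels, data.frame(from = src, to = tgt, weight = w),
            directed = directed)
}

write_graphml <- function(g, path) {
  esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", x))
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="weight" for="edge" attr.name="weight" attr.type="double"/>',
    sprintf('  <graph id="G" edgedefault="%s">',
            if (g$directed) "directed" else "undirected"),
    sprintf('    <node id="%s"/>', esc(g$labels)),
    if (n_edges(g) > 0L)
      sprintf(paste0('    <edge source="%s" target="%s">',
                     '<data key="weight">%s</data></edge>'),
              esc(g$labels[g$edges$from]), esc(g$labels[g$edges$to]),
              format(g$edges$weight, digits = 15, scientific = FALSE,
                     trim = TRUE)),
    "  </graph>", "</graphml>")
  writeLines(lines, path)
}

#' Read and write conditional probability tables as JSON
#'
#' Schema: a list of `{node, parents: [...], rows: [{config: [0/1...],
#' p1: number}, ...]}` objects, one per node.
#'
#' @param net An `mcc_bn`.
#' @param path File path.
#' @export
write_cpts <- function(net, path) {
  stopifnot(inherits(net, "mcc_bn"))
  payload <- lapply(net$cpts, function(cp) list(
    node = cp$node, parents = as.list(cp$parents),
    rows = lapply(seq_len(nrow(cp$table)), function(j) list(
      config = as.list(cp$table$config[[j]]), p1 = cp$table$p1[j]))))
  jsonlite::write_json(unname(payload), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_cpts
#' @param graph The [mcc_graph()] the tables belong to.
#' @export
read_cpts <- function(path, graph) {
  payload <- jsonlite::read_json(path)
  cpts <- lapply(payload, function(cp) {
    parents <- unlist(cp$parents) %||% character(0)
    cfg <- lapply(cp$rows, function(r) as.integer(unlist(r$config)))
    p1 <- vapply(cp$rows, function(r) as.numeric(r$p1), numeric(1))
    list(node = cp$node, parents = as.character(parents),
         table = data.frame(config = I(cfg), p1 = p1, n = NA_real_,
                            flagged = FALSE))
  })
  names(cpts) <- vapply(cpts, `[[`, character(1), "node")
  cpts <- cpts[graph$labels]
  structure(list(graph = graph, cpts = cpts, pseudo_count = NA_real_),
            class = "mcc_bn")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a summarization trace as JSON lines
#'
#' One JSON record per removed edge: `round`, `from`, `to` (labels),
#' `delta`, `relative`, `lambda2_after`.
#'
#' @param summary An `eagl_summary`.
#' @param path File path.
#' @export
write_trace <- function(summary, path) {
  stopifnot(inherits(summary, "eagl_summary"))
  tr <- summary$trace
  lines <- vapply(seq_len(nrow(tr)), function(i) {
    jsonlite::toJSON(list(round = tr$round[i], from = tr$from_label[i],
                          to = tr$to_label[i], delta = tr$delta[i],
                          relative = tr$relative[i],
                          lambda2_after = tr$lambda2_after[i]),
                     auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write an evaluation table as CSV
#'
#' Columns `condition`, `year`, `setting`, `fold`, `auc`.
#'
#' @param evaluation An `eagl_evaluation` (see [cross_validate()]) or a
#'   data frame in the same layout.
#' @param path File path.
#' @export
write_evaluation <- function(evaluation, path) {
  utils::write.csv(as.data.frame(evaluation), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
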