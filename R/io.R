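delim_for <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") "," else "\t"
}

read_table_auto <- function(path) {
  utils::read.table(path, sep = delim_for(path), header = TRUE,
                    check.names = FALSE, stringsAsFactors = FALSE,
                    na.strings = c("NA", ""), quote = "\"",
                    comment.char = "")
}

#' Read a feature-by-sample intensity table with metadata
#'
#' Delimited text (TSV or CSV, auto-detected from the file extension).
#' The intensity table has feature ids in the first column and sample ids
#' in the header; empty cells or `NA` encode missing measurements.
#' Metadata tables are joined by `feature_id` / `sample_id`.
#'
#' @param path intensity table path.
#' @param feature_meta_path,sample_meta_path metadata table paths; sample
#'   metadata must cover every column of the intensity table.
#' @return A validated [omics_dataset()].
#' @export
read_omics_table <- function(path, feature_meta_path, sample_meta_path) {
  # read.table mangles duplicated header names, so check the raw header
  hdr <- strsplit(readLines(path, n = 1), delim_for(path), fixed = TRUE)[[1]]
  if (anyDuplicated(hdr[-1]))
    stop("duplicate sample id in intensity table header: ",
         paste(unique(hdr[-1][duplicated(hdr[-1])]), collapse = ", "))
  tab <- read_table_auto(path)
  fid <- as.character(tab[[1]])
  x <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(x) <- "double"
  fm <- read_table_auto(feature_meta_path)
  sm <- read_table_auto(sample_meta_path)
  if (is.null(fm$feature_id) || is.null(sm$sample_id))
    stop("metadata tables need feature_id / sample_id columns")
  fm$feature_id <- as.character(fm$feature_id)
  sm$sample_id <- as.character(sm$sample_id)
  if (anyDuplicated(fid))
    stop("duplicate feature id in intensity table: ",
         paste(unique(fid[duplicated(fid)]), collapse = ", "))
  sid <- colnames(x)
  if (anyDuplicated(sid))
    stop("duplicate sample id in intensity table header: ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "))
  mi <- match(fid, fm$feature_id)
  if (anyNA(mi))
    stop("feature ids missing from feature metadata: ",
         paste(head(fid[is.na(mi)], 5), collapse = ", "))
  fm <- fm[mi, , drop = FALSE]
  mi <- match(sid, sm$sample_id)
  if (anyNA(mi))
    stop("unknown sample id (absent from sample metadata): ",
         paste(head(sid[is.na(mi)], 5), collapse = ", "))
  sm <- sm[mi, , drop = FALSE]
  if (!is.null(sm$injection_order) &&
      any(sm$injection_order != round(sm$injection_order)))
    stop("non-integer injection order in sample metadata")
  sm$injection_order <- as.integer(sm$injection_order)
  if (!is.null(fm$is_internal_standard))
    fm$is_internal_standard <- as.logical(fm$is_internal_standard)
  fm$feature_id <- fid
  omics_dataset(x, fm, sm)
}

#' Write an OmicsDataset as delimited text
#'
#' Inverse of [read_omics_table()]; round-trips a dataset up to float
#' formatting (15 significant digits are written).
#'
#' @param ds an `omics_dataset`.
#' @param path,feature_meta_path,sample_meta_path output paths; the
#'   extension selects TSV (default) or CSV.
#' @return `ds`, invisibly.
#' @export
write_omics_table <- function(ds, path, feature_meta_path, sample_meta_path) {
  validate_omics_dataset(ds)
  tab <- data.frame(feature_id = ds$feature_meta$feature_id,
                    signif(ds$intensities, 15),
                    check.names = FALSE, stringsAsFactors = FALSE)
  for (p in list(list(tab, path),
                 list(ds$feature_meta, feature_meta_path),
                 list(ds$sample_meta, sample_meta_path)))
    utils::write.table(p[[1]], p[[2]], sep = delim_for(p[[2]]),
                       row.names = FALSE, quote = FALSE, na = "NA")
  invisible(ds)
}

#' Read / write knowledge-graph edge lists
#'
#' Plain TSV with columns `from`, `to`, `source` (one undirected edge per
#' row).
#'
#' @param kg a [knowledge_graph()].
#' @param path file path.
#' @return `read_knowledge_graph` returns a `knowledge_graph`.
#' @export
write_knowledge_graph <- function(kg, path) {
  utils::write.table(as.data.frame(unclass(kg), stringsAsFactors = FALSE),
                     path, sep = delim_for(path), row.names = FALSE,
                     quote = FALSE)
  invisible(kg)
}

#' @rdname write_knowledge_graph
#' @export
read_knowledge_graph <- function(path) {
  tab <- read_table_auto(path)
  knowledge_graph(tab$from, tab$to, if (is.null(tab$source)) "file" else tab$source)
}

#' Serialize a consensus network
#'
#' GraphML carries the node attribute `layer` and edge attributes
#' `strength_raw` and `strength_modified`; SIF uses the interaction label
#' `assoc`; TSV writes one edge per row with both strengths.
#'
#' @param network a `consensus_network` (see [consensus_network()]).
#' @param path output path.
#' @param format one of `"graphml"`, `"sif"`, `"tsv"`.
#' @return `network`, invisibly.
#' @export
write_network <- function(network, path, format = c("graphml", "sif", "tsv")) {
  format <- match.arg(format)
  nodes <- network$nodes; edges <- network$edges
  if (format == "sif") {
    lines <- if (nrow(edges)) paste(edges$from, "assoc", edges$to) else character()
    iso <- setdiff(nodes$feature_id, c(edges$from, edges$to))
    writeLines(c(lines, iso), path)
  } else if (format == "tsv") {
    utils::write.table(edges, path, sep = "\t", row.names = FALSE, quote = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(
      edges[, c("from", "to", "strength_raw", "strength_modified")],
      directed = FALSE, vertices = nodes[, c("feature_id", "layer")])
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(network)
}

#' Read a GraphML consensus network written by [write_network()]
#'
#' @param path GraphML path.
#' @return A `consensus_network` (threshold is not serialized by GraphML
#'   and is restored as `NA`).
#' @export
read_network <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- data.frame(feature_id = igraph::vertex_attr(g, "name"),
                      layer = igraph::vertex_attr(g, "layer"),
                      stringsAsFactors = FALSE)
  el <- igraph::as_edgelist(g)
  edges <- data.frame(from = pmin(el[, 1], el[, 2]),
                      to = pmax(el[, 1], el[, 2]),
                      strength_raw = igraph::edge_attr(g, "strength_raw"),
                      strength_modified = igraph::edge_attr(g, "strength_modified"),
                      stringsAsFactors = FALSE)
  if (!nrow(el))
    edges <- data.frame(from = character(), to = character(),
                        strength_raw = numeric(), strength_modified = numeric(),
                        stringsAsFactors = FALSE)
  consensus_network_object(nodes, edges, threshold = NA_real_)
}

#' Differential summary statistics for 109 CSF molecules
#'
#' The bundled example table of published matched case-control
#' differential results for preoperative cerebrospinal fluid in an
#' orthopedic-surgery delirium cohort: 51 metabolites, 26 lipids and 32
#' proteins significant at nominal p < 0.05 in at least one of the three
#' paired tests, with the lowest nominal p-value, its
#' Benjamini-Hochberg-adjusted value, and the signed Tukey-biweight fold
#' change (negative = down in delirium).
#'
#' @return A data.frame of `differential_record` rows (see
#'   [differential_records()]).
#' @export
delirium_csf_difftable <- function() {
  path <- system.file("extdata", "delirium_csf_difftable.tsv",
                      package = "pairomics", mustWork = TRUE)
  tab <- read_table_auto(path)
  # every bundled row is published as significant; one lipid's p prints
  # as 0.050 at table precision, so the flag is carried, not re-derived
  differential_records(tab$feature_id, tab$layer, min_p = tab$p_value,
                       bh_min = tab$bh_p, tfc = tab$tfc, significant = TRUE)
}
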