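#' Construct an OmicsDataset
#'
#' The container every pipeline stage consumes and returns: a
#' feature-by-sample intensity matrix with feature and sample metadata.
#' Missing measurements are `NA` (never 0: zeros in input are measured
#' values, absence is missingness). One acquisition batch per dataset.
#'
#' @param intensities numeric matrix, rows = features, columns = samples;
#'   non-negative or `NA`.
#' @param feature_meta data.frame with columns `feature_id` (unique),
#'   `layer` (one of `"metabolite"`, `"lipid"`, `"protein"`),
#'   `is_internal_standard` (logical) and `consolidation_key` (character,
#'   `""` when the row is not a split lipid line). Missing columns are
#'   filled with defaults.
#' @param sample_meta data.frame with columns `sample_id` (unique),
#'   `role` (`"study"` or `"pooled_qc"`), `group` (`"DEL"`, `"CNT"` or
#'   `"none"`), `pair_id` (character, `""` if unpaired) and
#'   `injection_order` (positive integer, unique).
#' @return A validated object of class `omics_dataset`.
#' @export
omics_dataset <- function(intensities, feature_meta, sample_meta) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  feature_meta <- as.data.frame(feature_meta, stringsAsFactors = FALSE)
  sample_meta <- as.data.frame(sample_meta, stringsAsFactors = FALSE)
  if (is.null(feature_meta$layer)) feature_meta$layer <- "metabolite"
  if (is.null(feature_meta$is_internal_standard))
    feature_meta$is_internal_standard <- FALSE
  if (is.null(feature_meta$consolidation_key))
    feature_meta$consolidation_key <- ""
  if (is.null(sample_meta$group)) sample_meta$group <- "none"
  if (is.null(sample_meta$pair_id)) sample_meta$pair_id <- ""
  feature_meta$consolidation_key[is.na(feature_meta$consolidation_key)] <- ""
  sample_meta$pair_id[is.na(sample_meta$pair_id)] <- ""
  if (nrow(feature_meta) != nrow(intensities) ||
      nrow(sample_meta) != ncol(intensities))
    stop("metadata dimensions do not match the intensity matrix")
  rownames(intensities) <- feature_meta$feature_id
  colnames(intensities) <- sample_meta$sample_id
  rownames(feature_meta) <- NULL
  rownames(sample_meta) <- NULL
  ds <- structure(list(intensities = intensities,
                       feature_meta = feature_meta,
                       sample_meta = sample_meta),
                  class = "omics_dataset")
  validate_omics_dataset(ds)
  ds
}

#' Validate an OmicsDataset
#'
#' Checks the structural invariants: unique feature and sample ids,
#' pooled-QC samples carry no group or pair, injection orders unique,
#' intensities non-negative. Called by every pipeline stage.
#'
#' @param ds an `omics_dataset`.
#' @return `ds`, invisibly; stops with a contextual message on violation.
#' @export
validate_omics_dataset <- function(ds) {
  stopifnot(inherits(ds, "omics_dataset"))
  fm <- ds$feature_meta; sm <- ds$sample_meta; x <- ds$intensities
  if (nrow(fm) != nrow(x) || nrow(sm) != ncol(x))
    stop("metadata dimensions do not match the intensity matrix")
  dup <- fm$feature_id[duplicated(fm$feature_id)]
  if (length(dup)) stop("duplicate feature id: ", paste(unique(dup), collapse = ", "))
  dup <- sm$sample_id[duplicated(sm$sample_id)]
  if (length(dup)) stop("duplicate sample id: ", paste(unique(dup), collapse = ", "))
  if (!all(fm$layer %in% c("metabolite", "lipid", "protein")))
    stop("layer must be one of metabolite/lipid/protein")
  if (!all(sm$role %in% c("study", "pooled_qc")))
    stop("sample role must be study or pooled_qc")
  if (!all(sm$group %in% c("DEL", "CNT", "none")))
    stop("sample group must be DEL, CNT or none")
  bad <- sm$role == "pooled_qc" & (sm$group != "none" | sm$pair_id != "")
  if (any(bad))
    stop("pooled-QC sample with group/pair assignment: ",
         paste(sm$sample_id[bad], collapse = ", "))
  io <- sm$injection_order
  if (any(is.na(io)) || any(io != as.integer(io)) || any(io < 1))
    stop("injection_order must be positive integers")
  if (anyDuplicated(io))
    stop("injection_order values must be unique within the acquisition batch")
  neg <- which(!is.na(x) & x < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop("negative intensity at feature ", rownames(x)[neg[1, 1]],
         ", sample ", colnames(x)[neg[1, 2]])
  invisible(ds)
}

#' @export
print.omics_dataset <- function(x, ...) {
  sm <- x$sample_meta
  cat(sprintf("<omics_dataset> %d features x %d samples (%d study, %d pooled QC)\n",
              nrow(x$intensities), ncol(x$intensities),
              sum(sm$role == "study"), sum(sm$role == "pooled_qc")))
  cat("  layers:", paste(sprintf("%s=%d", names(table(x$feature_meta$layer)),
                                 table(x$feature_meta$layer)), collapse = " "),
      "\n")
  cat(sprintf("  missing: %.1f%%  internal standards: %d\n",
              100 * mean(is.na(x$intensities)),
              sum(x$feature_meta$is_internal_standard)))
  invisible(x)
}

#' Subset a dataset by features and/or samples
#'
#' @param ds an [omics_dataset()].
#' @param features,samples character ids, integer indices or logical
#'   vectors; `NULL` keeps everything.
#' @return the subset `omics_dataset`.
#' @export
subset_dataset <- function(ds, features = NULL, samples = NULL) {
  fi <- seq_len(nrow(ds$intensities)); si <- seq_len(ncol(ds$intensities))
  if (!is.null(features)) {
    fi <- if (is.character(features)) match(features, ds$feature_meta$feature_id)
          else which(rep_len(TRUE, nrow(ds$intensities)))[features]
    if (anyNA(fi)) stop("unknown feature id")
  }
  if (!is.null(samples)) {
    si <- if (is.character(samples)) match(samples, ds$sample_meta$sample_id)
          else which(rep_len(TRUE, ncol(ds$intensities)))[samples]
    if (anyNA(si)) stop("unknown sample id")
  }
  omics_dataset(ds$intensities[fi, si, drop = FALSE],
                ds$feature_meta[fi, , drop = FALSE],
                ds$sample_meta[si, , drop = FALSE])
}

#' Construct a matched case-control design
#'
#' An ordered list of (case, control) sample-id pairs. Cases must carry
#' group `DEL` and controls group `CNT` in any dataset the design is
#' applied to; each sample id may appear in at most one pair.
#'
#' @param case character vector of case (DEL) sample ids.
#' @param control character vector of control (CNT) sample ids, same length.
#' @return Object of class `matched_design` (a data.frame with columns
#'   `case` and `control`).
#' @export
matched_design <- function(case, control) {
  case <- as.character(case); control <- as.character(control)
  if (length(case) != length(control))
    stop("case and control id vectors must have equal length")
  ids <- c(case, control)
  if (anyDuplicated(ids))
    stop("sample id in more than one pair: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  structure(data.frame(case = case, control = control,
                       stringsAsFactors = FALSE),
            class = c("matched_design", "data.frame"))
}

# Check a design against a dataset; returns sample-column indices.
design_indices <- function(ds, design) {
  sm <- ds$sample_meta
  ci <- match(design$case, sm$sample_id)
  ki <- match(design$control, sm$sample_id)
  if (anyNA(ci) || anyNA(ki))
    stop("design references samples absent from the dataset: ",
         paste(c(design$case[is.na(ci)], design$control[is.na(ki)]), collapse = ", "))
  if (!all(sm$group[ci] == "DEL")) stop("case samples must have group DEL")
  if (!all(sm$group[ki] == "CNT")) stop("control samples must have group CNT")
  list(case = ci, control = ki)
}

#' Construct a knowledge graph
#'
#' A set of unordered molecule-molecule edges from external curation
#' (e.g. pathway databases), used to boost bootstrap edge strengths
#' during network integration. Self-loops are rejected; edge order and
#' duplicate orientation are normalized away.
#'
#' @param from,to character vectors of feature ids.
#' @param source character vector (recycled) tagging the provenance of
#'   each edge.
#' @return Object of class `knowledge_graph` (data.frame `from`, `to`,
#'   `source` with `from < to` lexicographically).
#' @export
knowledge_graph <- function(from = character(), to = character(),
                            source = "curated") {
  from <- as.character(from); to <- as.character(to)
  if (length(from) != length(to)) stop("from/to length mismatch")
  if (any(from == to)) stop("self-loops are not allowed in a knowledge graph")
  a <- pmin(from, to); b <- pmax(from, to)
  source <- rep_len(as.character(source), length(a))
  keep <- !duplicated(paste0(a, "\r", b))
  structure(data.frame(from = a[keep], to = b[keep], source = source[keep],
                       stringsAsFactors = FALSE),
            class = c("knowledge_graph", "data.frame"))
}

# Canonical undirected edge keys.
edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
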