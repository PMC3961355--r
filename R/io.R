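#' Read a probe-by-sample expression table
#'
#' Reads a delimited text matrix whose column names encode condition,
#' timepoint and replicate, e.g. `LD_0_1` for condition LD, hour 0,
#' replicate 1 under the default `"condition_time_rep"` layout. The first
#' column must be `probe_id`; an optional `gene_id` column may follow.
#' Every condition must supply the full timepoint-by-replicate grid.
#'
#' @param path File path; comma-delimited when the extension is `.csv`,
#'   tab-delimited otherwise (override with `sep`).
#' @param layout Column-naming convention; only `"condition_time_rep"`
#'   (fields joined by `_`) is currently defined.
#' @param sep Field separator; `NULL` = infer from the extension.
#' @return An [expression_dataset()].
#' @export
read_expression_table <- function(path, layout = "condition_time_rep",
                                  sep = NULL) {
  layout <- match.arg(layout)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, fill = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  if (names(df)[1L] != "probe_id")
    stop("first column must be 'probe_id', found '", names(df)[1L], "'")
  probe_ids <- as.character(df[[1L]])
  if (anyDuplicated(probe_ids))
    stop("duplicate probe IDs: ",
         paste(unique(probe_ids[duplicated(probe_ids)]), collapse = ", "))
  gene_ids <- NULL
  first_val <- 2L
  if (ncol(df) >= 2L && names(df)[2L] == "gene_id") {
    gene_ids <- as.character(df[[2L]])
    first_val <- 3L
  }
  val_cols <- names(df)[first_val:ncol(df)]
  parts <- strsplit(val_cols, "_", fixed = TRUE)
  bad <- lengths(parts) != 3L
  if (any(bad))
    stop("column(s) not matching <condition>_<time>_<replicate>: ",
         paste(val_cols[bad], collapse = ", "))
  meta <- data.frame(col = val_cols,
                     condition = vapply(parts, `[`, "", 1L),
                     time = as.numeric(vapply(parts, `[`, "", 2L)),
                     rep = as.integer(vapply(parts, `[`, "", 3L)),
                     stringsAsFactors = FALSE)
  if (anyNA(meta$time) || anyNA(meta$rep))
    stop("non-numeric time or replicate field in column names")
  assemble_dataset(df[val_cols], probe_ids, gene_ids, meta)
}

# Build per-condition probes x time x rep arrays from long column metadata;
# requires a complete, unduplicated grid per condition.
assemble_dataset <- function(valdf, probe_ids, gene_ids, meta) {
  tps <- sort(unique(meta$time))
  reps <- sort(unique(meta$rep))
  conds <- unique(meta$condition)
  values <- list()
  for (cn in conds) {
    sub <- meta[meta$condition == cn, ]
    want <- expand.grid(time = tps, rep = reps)
    key <- paste(sub$time, sub$rep)
    if (anyDuplicated(key))
      stop("condition '", cn, "' has duplicated sample columns: ",
           paste(sub$col[duplicated(key)], collapse = ", "))
    miss <- !(paste(want$time, want$rep) %in% key)
    if (any(miss))
      stop("condition '", cn, "' is missing sample(s): ",
           paste(paste0(cn, "_", want$time[miss], "_", want$rep[miss]),
                 collapse = ", "))
    a <- array(NA_real_, dim = c(length(probe_ids), length(tps),
                                 length(reps)))
    for (j in seq_len(nrow(sub))) {
      ti <- match(sub$time[j], tps)
      ri <- match(sub$rep[j], reps)
      a[, ti, ri] <- as.numeric(valdf[[sub$col[j]]])
    }
    values[[cn]] <- a
  }
  expression_dataset(values, probe_ids = probe_ids, timepoints = tps,
                     gene_ids = gene_ids)
}

#' Write an expression dataset as a delimited table
#'
#' Inverse of [read_expression_table()]: one row per probe, columns named
#' `<condition>_<time>_<replicate>`.
#'
#' @param dataset An `expr_dataset`.
#' @param path Output path (`.csv` = comma-delimited, else tab).
#' @export
write_expression_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "expr_dataset"))
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  out <- data.frame(probe_id = dataset$probe_ids, stringsAsFactors = FALSE)
  if (!is.null(dataset$gene_ids)) out$gene_id <- dataset$gene_ids
  for (cn in dataset$conditions) {
    v <- dataset$values[[cn]]
    for (r in seq_len(dim(v)[3L]))
      for (ti in seq_along(dataset$timepoints))
        out[[paste(cn, dataset$timepoints[ti], r, sep = "_")]] <- v[, ti, r]
  }
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GEO series-matrix file with an explicit sample mapping
#'
#' Parses the series-matrix text dialect (metadata lines prefixed `!`, the
#' expression table between `!series_matrix_table_begin` and
#' `!series_matrix_table_end`). GEO metadata describes samples in free
#' text, so the assignment of each GSM to (condition, timepoint,
#' replicate) must be supplied explicitly. Samples present in the file but
#' absent from the mapping are dropped with a warning; a mapped sample
#' missing from the file is an error.
#'
#' @param path Series-matrix file path.
#' @param sample_map Data frame (or path to a TSV) with columns
#'   `sample_id`, `condition`, `timepoint`, `replicate`.
#' @return An [expression_dataset()].
#' @export
read_series_matrix <- function(path, sample_map) {
  if (is.character(sample_map))
    sample_map <- utils::read.table(sample_map, header = TRUE, sep = "\t",
                                    stringsAsFactors = FALSE)
  need <- c("sample_id", "condition", "timepoint", "replicate")
  if (!all(need %in% names(sample_map)))
    stop("sample map needs columns: ", paste(need, collapse = ", "))
  lines <- readLines(path)
  b <- grep("^!series_matrix_table_begin", lines)
  e <- grep("^!series_matrix_table_end", lines)
  if (length(b) != 1L || length(e) != 1L || e <= b + 1L)
    stop("series-matrix table delimiters not found in ", path)
  tab <- utils::read.table(text = lines[(b + 1L):(e - 1L)], header = TRUE,
                           sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "")
  samples <- names(tab)[-1L]
  absent <- setdiff(sample_map$sample_id, samples)
  if (length(absent))
    stop("mapped sample(s) absent from the file: ",
         paste(absent, collapse = ", "))
  extra <- setdiff(samples, sample_map$sample_id)
  if (length(extra))
    warning("dropping ", length(extra), " unmapped sample(s): ",
            paste(extra, collapse = ", "))
  probe_ids <- as.character(tab[[1L]])
  if (anyDuplicated(probe_ids))
    stop("duplicate probe IDs in series matrix")
  meta <- data.frame(col = as.character(sample_map$sample_id),
                     condition = as.character(sample_map$condition),
                     time = as.numeric(sample_map$timepoint),
                     rep = as.integer(sample_map$replicate),
                     stringsAsFactors = FALSE)
  assemble_dataset(tab[meta$col], probe_ids, NULL, meta)
}

#' Write the per-probe node table
#'
#' One row per analysed probe: degrees in both conditions, connectivity
#' difference, and the key-probe selection flag (`neg`, `pos` or empty).
#'
#' @param diff A `"conn_diff"` table (with selection columns from
#'   [select_key_probes()], optional).
#' @param path Output TSV path.
#' @param gene_ids Optional named character vector mapping probe IDs to
#'   gene symbols for the `gene_id` column.
#' @export
write_node_table <- function(diff, path, gene_ids = NULL) {
  stopifnot(inherits(diff, "conn_diff"))
  out <- as.data.frame(diff)
  out <- cbind(out[1L],
               gene_id = if (!is.null(gene_ids))
                 unname(gene_ids[out$probe_id]) else NA_character_,
               out[-1L])
  if (!is.null(out$selected_neg)) {
    out$selected <- ifelse(out$selected_neg, "neg",
                           ifelse(out$selected_pos, "pos", ""))
    out$selected_neg <- out$selected_pos <- NULL
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read back a node table written by [write_node_table()]
#'
#' @param path TSV path.
#' @return Data frame with the node-table columns.
#' @export
read_node_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, na.strings = "",
                    colClasses = NA, check.names = FALSE)
}

#' Write a network's edge list
#'
#' One row per undirected edge (`i < j` only, never both orientations),
#' with the underlying correlation and the condition label.
#'
#' @param network A thresholded `"corr_network"`.
#' @param path Output TSV path.
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "corr_network"))
  if (is.null(network$L)) stop("apply threshold_adjacency() first")
  idx <- which(network$L == 1L & upper.tri(network$L), arr.ind = TRUE)
  out <- data.frame(probe_i = network$probe_ids[idx[, 1L]],
                    probe_j = network$probe_ids[idx[, 2L]],
                    r = network$R[idx],
                    condition = rep(if (is.null(network$condition)) NA
                                    else network$condition, nrow(idx)),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a network as GraphML
#'
#' @param network A thresholded `"corr_network"`.
#' @param path Output `.graphml` path.
#' @export
write_graphml <- function(network, path) {
  stopifnot(inherits(network, "corr_network"))
  if (is.null(network$L)) stop("apply threshold_adjacency() first")
  g <- igraph::graph_from_adjacency_matrix(network$L, mode = "undirected")
  igraph::V(g)$degree <- as.numeric(network$degrees)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read a probe-to-gene mapping table
#'
#' @param path TSV with columns `probe_id` and `gene_id`; a blank `gene_id`
#'   marks an unannotated probe.
#' @return Data frame usable as `gene_map` in [collapse_to_genes()].
#' @export
read_gene_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = "")
  if (!all(c("probe_id", "gene_id") %in% names(df)))
    stop("gene map needs columns probe_id, gene_id")
  df
}
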