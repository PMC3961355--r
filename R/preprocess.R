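#' Average biological replicates
#'
#' Collapses the replicate axis of each condition to its arithmetic mean,
#' yielding one profile per probe per condition (24 mean profiles per probe
#' pair of conditions in a 12-timepoint two-condition design).
#'
#' @param dataset An [expression_dataset()].
#' @return An `expr_dataset` with a single (averaged) replicate per condition.
#' @export
average_replicates <- function(dataset) {
  stopifnot(inherits(dataset, "expr_dataset"))
  vals <- lapply(dataset$values, function(v) {
    m <- apply(v, c(1L, 2L), mean)
    array(m, dim = c(dim(m), 1L))
  })
  expression_dataset(vals, probe_ids = dataset$probe_ids,
                     timepoints = dataset$timepoints,
                     gene_ids = dataset$gene_ids)
}

#' Collapse probes to genes
#'
#' Removes probes with no gene annotation and replaces multiple probes
#' mapped to one gene by a single record whose values are the arithmetic
#' mean of the member probes, per condition and timepoint. Record IDs of the
#' result are the gene symbols. Replicates must already be averaged.
#'
#' @param dataset An `expr_dataset` with one replicate.
#' @param gene_map Optional probe-to-gene map: a data frame with columns
#'   `probe_id` and `gene_id` (blank or `NA` `gene_id` = unmapped), or a
#'   named character vector. Defaults to the dataset's own `gene_ids`.
#' @return An `expr_dataset` keyed by gene, with attributes `n_removed`
#'   (probes dropped for lack of annotation) and `n_merged` (probes absorbed
#'   into multi-probe genes).
#' @export
collapse_to_genes <- function(dataset, gene_map = NULL) {
  stopifnot(inherits(dataset, "expr_dataset"))
  if (n_replicates(dataset) != 1L)
    stop("average replicates before collapsing to genes")
  genes <- resolve_gene_map(dataset, gene_map)
  mapped <- !is.na(genes)
  n_removed <- sum(!mapped)
  if (!any(mapped)) stop("no probe has a gene annotation; nothing to collapse")
  glev <- unique(genes[mapped])
  grp <- match(genes, glev)               # NA for unmapped
  vals <- lapply(dataset$values, function(v) {
    m <- v[, , 1L, drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, nrow = dim(v)[1L])
    out <- rowsum(m[mapped, , drop = FALSE], grp[mapped], reorder = FALSE)
    out <- out / as.vector(table(grp[mapped])[rownames(out)])
    array(out, dim = c(nrow(out), ncol(out), 1L))
  })
  res <- expression_dataset(vals, probe_ids = glev,
                            timepoints = dataset$timepoints,
                            gene_ids = glev)
  attr(res, "n_removed") <- n_removed
  attr(res, "n_merged") <- sum(mapped) - length(glev)
  message("gene collapsing: ", length(dataset$probe_ids), " probes -> ",
          length(glev), " gene records (", n_removed, " unmapped removed, ",
          attr(res, "n_merged"), " merged)")
  res
}

resolve_gene_map <- function(dataset, gene_map) {
  if (is.null(gene_map)) {
    if (is.null(dataset$gene_ids))
      stop("no gene annotation: supply 'gene_map' or a dataset with gene_ids")
    return(dataset$gene_ids)
  }
  if (is.data.frame(gene_map)) {
    if (!all(c("probe_id", "gene_id") %in% names(gene_map)))
      stop("'gene_map' data frame needs columns probe_id, gene_id")
    gene_map <- stats::setNames(as.character(gene_map$gene_id),
                                as.character(gene_map$probe_id))
  }
  g <- unname(gene_map[dataset$probe_ids])
  g[!is.na(g) & g == ""] <- NA_character_
  g
}

#' Min--max normalize one expression record to [-1, 1]
#'
#' Maps a record `x` to `x' = 2 (x - x_min) / (x_max - x_min) - 1`, so its
#' minimum becomes -1 and its maximum +1 exactly. A constant record
#' (`x_min == x_max`) is mapped to all zeros, the midpoint of the target
#' interval, which makes flat probes inert in later correlation analysis.
#'
#' @param values Finite numeric vector of length >= 2.
#' @return Numeric vector in `[-1, 1]` with attributes `x_min` and `x_max`
#'   (the pre-normalization extremes, kept for audit).
#' @examples
#' normalize_record(c(0, 5, 10))   # -1, 0, 1
#' @export
normalize_record <- function(values) {
  if (length(values) < 2L) stop("record must have length >= 2")
  if (!all(is.finite(values))) stop("record contains non-finite values")
  lo <- min(values); hi <- max(values)
  out <- if (lo == hi) rep(0, length(values))
         else 2 * (values - lo) / (hi - lo) - 1
  structure(out, x_min = lo, x_max = hi)
}

#' Normalize every record of a dataset to [-1, 1]
#'
#' Applies [normalize_record()] to each probe's profile in each condition,
#' producing the per-condition "working database" of normalized profiles.
#' Replicates must already be averaged.
#'
#' @param dataset An `expr_dataset` with one replicate.
#' @return An `expr_dataset` whose values lie in `[-1, 1]`, with attribute
#'   `norm_range`: per condition, a two-column matrix of the original
#'   `x_min`/`x_max` per probe.
#' @export
normalize_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "expr_dataset"))
  if (n_replicates(dataset) != 1L)
    stop("average replicates before normalizing")
  ranges <- list()
  vals <- dataset$values
  for (cn in dataset$conditions) {
    m <- vals[[cn]][, , 1L, drop = FALSE]
    lo <- apply(m, 1L, min); hi <- apply(m, 1L, max)
    rng <- hi - lo
    const <- rng == 0
    scaled <- 2 * (m[, , 1L] - lo) / ifelse(const, 1, rng) - 1
    scaled[const, ] <- 0
    vals[[cn]] <- array(scaled, dim = dim(m))
    ranges[[cn]] <- cbind(x_min = lo, x_max = hi)
  }
  res <- expression_dataset(vals, probe_ids = dataset$probe_ids,
                            timepoints = dataset$timepoints,
                            gene_ids = dataset$gene_ids)
  attr(res, "norm_range") <- ranges
  attr(res, "normalized") <- TRUE
  res
}

#' Extract one condition's profile matrix
#'
#' @param dataset An `expr_dataset` with one replicate.
#' @param condition Condition name.
#' @return Numeric `probes x timepoints` matrix with probe IDs as row names.
#' @export
profile_matrix <- function(dataset, condition) {
  stopifnot(inherits(dataset, "expr_dataset"))
  if (!condition %in% dataset$conditions)
    stop("unknown condition '", condition, "'")
  if (n_replicates(dataset) != 1L)
    stop("average replicates first")
  m <- dataset$values[[condition]][, , 1L, drop = TRUE]
  if (is.null(dim(m)))
    m <- matrix(m, nrow = length(dataset$probe_ids),
                ncol = length(dataset$timepoints))
  rownames(m) <- dataset$probe_ids
  m
}
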