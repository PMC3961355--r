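#' Construct a two-condition time-course expression dataset
#'
#' Container for probe-by-timepoint-by-replicate expression intensities
#' measured under two (or more) experimental conditions, e.g. an alternating
#' light--dark cycle ("LD") versus constant darkness ("DD"). All downstream
#' steps (replicate averaging, gene collapsing, min--max normalization,
#' distance screening, wavelet transform, correlation networks) operate on
#' this class.
#'
#' @param values Named list, one element per condition, each a numeric
#'   `probes x timepoints x replicates` array (a `probes x timepoints` matrix
#'   is promoted to a single-replicate array). All conditions must share the
#'   same probe set and order, timepoint count and replicate count.
#' @param probe_ids Character vector of unique probe identifiers, one per row.
#' @param timepoints Optional numeric vector of sampling times in hours
#'   (defaults to `0, 4, 8, ...`, the 4-hour grid of a two-day circadian
#'   time course).
#' @param gene_ids Optional character vector of gene symbols parallel to
#'   `probe_ids`; `NA` marks a probe with no gene annotation.
#' @param na_policy How to treat missing values at construction: `"reject"`
#'   (default, any `NA`/`NaN` is an error) or `"drop"` (probes containing a
#'   missing value in any condition are removed, with a message giving the
#'   count).
#'
#' @return An object of class `"expr_dataset"`: a list with elements
#'   `values`, `probe_ids`, `gene_ids`, `timepoints`, `conditions`.
#' @examples
#' x <- matrix(rnorm(8), 4, 2, dimnames = list(paste0("p", 1:4), NULL))
#' ds <- expression_dataset(list(LD = x, DD = x + 1), probe_ids = rownames(x),
#'                          timepoints = c(0, 4))
#' ds
#' @export
expression_dataset <- function(values, probe_ids, timepoints = NULL,
                               gene_ids = NULL,
                               na_policy = c("reject", "drop")) {
  na_policy <- match.arg(na_policy)
  if (!is.list(values) || is.null(names(values)) || any(names(values) == ""))
    stop("'values' must be a named list with one element per condition")
  values <- lapply(values, function(v) {
    if (is.matrix(v)) v <- array(v, dim = c(dim(v), 1L))
    if (!is.array(v) || length(dim(v)) != 3L)
      stop("each condition's values must be a matrix or 3-d array")
    storage.mode(v) <- "double"
    v
  })
  probe_ids <- as.character(probe_ids)
  if (anyDuplicated(probe_ids)) {
    dup <- unique(probe_ids[duplicated(probe_ids)])
    stop("duplicate probe IDs: ", paste(dup, collapse = ", "))
  }
  d1 <- dim(values[[1L]])
  for (cn in names(values)) {
    d <- dim(values[[cn]])
    if (d[1L] != length(probe_ids))
      stop("condition '", cn, "' has ", d[1L], " rows but ",
           length(probe_ids), " probe IDs were given")
    if (!identical(d, d1))
      stop("condition '", cn, "' has dimensions ", paste(d, collapse = "x"),
           " but '", names(values)[1L], "' has ", paste(d1, collapse = "x"))
  }
  if (is.null(timepoints)) timepoints <- seq(0, by = 4, length.out = d1[2L])
  if (length(timepoints) != d1[2L])
    stop("length(timepoints) must equal the timepoint dimension (", d1[2L], ")")
  if (!is.null(gene_ids)) {
    gene_ids <- as.character(gene_ids)
    if (length(gene_ids) != length(probe_ids))
      stop("'gene_ids' must be parallel to 'probe_ids'")
    gene_ids[!is.na(gene_ids) & gene_ids == ""] <- NA_character_
  }
  has_na <- Reduce(`|`, lapply(values, function(v) apply(is.na(v), 1L, any)))
  if (any(has_na)) {
    if (na_policy == "reject")
      stop("missing values in probes: ",
           paste(utils::head(probe_ids[has_na], 5L), collapse = ", "),
           if (sum(has_na) > 5L) ", ..." else "",
           " (use na_policy = \"drop\" to remove them)")
    message("dropping ", sum(has_na), " probe(s) with missing values")
    keep <- !has_na
    values <- lapply(values, function(v) v[keep, , , drop = FALSE])
    probe_ids <- probe_ids[keep]
    if (!is.null(gene_ids)) gene_ids <- gene_ids[keep]
  }
  values <- lapply(values, function(v) {
    dimnames(v) <- list(probe_ids, NULL, NULL)
    v
  })
  structure(list(values = values, probe_ids = probe_ids, gene_ids = gene_ids,
                 timepoints = as.numeric(timepoints),
                 conditions = names(values)),
            class = "expr_dataset")
}

#' @export
print.expr_dataset <- function(x, ...) {
  d <- dim(x$values[[1L]])
  cat("Two-condition expression dataset\n")
  cat("  conditions: ", paste(x$conditions, collapse = ", "), "\n", sep = "")
  cat("  probes: ", d[1L], "   timepoints: ", d[2L],
      "   replicates: ", d[3L], "\n", sep = "")
  if (!is.null(x$gene_ids))
    cat("  gene annotation: ", sum(!is.na(x$gene_ids)), " of ", d[1L],
        " probes mapped\n", sep = "")
  invisible(x)
}

#' @export
dim.expr_dataset <- function(x) dim(x$values[[1L]])

n_replicates <- function(x) dim(x$values[[1L]])[3L]

#' Subset an expression dataset by probe
#'
#' @param x An `expr_dataset`.
#' @param i Probe indices or IDs to keep.
#' @param ... Ignored.
#' @return An `expr_dataset` restricted to the selected probes.
#' @export
`[.expr_dataset` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$probe_ids)
  if (anyNA(i)) stop("unknown probe ID in subset")
  expression_dataset(lapply(x$values, function(v) v[i, , , drop = FALSE]),
                     probe_ids = x$probe_ids[i],
                     timepoints = x$timepoints,
                     gene_ids = if (!is.null(x$gene_ids)) x$gene_ids[i])
}
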