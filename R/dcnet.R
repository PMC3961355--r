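#' Fit a differential-connectivity gene network model
#'
#' End-to-end estimator of per-gene differential network connectivity
#' between two conditions of a time-course expression experiment. The
#' chain is: average biological replicates; optionally collapse probes to
#' genes; min--max normalize each record to `[-1, 1]`; rank records by
#' between-condition Euclidean distance and keep the high-distance tail
#' (knee of the sorted curve, or a manual threshold); take the level-1
#' discrete wavelet transform of each retained profile; correlate the
#' 12-dimensional `[approximation, detail]` frequency vectors within each
#' condition (Pearson); build a hard-threshold network (`|r| >= tau`);
#' difference the per-probe degrees between conditions; and select key
#' probes from both tails of the difference curve.
#'
#' @param dataset An [expression_dataset()] with (at least) two conditions.
#' @param gene_map Optional probe-to-gene map (see [collapse_to_genes()]);
#'   `NULL` skips gene collapsing unless the dataset carries `gene_ids` and
#'   `collapse = TRUE`.
#' @param collapse Collapse probes to genes before normalization?
#' @param screen Apply the distance-screening stage? `FALSE` analyses every
#'   record.
#' @param screen_threshold Manual distance threshold (records with distance
#'   strictly greater are kept); `NULL` uses the automatic knee.
#' @param screen_window Smoothing window for the screening knee search.
#' @param wavelet Wavelet basis: `"haar"` (default), `"db2"` or `"db3"`.
#' @param tau Hard correlation threshold in `(0, 1]`; default 0.7.
#' @param neg_threshold,pos_threshold Manual selection thresholds on the
#'   connectivity difference (inclusive; `NULL` = automatic knee).
#' @param diff_window Smoothing window for the difference knee search.
#' @param conditions Length-2 character vector: which conditions to
#'   compare, first minus second (default: the dataset's first two, e.g.
#'   LD minus DD).
#'
#' @return An object of class `"dcnet"`: a list with components
#'   `call`, `conditions`, `n_input` (records entering screening),
#'   `ranking` (distance ranking with selection flags, or `NULL`),
#'   `selected_ids`, `freq` (frequency vectors), `networks` (per-condition
#'   thresholded `"corr_network"`s), `diff` (the `"conn_diff"` table with
#'   key-probe flags), `square_ratio` (list `S_neg`, `S_pos`), and
#'   `params`. Methods: `print`, `summary`, `coef` (named vector of
#'   connectivity differences), `plot`, `as.data.frame`.
#' @examples
#' sim <- simulate_dataset(sim_config(n_probes = 60, seed = 7,
#'                                    modules = list(sim_module(size = 10))))
#' fit <- dcnet(sim$dataset, screen = FALSE)
#' summary(fit)
#' head(coef(fit))
#' @export
dcnet <- function(dataset, gene_map = NULL, collapse = !is.null(gene_map),
                  screen = TRUE, screen_threshold = NULL,
                  screen_window = NULL, wavelet = "haar", tau = 0.7,
                  neg_threshold = NULL, pos_threshold = NULL,
                  diff_window = NULL, conditions = NULL) {
  stopifnot(inherits(dataset, "expr_dataset"))
  if (is.null(conditions)) conditions <- dataset$conditions[1:2]

  ds <- if (n_replicates(dataset) > 1L) average_replicates(dataset) else dataset
  if (collapse) ds <- collapse_to_genes(ds, gene_map)
  ds <- normalize_dataset(ds)
  n_input <- length(ds$probe_ids)

  ranking <- NULL
  if (screen) {
    ranking <- profile_distances(ds, conditions)
    ranking <- select_important(ranking, threshold = screen_threshold,
                                window = screen_window)
    selected_ids <- attr(ranking, "selected_ids")
    if (length(selected_ids) < 2L)
      stop("screening retained fewer than 2 records; lower the threshold ",
           "or set screen = FALSE")
    ds <- ds[selected_ids]
  }

  freq <- build_frequency_vectors(ds, basis = wavelet)
  nets <- lapply(conditions, function(cn)
    threshold_adjacency(correlation_matrix(freq, cn), tau = tau))
  names(nets) <- conditions

  diff <- connectivity_difference(nets[[1L]], nets[[2L]])
  sq <- if (any(diff$m != 0)) square_ratio(diff) else {
    warning("all connectivity differences are zero; square ratios undefined")
    list(S_neg = NA_real_, S_pos = NA_real_)
  }
  diff <- select_key_probes(diff, neg_threshold = neg_threshold,
                            pos_threshold = pos_threshold,
                            window = diff_window)

  structure(list(call = match.call(), conditions = conditions,
                 n_input = n_input, ranking = ranking,
                 selected_ids = ds$probe_ids, freq = freq,
                 networks = nets, diff = diff, square_ratio = sq,
                 params = list(wavelet = wavelet, tau = tau,
                               screen_threshold = screen_threshold,
                               neg_threshold = neg_threshold,
                               pos_threshold = pos_threshold)),
            class = "dcnet")
}

#' @export
print.dcnet <- function(x, ...) {
  sel <- attr(x$diff, "selection")
  cat("Differential-connectivity network model\n")
  cat("  conditions: ", x$conditions[1L], " - ", x$conditions[2L],
      "   wavelet: ", x$params$wavelet, "   tau: ", x$params$tau, "\n",
      sep = "")
  cat("  records: ", x$n_input, " in, ", length(x$selected_ids),
      " analysed\n", sep = "")
  cat("  key probes: ", sel$negative$n, " negative + ", sel$positive$n,
      " positive = ", sel$negative$n + sel$positive$n, "\n", sep = "")
  invisible(x)
}

#' @export
summary.dcnet <- function(object, ...) {
  cnt <- attr(object$diff, "counts")
  sel <- attr(object$diff, "selection")
  out <- list(conditions = object$conditions,
              n_input = object$n_input,
              n_analysed = length(object$selected_ids),
              counts = cnt,
              S_neg = object$square_ratio$S_neg,
              S_pos = object$square_ratio$S_pos,
              selection = sel,
              degrees = lapply(object$networks, function(n) summary(
                as.numeric(n$degrees))),
              params = object$params)
  class(out) <- "summary.dcnet"
  out
}

#' @export
print.summary.dcnet <- function(x, ...) {
  cat("Differential-connectivity network model: ", x$conditions[1L], " - ",
      x$conditions[2L], "\n", sep = "")
  cat("records analysed: ", x$n_analysed, " of ", x$n_input, "\n", sep = "")
  cat("connectivity differences m = l(", x$conditions[1L], ") - l(",
      x$conditions[2L], "):\n", sep = "")
  cat("  negative (more connected in ", x$conditions[2L], "): ",
      x$counts[["negative"]], "\n", sep = "")
  cat("  positive (more connected in ", x$conditions[1L], "): ",
      x$counts[["positive"]], "\n", sep = "")
  cat("  zero: ", x$counts[["zero"]], "\n", sep = "")
  cat(sprintf("square ratios: S_neg = %.2f%%, S_pos = %.2f%%\n",
              100 * x$S_neg, 100 * x$S_pos))
  cat("key probes: ", x$selection$negative$n, " negative (m <= ",
      signif(x$selection$negative$threshold, 4), "), ",
      x$selection$positive$n, " positive (m >= ",
      signif(x$selection$positive$threshold, 4), ")\n", sep = "")
  invisible(x)
}

#' @export
coef.dcnet <- function(object, ...) {
  stats::setNames(object$diff$m, object$diff$probe_id)
}

#' @export
as.data.frame.dcnet <- function(x, ...) as.data.frame(x$diff)

#' Plot a differential-connectivity fit
#'
#' Two base-graphics panels: the sorted between-condition distance curve
#' with the screening knee (when screening was run), and the sorted
#' connectivity-difference curve with the two selection thresholds.
#'
#' @param x A `"dcnet"` object.
#' @param which Which panels to draw (subset of `1:2`).
#' @param ... Passed to [plot.default()].
#' @export
plot.dcnet <- function(x, which = if (is.null(x$ranking)) 2L else 1:2, ...) {
  op <- graphics::par(mfrow = c(1, length(which)))
  on.exit(graphics::par(op))
  if (1L %in% which && !is.null(x$ranking)) {
    infl <- attr(x$ranking, "inflection")
    plot(x$ranking$distance, type = "l", xlab = "rank",
         ylab = "between-condition distance",
         main = "distance screening", ...)
    graphics::abline(v = infl$index, h = infl$value, lty = 2, col = 2)
  }
  if (2L %in% which) {
    sel <- attr(x$diff, "selection")
    m <- sort(x$diff$m)
    plot(m, type = "l", xlab = "rank",
         ylab = paste0("m = l(", x$conditions[1L], ") - l(",
                       x$conditions[2L], ")"),
         main = "connectivity differences", ...)
    graphics::abline(h = c(sel$negative$threshold, sel$positive$threshold),
                     lty = 2, col = c(4, 2))
  }
  invisible(x)
}
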