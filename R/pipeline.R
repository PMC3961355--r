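#' Run the full differential-connectivity pipeline from a config
#'
#' Thin orchestration over [dcnet()] for shell / batch use: reads the input
#' expression data, runs the whole chain, persists every stage's output as
#' TSV (so any stage can be audited or resumed), and writes a YAML run
#' report containing the resolved configuration and every intermediate
#' count (records after collapsing, screened probes, negative / positive /
#' zero differences, square ratios, key probes).
#'
#' @param config A named list, or path to a YAML file, with entries:
#'   \describe{
#'     \item{expression / layout}{path to a delimited expression table and
#'       its column layout (see [read_expression_table()]); or}
#'     \item{series_matrix / sample_map}{a GEO series-matrix file plus
#'       sample-mapping TSV (see [read_series_matrix()]).}
#'     \item{gene_map}{optional probe-to-gene TSV; enables gene collapsing.}
#'     \item{screen, screen_threshold, screen_window}{screening controls.}
#'     \item{wavelet, tau, neg_threshold, pos_threshold, diff_window}{model
#'       parameters as in [dcnet()].}
#'     \item{out_dir}{output directory (created if absent).}
#'     \item{seed}{integer seed for any stochastic step.}
#'   }
#' @param dataset Optionally, an already-loaded `expr_dataset` (overrides
#'   the input paths in `config`).
#' @return Invisibly, a list with `fit` (the `"dcnet"` object) and `report`
#'   (the report list, also written to `out_dir/report.yaml`).
#' @export
run_pipeline <- function(config, dataset = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(layout = "condition_time_rep", gene_map = NULL,
                   screen = TRUE, screen_threshold = NULL,
                   screen_window = NULL, wavelet = "haar", tau = 0.7,
                   neg_threshold = NULL, pos_threshold = NULL,
                   diff_window = NULL, out_dir = ".", seed = 1L)
  config <- utils::modifyList(defaults, config)
  if (!is.null(config$seed)) set.seed(as.integer(config$seed))

  if (is.null(dataset)) {
    dataset <- if (!is.null(config$expression))
      read_expression_table(config$expression, layout = config$layout)
    else if (!is.null(config$series_matrix))
      read_series_matrix(config$series_matrix, config$sample_map)
    else stop("config must name an 'expression' table or a 'series_matrix'")
  }
  gene_map <- if (!is.null(config$gene_map)) read_gene_map(config$gene_map)

  fit <- dcnet(dataset, gene_map = gene_map,
               collapse = !is.null(gene_map),
               screen = isTRUE(config$screen),
               screen_threshold = config$screen_threshold,
               screen_window = config$screen_window,
               wavelet = config$wavelet, tau = config$tau,
               neg_threshold = config$neg_threshold,
               pos_threshold = config$pos_threshold,
               diff_window = config$diff_window)

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$out_dir, f)
  if (!is.null(fit$ranking))
    utils::write.table(as.data.frame(fit$ranking)[
      c("probe_id", "distance", "selected")],
      p("distances.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  for (cn in fit$conditions) {
    fvs <- cbind(probe_id = attr(fit$freq, "probe_ids"),
                 as.data.frame(fit$freq[[cn]]))
    utils::write.table(fvs, p(paste0("frequency_", cn, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_edge_list(fit$networks[[cn]], p(paste0("edges_", cn, ".tsv")))
    write_graphml(fit$networks[[cn]], p(paste0("network_", cn, ".graphml")))
  }
  write_node_table(fit$diff, p("nodes.tsv"))

  cnt <- attr(fit$diff, "counts")
  sel <- attr(fit$diff, "selection")
  report <- list(
    config = config[!vapply(config, is.null, logical(1L))],
    records_in = fit$n_input,
    records_analysed = length(fit$selected_ids),
    screening = if (!is.null(fit$ranking))
      attr(fit$ranking, "inflection")[c("index", "value", "method")],
    counts = as.list(cnt),
    square_ratio = lapply(fit$square_ratio, function(v) round(v, 6)),
    key_probes = list(
      negative = list(threshold = sel$negative$threshold,
                      n = sel$negative$n, ids = sel$negative$ids),
      positive = list(threshold = sel$positive$threshold,
                      n = sel$positive$n, ids = sel$positive$ids)))
  yaml::write_yaml(report, p("report.yaml"))
  message("pipeline complete: ", sel$negative$n + sel$positive$n,
          " key probes; report in ", p("report.yaml"))
  invisible(list(fit = fit, report = report))
}

#' Write a simulated dataset and its ground truth to disk
#'
#' Convenience wrapper for batch use: simulates from a config and writes
#' the expression table plus the ground-truth module table.
#'
#' @param config A [sim_config()], or path to a YAML file whose entries are
#'   `sim_config()` arguments (modules given as lists of `sim_module()`
#'   arguments).
#' @param out_dir Output directory.
#' @return Invisibly, the [simulate_dataset()] result.
#' @export
write_simulation <- function(config, out_dir) {
  if (is.character(config)) {
    cfg <- yaml::read_yaml(config)
    if (!is.null(cfg$modules))
      cfg$modules <- lapply(cfg$modules, function(m) do.call(sim_module, m))
    config <- do.call(sim_config, cfg)
  }
  sim <- simulate_dataset(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_table(sim$dataset, file.path(out_dir, "expression.tsv"))
  utils::write.table(sim$truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(sim)
}
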