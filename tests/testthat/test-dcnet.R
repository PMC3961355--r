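fit_small <- local({
  sim <- simulate_dataset(sim_config(n_probes = 80,
                                     modules = list(sim_module(size = 12)),
                                     seed = 29))
  suppressMessages(suppressWarnings(dcnet(sim$dataset, screen = FALSE)))
})

test_that("the fitted object exposes the standard modelling surface", {
  expect_s3_class(fit_small, "dcnet")
  expect_named(coef(fit_small), fit_small$diff$probe_id)
  expect_true(all(coef(fit_small) ==
                    fit_small$networks$LD$degrees -
                    fit_small$networks$DD$degrees))
  expect_output(print(fit_small), "key probes")
  s <- summary(fit_small)
  expect_s3_class(s, "summary.dcnet")
  expect_output(print(s), "square ratios")
  expect_equal(sum(unname(s$counts)), length(fit_small$selected_ids))
  df <- as.data.frame(fit_small)
  expect_true(all(c("probe_id", "m", "selected_neg") %in% names(df)))
  f <- tempfile(fileext = ".png")
  grDevices::png(f); plot(fit_small); grDevices::dev.off()
  expect_true(file.exists(f)); unlink(f)
})

test_that("screening integrates into the fit and bounds the analysed set", {
  sim <- simulate_dataset(sim_config(n_probes = 120,
                                     modules = list(sim_module(size = 15)),
                                     seed = 47))
  fit <- suppressMessages(suppressWarnings(
    dcnet(sim$dataset, screen = TRUE, screen_threshold = 1)))
  expect_lte(length(fit$selected_ids), 120)
  expect_setequal(fit$selected_ids, attr(fit$ranking, "selected_ids"))
  expect_identical(fit$diff$probe_id, fit$selected_ids)
})

test_that("run_pipeline writes every stage artifact and a faithful report", {
  dir <- withr::local_tempdir()
  sim <- write_simulation(sim_config(n_probes = 60,
                                     modules = list(sim_module(size = 10)),
                                     seed = 13), file.path(dir, "sim"))
  cfg <- list(expression = file.path(dir, "sim", "expression.tsv"),
              screen = FALSE, out_dir = file.path(dir, "out"), seed = 13)
  res <- suppressMessages(suppressWarnings(run_pipeline(cfg)))
  out <- file.path(dir, "out")
  for (f in c("nodes.tsv", "edges_LD.tsv", "edges_DD.tsv",
              "frequency_LD.tsv", "frequency_DD.tsv",
              "network_LD.graphml", "report.yaml"))
    expect_true(file.exists(file.path(out, f)), info = f)
  rep <- yaml::read_yaml(file.path(out, "report.yaml"))
  expect_equal(rep$records_analysed, 60)
  cnt <- attr(res$fit$diff, "counts")
  expect_equal(rep$counts$negative, unname(cnt["negative"]))
  expect_equal(rep$counts$negative + rep$counts$positive + rep$counts$zero,
               60)
  if (!is.null(rep$square_ratio$S_neg) && !is.na(rep$square_ratio$S_neg))
    expect_equal(rep$square_ratio$S_neg + rep$square_ratio$S_pos, 1,
                 tolerance = 1e-4)
  nodes <- read_node_table(file.path(out, "nodes.tsv"))
  expect_equal(nrow(nodes), 60)

  # rerunning with the same config reproduces the outputs byte for byte
  cfg2 <- cfg; cfg2$out_dir <- file.path(dir, "out2")
  suppressMessages(suppressWarnings(run_pipeline(cfg2)))
  drop_outdir <- function(x) x[!grepl("out_dir", x)]
  for (f in c("nodes.tsv", "edges_LD.tsv", "report.yaml"))
    expect_identical(drop_outdir(readLines(file.path(out, f))),
                     drop_outdir(readLines(file.path(cfg2$out_dir, f))),
                     label = f)
})

test_that("a pure-noise dataset selects only branch tails", {
  sim <- simulate_dataset(sim_config(n_probes = 80, modules = list(),
                                     seed = 71))
  fit <- suppressMessages(suppressWarnings(dcnet(sim$dataset,
                                                 screen = FALSE)))
  sel <- attr(fit$diff, "selection")
  expect_lt(sel$negative$n + sel$positive$n, 80)
  m <- fit$diff$m
  if (sel$negative$n > 0)
    expect_true(all(sort(m[fit$diff$selected_neg]) ==
                      head(sort(m[m < 0]), sel$negative$n)))
  if (sel$positive$n > 0)
    expect_true(all(sort(m[fit$diff$selected_pos]) ==
                      tail(sort(m[m > 0]), sel$positive$n)))
  if (any(fit$diff$m != 0))
    expect_equal(fit$square_ratio$S_neg + fit$square_ratio$S_pos, 1,
                 tolerance = 1e-12)
})

test_that("yaml-driven configuration reaches the same fit", {
  dir <- withr::local_tempdir()
  write_simulation(sim_config(n_probes = 40,
                              modules = list(sim_module(size = 8)),
                              seed = 3), file.path(dir, "sim"))
  yml <- file.path(dir, "run.yaml")
  yaml::write_yaml(list(expression = file.path(dir, "sim", "expression.tsv"),
                        screen = FALSE, tau = 0.8,
                        out_dir = file.path(dir, "out")), yml)
  res <- suppressMessages(suppressWarnings(run_pipeline(yml)))
  expect_equal(res$fit$params$tau, 0.8)
  expect_equal(length(res$fit$selected_ids), 40)
})
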