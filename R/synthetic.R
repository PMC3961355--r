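#' Simulation configuration for two-condition circadian time courses
#'
#' Describes a synthetic two-condition (light--dark vs constant-dark)
#' expression experiment: rhythmic co-expression modules whose tightness
#' differs between conditions, on a background of independent noise probes,
#' with replicate-level measurement noise. The defaults emulate the coral
#' circadian study design this package targets: 300 screened probes,
#' 12 timepoints at 4-hour intervals over two days, 3 biological
#' replicates, a 24-hour rhythm, and one planted 30-probe module that is
#' tightly co-expressed under constant darkness (target within-module
#' correlation 0.9) but loosely under the light--dark cycle (0.2), with
#' replicate noise sd 0.3.
#'
#' @param n_probes Total probe count.
#' @param n_timepoints Timepoints per condition.
#' @param n_replicates Biological replicates per condition/timepoint.
#' @param interval Sampling interval in hours.
#' @param modules List of module specs from [sim_module()]; sizes must sum
#'   to at most `n_probes`.
#' @param noise_sd Sd of the stochastic (non-rhythmic) component of latent
#'   and background signals; 0 switches noise off entirely.
#' @param replicate_sd Sd of additive per-replicate measurement noise.
#' @param conditions Names of the two conditions.
#' @param seed Integer seed; a fixed seed gives bit-identical datasets.
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(n_probes = 300L, n_timepoints = 12L,
                       n_replicates = 3L, interval = 4,
                       modules = list(sim_module()),
                       noise_sd = 1, replicate_sd = 0.3,
                       conditions = c("LD", "DD"), seed = 1L) {
  sizes <- vapply(modules, function(m) m$size, integer(1L))
  if (sum(sizes) > n_probes)
    stop("module sizes (", sum(sizes), ") exceed n_probes (", n_probes, ")")
  structure(list(n_probes = as.integer(n_probes),
                 n_timepoints = as.integer(n_timepoints),
                 n_replicates = as.integer(n_replicates),
                 interval = interval, modules = modules,
                 noise_sd = noise_sd, replicate_sd = replicate_sd,
                 conditions = conditions, seed = as.integer(seed)),
            class = "sim_config")
}

#' Specify one planted co-expression module
#'
#' @param size Number of member probes.
#' @param r_target Length-2 vector: target within-module correlation per
#'   condition (each in `[0, 1]`), first condition first.
#' @param amplitude Length-2 vector: rhythmic amplitude of the module's
#'   latent signal per condition (0 = arrhythmic).
#' @param period Rhythm period in hours.
#' @return List describing the module.
#' @export
sim_module <- function(size = 30L, r_target = c(0.2, 0.9),
                       amplitude = c(1, 1), period = 24) {
  if (any(r_target < 0 | r_target > 1))
    stop("correlation targets must lie in [0, 1]")
  list(size = as.integer(size), r_target = r_target,
       amplitude = amplitude, period = period)
}

standardize_or_zero <- function(x) {
  s <- stats::sd(x)
  if (s == 0) return(x - mean(x))
  (x - mean(x)) / s
}

#' Simulate a two-condition time-course expression dataset
#'
#' Each module has, per condition, a latent signal: a sinusoid of the given
#' period and amplitude plus Gaussian noise of sd `noise_sd`, standardized
#' over timepoints. Member probe `i` mixes the latent with an independent
#' standardized noise profile, `x_i = sqrt(r) z + sqrt(1 - r) e_i`, so the
#' expected within-module correlation equals the target `r`. Background
#' probes are independent noise. Every replicate observes the probe signal
#' plus independent `N(0, replicate_sd^2)` noise. The ground-truth table
#' records module membership and the expected sign of each probe's
#' connectivity difference (first condition minus second: a module tighter
#' in the second condition gives its members an expected negative sign).
#'
#' @param config A [sim_config()].
#' @return List with `dataset` (an `expr_dataset`) and `truth` (data frame
#'   `probe_id`, `module`, `expected_sign`).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  tp <- seq(0, by = config$interval, length.out = config$n_timepoints)
  np <- config$n_probes; nt <- config$n_timepoints; nr <- config$n_replicates
  ids <- sprintf("P%04d", seq_len(np))
  sizes <- vapply(config$modules, function(m) m$size, integer(1L))
  module_of <- rep(0L, np)
  if (length(sizes)) module_of[seq_len(sum(sizes))] <- rep(seq_along(sizes), sizes)

  signal <- lapply(config$conditions, function(cn) matrix(0, np, nt))
  names(signal) <- config$conditions
  for (k in seq_along(config$modules)) {
    mod <- config$modules[[k]]
    phase <- stats::runif(1, 0, 2 * pi)
    members <- which(module_of == k)
    for (ci in seq_along(config$conditions)) {
      cn <- config$conditions[ci]
      z <- mod$amplitude[ci] * sin(2 * pi * tp / mod$period + phase)
      if (config$noise_sd > 0)
        z <- z + stats::rnorm(nt, sd = config$noise_sd)
      z <- standardize_or_zero(z)
      r <- mod$r_target[ci]
      for (i in members) {
        e <- if (config$noise_sd > 0) standardize_or_zero(stats::rnorm(nt))
             else numeric(nt)
        signal[[cn]][i, ] <- sqrt(r) * z + sqrt(1 - r) * e
      }
    }
  }
  bg <- which(module_of == 0L)
  if (length(bg) && config$noise_sd > 0)
    for (cn in config$conditions)
      signal[[cn]][bg, ] <- matrix(stats::rnorm(length(bg) * nt,
                                                sd = config$noise_sd),
                                   length(bg), nt)

  values <- lapply(signal, function(s) {
    v <- array(0, dim = c(np, nt, nr))
    for (r in seq_len(nr)) {
      noise <- if (config$replicate_sd > 0)
        matrix(stats::rnorm(np * nt, sd = config$replicate_sd), np, nt)
      else 0
      v[, , r] <- s + noise
    }
    v
  })

  expected_sign <- integer(np)
  for (k in seq_along(config$modules)) {
    rt <- config$modules[[k]]$r_target
    expected_sign[module_of == k] <- sign(rt[1L] - rt[2L])
  }
  list(dataset = expression_dataset(values, probe_ids = ids, timepoints = tp),
       truth = data.frame(probe_id = ids, module = module_of,
                          expected_sign = expected_sign,
                          stringsAsFactors = FALSE))
}

#' Deterministic 8-probe worked example
#'
#' A tiny fixed dataset (8 probes, 12 timepoints, 2 conditions, single
#' replicate, closed-form sinusoids/trends — no randomness) together with
#' the expected results of the full chain at the default settings (Haar
#' basis, Pearson correlation, `tau = 0.7`): correlation matrices, degrees
#' and connectivity differences. The expectations were computed once with
#' an independent naive-loop implementation and are frozen here; probes
#' p1--p4 form a module that is tight only in DD, p8 is constant in LD
#' (exercising the degenerate zero-variance policy) and coincides with p5's
#' sampled rhythm in DD (exercising the inclusive `|r| <= 1` bound).
#'
#' @return List with `dataset` (an `expr_dataset`) and `expected` (list
#'   `R_LD`, `R_DD`, `degrees_LD`, `degrees_DD`, `m`, `S_neg`, `S_pos`).
#' @export
make_worked_example <- function() {
  t <- seq(0, 44, by = 4)
  w <- 2 * pi / 24
  LD <- rbind(sin(w * t),
              sin(w * t + 2),
              sin(w * t + 4),
              0.5 * sin(w * t + 1) + 0.5 * cos(2 * w * t),
              cos(w * t),
              0.8 * cos(w * t) + 0.2 * (t / 44),
              t / 44,
              rep(5, 12))
  DD <- rbind(sin(w * t + 0.10),
              sin(w * t + 0.20),
              sin(w * t + 0.15),
              sin(w * t + 0.05),
              cos(3 * w * t),
              (t / 44)^2,
              -t / 44,
              (-1)^(0:11))
  ids <- paste0("p", 1:8)
  ds <- expression_dataset(list(LD = LD, DD = DD), probe_ids = ids,
                           timepoints = t)
  deg_LD <- c(0L, 2L, 2L, 0L, 3L, 3L, 0L, 0L)
  deg_DD <- c(3L, 3L, 3L, 3L, 1L, 1L, 1L, 1L)
  R_LD <- matrix(c(
    1, -0.416146836547, -0.653643620864, 0.377247446269, 0, -0.0400151196795,
    -0.356662978967, 0,
    -0.416146836547, 1, -0.416146836547, 0.377247446269, 0.909297426826,
    0.919964437595, -0.0388178709899, 0,
    -0.653643620864, -0.416146836547, 1, -0.69122810899, -0.756802495308,
    -0.725665461202, 0.388970847395, 0,
    0.377247446269, 0.377247446269, -0.69122810899, 1, 0.587528086926,
    0.54695635691, -0.415586012204, 0,
    0, 0.909297426826, -0.756802495308, 0.587528086926, 1, 0.9934178251,
    -0.205919466916, 0,
    -0.0400151196795, 0.919964437595, -0.725665461202, 0.54695635691,
    0.9934178251, 1, -0.0947496365965, 0,
    -0.356662978967, -0.0388178709899, 0.388970847395, -0.415586012204,
    -0.205919466916, -0.0947496365965, 1, 0,
    0, 0, 0, 0, 0, 0, 0, 1), 8, 8, byrow = TRUE)
  R_DD <- matrix(c(
    1, 0.995004165278, 0.998750260395, 0.998750260395, 0, -0.379086664653,
    0.375438793609, 0,
    0.995004165278, 1, 0.998750260395, 0.988771077936, 0, -0.38756189703,
    0.390463347928, 0,
    0.998750260395, 0.998750260395, 1, 0.995004165278, 0, -0.383803935821,
    0.383430258749, 0,
    0.998750260395, 0.988771077936, 0.995004165278, 1, 0, -0.373421874249,
    0.366508927009, 0,
    0, 0, 0, 0, 1, 0.226493121111, 0.102959733458, 1,
    -0.379086664653, -0.38756189703, -0.383803935821, -0.373421874249,
    0.226493121111, 1, -0.909467183809, 0.226493121111,
    0.375438793609, 0.390463347928, 0.383430258749, 0.366508927009,
    0.102959733458, -0.909467183809, 1, 0.102959733458,
    0, 0, 0, 0, 1, 0.226493121111, 0.102959733458, 1), 8, 8, byrow = TRUE)
  dimnames(R_LD) <- dimnames(R_DD) <- list(ids, ids)
  list(dataset = ds,
       expected = list(R_LD = R_LD, R_DD = R_DD,
                       degrees_LD = stats::setNames(deg_LD, ids),
                       degrees_DD = stats::setNames(deg_DD, ids),
                       m = stats::setNames(deg_LD - deg_DD, ids),
                       S_neg = 22 / 30, S_pos = 8 / 30))
}
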