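freq_net <- function(X, ids = sprintf("p%d", seq_len(nrow(X))),
                     condition = "LD") {
  rownames(X) <- ids
  correlation_matrix(X, condition = condition)
}

test_that("correlation matrix matches a brute-force pairwise Pearson loop", {
  set.seed(2)
  X <- matrix(rnorm(5 * 12), 5, 12)
  net <- freq_net(X)
  expect_equal(unname(diag(net$R)), rep(1, 5))
  expect_equal(net$R, t(net$R))
  for (i in 1:5)
    for (j in 1:5)
      if (i != j)
        expect_equal(unname(net$R[i, j]), oracle_pearson(X[i, ], X[j, ]),
                     tolerance = 1e-12)

  # perfect co- and anti-correlation
  Y <- rbind(X[1, ], X[1, ] * 2 + 1, -X[1, ])
  nety <- freq_net(Y)
  expect_equal(unname(nety$R[1, 2]), 1)
  expect_equal(unname(nety$R[1, 3]), -1)
})

test_that("degenerate zero-variance vectors get correlation 0, not NA", {
  X <- rbind(rnorm(12), rep(2, 12), rnorm(12))
  expect_warning(net <- freq_net(X), "zero-variance")
  expect_equal(unname(net$R[2, c(1, 3)]), c(0, 0))
  expect_false(anyNA(net$R))
  expect_error(suppressWarnings(freq_net(rbind(rep(1, 12), rep(2, 12)))),
               "all")
})

test_that("hard thresholding is inclusive at tau and at |r| = 1", {
  ids <- c("a", "b", "c", "d")
  R <- diag(4)
  R[1, 2] <- R[2, 1] <- 0.7          # exactly tau: edge
  R[1, 3] <- R[3, 1] <- -0.7         # inclusive on |r|
  R[1, 4] <- R[4, 1] <- 0.699999     # just below: no edge
  R[2, 3] <- R[3, 2] <- 1            # |r| = 1 kept
  R[2, 4] <- R[4, 2] <- -0.2
  R[3, 4] <- R[4, 3] <- 0.95
  dimnames(R) <- list(ids, ids)
  net <- structure(list(condition = "LD", probe_ids = ids, R = R),
                   class = "corr_network")
  thr <- threshold_adjacency(net, 0.7)
  expect_equal(unname(thr$L[1, ]), c(0, 1, 1, 0))
  expect_equal(unname(diag(thr$L)), rep(0, 4))
  expect_equal(unname(thr$degrees), c(2, 2, 3, 1))
  expect_equal(thr$L, t(thr$L))

  # brute-force degree count
  for (i in 1:4) {
    cnt <- 0
    for (j in 1:4)
      if (i != j && abs(R[i, j]) >= 0.7 && abs(R[i, j]) <= 1) cnt <- cnt + 1
    expect_equal(unname(thr$degrees[i]), cnt)
  }

  expect_error(threshold_adjacency(net, 0), "tau")
  expect_error(threshold_adjacency(net, 1.2), "tau")

  # tau = 1 with |r| < 1 off-diagonal empties the graph
  set.seed(6)
  net2 <- freq_net(matrix(rnorm(4 * 12), 4, 12))
  expect_equal(sum(threshold_adjacency(net2, 1)$L), 0)
})

test_that("raising tau never increases any degree", {
  set.seed(14)
  net <- freq_net(matrix(rnorm(10 * 12), 10, 12))
  taus <- seq(0.1, 1, by = 0.1)
  degs <- sapply(taus, function(t) threshold_adjacency(net, t)$degrees)
  expect_true(all(diff(t(degs)) <= 0))
})

test_that("connectivity differences subtract degrees in fixed probe order", {
  set.seed(9)
  X <- matrix(rnorm(6 * 12), 6, 12)
  n1 <- threshold_adjacency(freq_net(X), 0.5)
  n2 <- threshold_adjacency(freq_net(X), 0.5)
  d0 <- connectivity_difference(n1, n2)
  expect_true(all(d0$m == 0))
  expect_equal(unname(attr(d0, "counts")),
               c(0L, 0L, 6L))

  Y <- matrix(rnorm(6 * 12), 6, 12)
  n3 <- threshold_adjacency(freq_net(Y, condition = "DD"), 0.5)
  d1 <- connectivity_difference(n1, n3)
  expect_equal(sum(d1$m), sum(n1$degrees) - sum(n3$degrees))
  expect_equal(sum(unname(attr(d1, "counts"))), 6)

  n4 <- threshold_adjacency(freq_net(Y, ids = rev(sprintf("p%d", 1:6))), 0.5)
  expect_error(connectivity_difference(n1, n4), "order")
  expect_error(connectivity_difference(freq_net(X), n1), "threshold_adjacency")
})

test_that("square ratios partition the squared differences", {
  mk <- function(m) {
    structure(data.frame(probe_id = paste0("p", seq_along(m)),
                         degree_1 = 0L, degree_2 = 0L, m = as.integer(m)),
              class = c("conn_diff", "data.frame"))
  }
  expect_equal(square_ratio(mk(c(-2, 1, 1))), list(S_neg = 4 / 6,
                                                   S_pos = 2 / 6))
  expect_equal(square_ratio(mk(c(-3, -1))), list(S_neg = 1, S_pos = 0))
  expect_error(square_ratio(mk(c(0, 0))), "zero")
  set.seed(41)
  for (k in 1:20) {
    m <- sample(-5:5, 12, replace = TRUE)
    if (all(m == 0)) next
    sr <- square_ratio(mk(m))
    expect_equal(sr$S_neg + sr$S_pos, 1, tolerance = 1e-12)
    expect_gte(sr$S_neg, 0); expect_lte(sr$S_neg, 1)
  }
})

test_that("manual key-probe thresholds select the inclusive tails", {
  m <- c(-30, -20, -19, -5, 0, 3, 10, 11, 25)
  tab <- structure(data.frame(probe_id = paste0("p", 1:9),
                              degree_1 = 0L, degree_2 = 0L,
                              m = as.integer(m)),
                   class = c("conn_diff", "data.frame"))
  sel <- select_key_probes(tab, neg_threshold = -19.88, pos_threshold = 10)
  s <- attr(sel, "selection")
  expect_identical(s$negative$ids, c("p1", "p2"))    # m <= -19.88, so <= -20
  expect_identical(s$positive$ids, c("p7", "p8", "p9"))  # m >= 10 inclusive
  # tails of the sorted sequence
  expect_true(all(sort(m[match(s$negative$ids, tab$probe_id)]) ==
                    head(sort(m), s$negative$n)))

  zero <- tab; zero$m <- 0L
  selz <- suppressWarnings(select_key_probes(zero))
  sz <- attr(selz, "selection")
  expect_equal(sz$negative$n + sz$positive$n, 0)
})

test_that("the automatic knee recovers planted strong-negative hubs", {
  set.seed(55)
  m <- sample(c(-2L, -1L, 0L, 1L, 2L), 95, replace = TRUE)
  m <- c(m, c(-40L, -38L, -35L, -33L, -31L))
  ids <- sprintf("p%03d", seq_along(m))
  tab <- structure(data.frame(probe_id = ids, degree_1 = 0L,
                              degree_2 = 0L, m = m),
                   class = c("conn_diff", "data.frame"))
  sel <- select_key_probes(tab, window = 1)
  expect_setequal(attr(sel, "selection")$negative$ids, tail(ids, 5))
})

test_that("the full chain matches the brute-force oracle on small instances", {
  set.seed(100)
  for (k in 1:10) {
    np <- sample(3:8, 1)
    LD <- matrix(rnorm(np * 12), np, 12)
    DD <- matrix(rnorm(np * 12), np, 12)
    ds <- expression_dataset(list(LD = LD, DD = DD),
                             probe_ids = sprintf("p%d", 1:np))
    fit <- suppressWarnings(suppressMessages(
      dcnet(ds, screen = FALSE, neg_threshold = -1e9, pos_threshold = 1e9)))
    want <- oracle_chain(list(LD, DD), tau = 0.7)
    expect_equal(unname(fit$networks$LD$R), want[[1]]$R, tolerance = 1e-9)
    expect_equal(unname(fit$networks$DD$L), want[[2]]$L)
    expect_equal(fit$diff$m, as.integer(want$m))
  }
})

test_that("permuting probe order permutes all outputs consistently", {
  set.seed(61)
  LD <- matrix(rnorm(7 * 12), 7, 12)
  DD <- matrix(rnorm(7 * 12), 7, 12)
  ids <- sprintf("p%d", 1:7)
  ds <- expression_dataset(list(LD = LD, DD = DD), probe_ids = ids)
  perm <- sample(7)
  dsp <- expression_dataset(list(LD = LD[perm, ], DD = DD[perm, ]),
                            probe_ids = ids[perm])
  f1 <- suppressWarnings(suppressMessages(dcnet(ds, screen = FALSE)))
  f2 <- suppressWarnings(suppressMessages(dcnet(dsp, screen = FALSE)))
  m1 <- coef(f1); m2 <- coef(f2)
  expect_equal(m1[ids], m2[ids])
  expect_equal(f1$networks$DD$R[ids, ids], f2$networks$DD$R[ids, ids],
               tolerance = 1e-12)
})

test_that("the worked example reproduces its frozen oracle expectations", {
  wk <- make_worked_example()
  ds <- normalize_dataset(wk$dataset)
  fv <- build_frequency_vectors(ds)
  expect_warning(nld <- correlation_matrix(fv, "LD"), "zero-variance")
  ndd <- correlation_matrix(fv, "DD")
  nld <- threshold_adjacency(nld, 0.7)
  ndd <- threshold_adjacency(ndd, 0.7)
  expect_equal(nld$R, wk$expected$R_LD, tolerance = 1e-9)
  expect_equal(ndd$R, wk$expected$R_DD, tolerance = 1e-9)
  expect_equal(nld$degrees, wk$expected$degrees_LD)
  expect_equal(ndd$degrees, wk$expected$degrees_DD)
  d <- connectivity_difference(nld, ndd)
  expect_equal(stats::setNames(d$m, d$probe_id), wk$expected$m)
  sr <- square_ratio(d)
  expect_equal(sr$S_neg, wk$expected$S_neg, tolerance = 1e-12)
  expect_equal(sr$S_pos, wk$expected$S_pos, tolerance = 1e-12)
})
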