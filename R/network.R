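#' Frequency-domain correlation matrix for one condition
#'
#' Pearson correlation (sample moments) between every pair of probes'
#' frequency vectors. A degenerate (zero-variance) frequency vector — e.g.
#' a probe whose profile was constant before normalization — gets
#' correlation 0 with every other probe, keeping the matrix complete and
#' symmetric; a warning reports how many.
#'
#' @param freq Numeric `probes x coefficients` matrix (one condition's slot
#'   of a [build_frequency_vectors()] result), with probe IDs as row names,
#'   or a `"freq_vectors"` object together with `condition`.
#' @param condition Condition name (used for labeling, and to pick the slot
#'   when `freq` is a `"freq_vectors"` object).
#' @return Object of class `"corr_network"`: list with `condition`,
#'   `probe_ids`, correlation matrix `R`, and empty slots `tau`, `L`,
#'   `degrees` to be filled by [threshold_adjacency()].
#' @export
correlation_matrix <- function(freq, condition = NULL) {
  if (inherits(freq, "freq_vectors")) {
    if (is.null(condition)) stop("give 'condition' to pick a matrix")
    freq <- freq[[condition]]
  }
  if (!is.matrix(freq) || nrow(freq) < 2L)
    stop("need a coefficient matrix with at least 2 probes")
  sds <- apply(freq, 1L, stats::sd)
  degenerate <- sds == 0
  R <- matrix(0, nrow(freq), nrow(freq))
  ok <- !degenerate
  if (sum(ok) >= 2L) R[ok, ok] <- stats::cor(t(freq[ok, , drop = FALSE]))
  diag(R) <- 1
  if (all(degenerate)) stop("all frequency vectors have zero variance")
  if (any(degenerate))
    warning(sum(degenerate), " zero-variance frequency vector(s); their ",
            "correlations are set to 0")
  ids <- rownames(freq)
  dimnames(R) <- list(ids, ids)
  structure(list(condition = condition, probe_ids = ids, R = R,
                 tau = NULL, L = NULL, degrees = NULL),
            class = "corr_network")
}

#' Hard-threshold adjacency and connectivity
#'
#' Declares probes `i` and `j` connected when `tau <= |r_ij| <= 1`
#' (inclusive at both ends), ignores autocorrelation (zero diagonal), and
#' counts each probe's connections — its connectivity (degree)
#' `l_i = sum_j l_ij`.
#'
#' @param network A `"corr_network"` with `R` computed.
#' @param tau Correlation threshold in `(0, 1]`; default 0.7.
#' @return The network with binary adjacency `L` and integer `degrees`
#'   filled, and `tau` recorded.
#' @export
threshold_adjacency <- function(network, tau = 0.7) {
  stopifnot(inherits(network, "corr_network"))
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0 || tau > 1)
    stop("'tau' must lie in (0, 1]")
  a <- abs(network$R)
  L <- (a >= tau & a <= 1 + 1e-12) * 1L
  diag(L) <- 0L
  network$tau <- tau
  network$L <- L
  network$degrees <- stats::setNames(as.integer(rowSums(L)),
                                     network$probe_ids)
  network
}

#' @export
print.corr_network <- function(x, ...) {
  cat("Correlation network", if (!is.null(x$condition))
    paste0("(", x$condition, ")"), "\n")
  cat("  probes:", length(x$probe_ids), "\n")
  if (!is.null(x$L))
    cat("  tau:", x$tau, "  edges:", sum(x$L) / 2L,
        "  mean degree:", signif(mean(x$degrees), 4), "\n")
  invisible(x)
}

#' Per-probe connectivity difference between two conditions
#'
#' For each probe, `m_i = l_i(first) - l_i(second)` — in the light-dark
#' study, LD minus DD, so a negative `m_i` means the probe is more
#' connected under constant darkness.
#'
#' @param net1,net2 Thresholded `"corr_network"` objects with identical
#'   probe order (conventionally LD first, DD second).
#' @return Object of class `"conn_diff"`: data frame with columns
#'   `probe_id`, `degree_1`, `degree_2`, `m`, plus attributes `conditions`
#'   and `counts` (named vector `negative`, `positive`, `zero`).
#' @export
connectivity_difference <- function(net1, net2) {
  stopifnot(inherits(net1, "corr_network"), inherits(net2, "corr_network"))
  if (is.null(net1$degrees) || is.null(net2$degrees))
    stop("apply threshold_adjacency() to both networks first")
  if (!identical(net1$probe_ids, net2$probe_ids))
    stop("probe order differs between the two networks")
  m <- net1$degrees - net2$degrees
  out <- data.frame(probe_id = net1$probe_ids,
                    degree_1 = as.integer(net1$degrees),
                    degree_2 = as.integer(net2$degrees),
                    m = as.integer(m), stringsAsFactors = FALSE,
                    row.names = NULL)
  conds <- c(net1$condition, net2$condition)
  if (!is.null(net1$condition) && !is.null(net2$condition))
    names(out)[2:3] <- paste0("degree_", conds)
  structure(out,
            conditions = conds,
            counts = c(negative = sum(m < 0), positive = sum(m > 0),
                       zero = sum(m == 0)),
            class = c("conn_diff", "data.frame"))
}

#' Square ratios of the connectivity differences
#'
#' The share of the total sum of squared connectivity differences carried
#' by the negative (and positive) differences:
#' `S_neg = sum(m_i^2; m_i < 0) / sum(m_i^2)` and correspondingly `S_pos`,
#' so `S_neg + S_pos = 1` whenever some difference is nonzero.
#'
#' @param diff A `"conn_diff"` table.
#' @return Named list with `S_neg` and `S_pos`, each in `[0, 1]`.
#' @export
square_ratio <- function(diff) {
  stopifnot(inherits(diff, "conn_diff"))
  m <- as.numeric(diff$m)
  tot <- sum(m^2)
  if (tot == 0) stop("all connectivity differences are zero; ratio undefined")
  list(S_neg = sum(m[m < 0]^2) / tot, S_pos = sum(m[m > 0]^2) / tot)
}

#' Select key probes from the tails of the difference curve
#'
#' Splits the connectivity differences into the negative and positive
#' branches and selects the extreme tail of each. With manual thresholds the
#' comparisons are inclusive: a probe is selected when `m <= neg_threshold`
#' or `m >= pos_threshold` (degrees are integers, so a published real-valued
#' knee such as -19.88 acts as `m <= -20`). Without a manual threshold each
#' branch is sorted ascending (negative branch: most negative first) and
#' its knee located by [find_inflection()]; the extreme side of the knee is
#' selected — ranks strictly below the knee index on the negative branch,
#' strictly above it on the positive branch — mirroring the screening rule.
#' An empty branch yields an empty selection with a warning; a branch too
#' short for a knee search (under 5 values) is selected whole.
#'
#' @param diff A `"conn_diff"` table.
#' @param neg_threshold,pos_threshold Optional manual thresholds for the
#'   negative and positive branches.
#' @param window Smoothing width for the automatic knee search.
#' @return The table with logical columns `selected_neg` and `selected_pos`
#'   added, and attribute `selection`: list with per-branch `threshold`,
#'   `n`, and `ids`.
#' @export
select_key_probes <- function(diff, neg_threshold = NULL,
                              pos_threshold = NULL, window = NULL) {
  stopifnot(inherits(diff, "conn_diff"))
  m <- diff$m
  branch_threshold <- function(vals, manual, side) {
    # vals: one branch sorted ascending; returns inclusive threshold on m
    # (NA = select nothing on this branch)
    if (length(vals) == 0L) {
      warning("empty branch; nothing selected")
      return(NA_real_)
    }
    if (!is.null(manual)) return(manual)
    n <- length(vals)
    if (n < 5L)                       # tiny branch: take it whole
      return(if (side == "neg") vals[n] else vals[1L])
    idx <- find_inflection(vals, window = window)$index
    if (side == "neg") {
      if (idx <= 1L) NA_real_ else vals[idx - 1L]
    } else {
      if (idx >= n) NA_real_ else vals[idx + 1L]
    }
  }
  thr_neg <- branch_threshold(sort(m[m < 0]), neg_threshold, "neg")
  thr_pos <- branch_threshold(sort(m[m > 0]), pos_threshold, "pos")
  diff$selected_neg <- !is.na(thr_neg) & m < 0 & m <= thr_neg
  diff$selected_pos <- !is.na(thr_pos) & m > 0 & m >= thr_pos
  attr(diff, "selection") <- list(
    negative = list(threshold = thr_neg, n = sum(diff$selected_neg),
                    ids = diff$probe_id[diff$selected_neg]),
    positive = list(threshold = thr_pos, n = sum(diff$selected_pos),
                    ids = diff$probe_id[diff$selected_pos]))
  diff
}
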