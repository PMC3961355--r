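#' Euclidean distance between a probe's profiles in two conditions
#'
#' @param x,y Numeric vectors of equal length (one probe's normalized
#'   profile in each condition).
#' @return Nonnegative scalar `sqrt(sum((x - y)^2))`.
#' @export
euclidean_distance <- function(x, y) {
  if (length(x) != length(y)) stop("profiles differ in length")
  sqrt(sum((x - y)^2))
}

#' Rank probes by between-condition expression distance
#'
#' Computes every probe's Euclidean distance between its normalized profiles
#' in the two conditions and sorts ascending. A large distance flags a probe
#' whose temporal expression pattern differs strongly between conditions.
#'
#' @param dataset A normalized, replicate-averaged two-condition
#'   `expr_dataset`.
#' @param conditions Length-2 character vector naming the conditions to
#'   compare (default: the dataset's first two).
#' @return Object of class `"distance_ranking"`: a data frame with columns
#'   `probe_id` and `distance`, sorted by ascending distance (ties keep
#'   original probe order).
#' @export
profile_distances <- function(dataset, conditions = NULL) {
  stopifnot(inherits(dataset, "expr_dataset"))
  if (is.null(conditions)) conditions <- dataset$conditions[1:2]
  a <- profile_matrix(dataset, conditions[1L])
  b <- profile_matrix(dataset, conditions[2L])
  d <- sqrt(rowSums((a - b)^2))
  ord <- order(d)
  structure(data.frame(probe_id = dataset$probe_ids[ord], distance = d[ord],
                       stringsAsFactors = FALSE),
            class = c("distance_ranking", "data.frame"))
}

#' Moving-average smoothing with shrinking edge windows
#'
#' Centered moving average of width `window` (odd); near the ends the window
#' shrinks symmetrically so every point is an average of observed values.
#'
#' @param values Numeric vector.
#' @param window Odd positive integer, `<= length(values)`.
#' @return Smoothed numeric vector of the same length.
#' @keywords internal
smooth_moving_average <- function(values, window) {
  n <- length(values)
  if (window < 1L || window %% 2L == 0L || window > n)
    stop("'window' must be an odd positive integer <= length(values)")
  if (window == 1L) return(values)
  half <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, values))
  i <- seq_len(n)
  k <- pmin(half, i - 1L, n - i)   # shrink symmetrically at edges
  (cs[i + k + 1L] - cs[i - k]) / (2L * k + 1L)
}

default_window <- function(n) {
  if (n > 1000L) return(101L)
  w <- max(1L, round(0.05 * n))
  if (w %% 2L == 0L) w <- w + 1L
  min(w, if (n %% 2L == 1L) n else n - 1L)
}

#' Find the knee of a sorted curve
#'
#' Smooths an ascending sequence with a centered moving average and locates
#' its inflection (knee) point by one of three rules:
#' \describe{
#'   \item{`"chord"` (default)}{the index of the smoothed curve farthest
#'     from the straight line joining its two endpoints, computed after
#'     rescaling both axes to the unit interval. This max-distance rule is
#'     invariant to affine changes of either axis and robust to local
#'     bumps, which matters when the curve's value range dwarfs its index
#'     range.}
#'   \item{`"curvature"`}{the index maximizing the discrete curvature
#'     `|s''| / (1 + s'^2)^(3/2)` of the raw smoothed sequence (central
#'     differences). Not scale-invariant: with steep curves the denominator
#'     suppresses the true knee, so prefer `"chord"` unless the axes are
#'     comparably scaled.}
#'   \item{`"manual"`}{the first index whose smoothed value reaches
#'     `threshold`, so a published knee value can be applied directly.}
#' }
#' Ties take the earliest index, with a warning when the optimum is not
#' unique (e.g. a strictly linear sequence).
#'
#' @param values Ascending numeric sequence (length >= 3 for `"chord"`,
#'   >= 5 for `"curvature"`).
#' @param window Odd smoothing width; default 101 for sequences longer than
#'   1000, otherwise about 5\% of the length rounded to odd.
#' @param method `"chord"`, `"curvature"` or `"manual"`.
#' @param threshold Manual threshold (required for `method = "manual"`; must
#'   lie within the value range).
#' @return List with `index`, `value` (smoothed value at the index),
#'   `window` and `method`.
#' @examples
#' v <- c(rep(0, 50), seq_len(30))            # hockey stick
#' find_inflection(v, window = 1)$index        # the breakpoint
#' @export
find_inflection <- function(values, window = NULL,
                            method = c("chord", "curvature", "manual"),
                            threshold = NULL) {
  method <- match.arg(method)
  n <- length(values)
  if (is.null(window)) window <- default_window(n)
  s <- smooth_moving_average(values, window)
  if (method == "manual") {
    if (is.null(threshold)) stop("manual method needs 'threshold'")
    if (threshold > max(s) || threshold < min(s))
      stop("manual threshold ", threshold, " is outside the smoothed range [",
           signif(min(s), 4), ", ", signif(max(s), 4), "]")
    idx <- which(s >= threshold)[1L]
    return(list(index = idx, value = s[idx], window = window,
                method = method))
  }
  crit <- if (method == "curvature") {
    if (n < 5L) stop("curvature method needs at least 5 values")
    i <- 2:(n - 1L)
    d1 <- (s[i + 1L] - s[i - 1L]) / 2
    d2 <- s[i + 1L] - 2 * s[i] + s[i - 1L]
    stats::setNames(abs(d2) / (1 + d1^2)^1.5, i)
  } else {
    if (n < 3L) stop("chord method needs at least 3 values")
    x <- (seq_len(n) - 1) / (n - 1)
    rng <- max(s) - min(s)
    y <- if (rng > 0) (s - min(s)) / rng else rep(0, n)
    stats::setNames(abs((y[n] - y[1L]) * x - (x[n] - x[1L]) * y +
                          x[n] * y[1L] - y[n] * x[1L]), seq_len(n))
  }
  top <- which(crit >= max(crit) - 1e-12)
  if (length(top) > 1L)
    warning("knee criterion maximum is not unique; ",
            "returning the earliest index")
  idx <- as.integer(names(crit)[top[1L]])
  list(index = idx, value = s[idx], window = window, method = method)
}

#' Select high-distance probes above the curve knee
#'
#' Flags the probes whose between-condition distance exceeds the selection
#' threshold. With a manual `threshold` `t` the selection is exactly
#' `{probes with distance > t}` (strict, so a published knee value
#' reproduces the published count). Without one, the knee of the smoothed
#' sorted-distance curve is found by [find_inflection()] and probes ranked
#' strictly above the knee index are selected.
#'
#' @param ranking A `"distance_ranking"` from [profile_distances()].
#' @param threshold Optional manual distance threshold.
#' @param window Smoothing width passed to [find_inflection()].
#' @return The ranking with an added logical column `selected`, plus
#'   attributes `inflection` (list with `index`, `value`) and
#'   `selected_ids`.
#' @export
select_important <- function(ranking, threshold = NULL, window = NULL) {
  stopifnot(inherits(ranking, "distance_ranking"))
  d <- ranking$distance
  n <- length(d)
  if (!is.null(threshold)) {
    sel <- d > threshold
    infl <- list(index = n - sum(sel), value = threshold, method = "manual")
  } else if (length(unique(d)) == 1L) {
    warning("all distances are equal; nothing selected")
    sel <- rep(FALSE, n)
    infl <- list(index = n, value = d[1L], method = "degenerate")
  } else {
    infl <- find_inflection(d, window = window)
    sel <- seq_len(n) > infl$index
  }
  ranking$selected <- sel
  attr(ranking, "inflection") <- infl
  attr(ranking, "selected_ids") <- ranking$probe_id[sel]
  message("distance screening: ", sum(sel), " of ", n,
          " probes selected (knee index ", infl$index, ", value ",
          signif(infl$value, 4), ")")
  ranking
}
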