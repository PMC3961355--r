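#' @name wavelet
#' @title Level-1 discrete wavelet transform of expression profiles
#'
#' @description
#' One level of the Mallat pyramid algorithm with dyadic dilation and
#' translation (both bases fixed at 2) and periodic boundary handling. A
#' 12-point profile yields 6 approximation (low-pass) coefficients `C` and 6
#' detail (high-pass) coefficients `D`; their concatenation `[C, D]` is the
#' 12-dimensional "frequency vector" used for correlation analysis. With an
#' orthonormal filter pair the transform conserves energy
#' (`||x||^2 == ||C||^2 + ||D||^2`) and is perfectly invertible.
#'
#' Supported bases: `"haar"` (default; for Haar,
#' `c_k = (x_{2k-1} + x_{2k}) / sqrt(2)` and
#' `d_k = (x_{2k-1} - x_{2k}) / sqrt(2)`), `"db2"`, `"db3"` (Daubechies
#' extremal-phase filters with periodic extension).
NULL

# orthonormal scaling (low-pass) filters; wavelet filter by QMF rule
wavelet_filters <- list(
  haar = c(1, 1) / sqrt(2),
  db2 = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2)),
  db3 = c(0.33267055295008263, 0.80689150931109257, 0.45987750211849154,
          -0.13501102001025458, -0.08544127388202666, 0.03522629188570953)
)

#' Analysis matrix of the periodized level-1 transform
#'
#' Rows `1..N/2` hold the even-shifted scaling filter, rows `N/2+1..N` the
#' even-shifted wavelet filter (quadrature mirror of the scaling filter), so
#' `W %*% x` is `c(approx, detail)` and `t(W)` inverts the transform.
#'
#' @param n Even signal length.
#' @param basis `"haar"`, `"db2"` or `"db3"`.
#' @return Orthogonal `n x n` matrix.
#' @keywords internal
dwt_matrix <- function(n, basis = "haar") {
  if (n %% 2L != 0L)
    stop("level-1 transform needs an even length; pad the profile explicitly")
  h <- wavelet_filters[[basis]]
  if (is.null(h)) stop("unknown wavelet basis '", basis, "'")
  L <- length(h)
  g <- (-1)^(seq_len(L) - 1L) * rev(h)
  W <- matrix(0, n, n)
  half <- n %/% 2L
  for (k in seq_len(half)) {
    idx <- ((2L * (k - 1L) + seq_len(L) - 1L) %% n) + 1L
    for (p in seq_len(L)) {
      W[k, idx[p]] <- W[k, idx[p]] + h[p]
      W[half + k, idx[p]] <- W[half + k, idx[p]] + g[p]
    }
  }
  W
}

#' Level-1 discrete wavelet transform of one profile
#'
#' @param profile Finite numeric vector of even length (12 in a two-day,
#'   4-hour-interval time course).
#' @param basis Wavelet basis name; see [wavelet].
#' @return List of class `"freq_vector"` with elements `approx`, `detail`
#'   (each length `length(profile)/2`), `combined` (their concatenation) and
#'   `basis`.
#' @examples
#' fv <- dwt_level1(c(1, 3, 2, 2, 0, 4, 1, 1, 2, 0, 3, 3))
#' sum(fv$combined^2) - sum(c(1, 3, 2, 2, 0, 4, 1, 1, 2, 0, 3, 3)^2)  # ~0
#' @export
dwt_level1 <- function(profile, basis = "haar") {
  if (!all(is.finite(profile))) stop("profile contains non-finite values")
  W <- dwt_matrix(length(profile), basis)
  co <- as.vector(W %*% profile)
  half <- length(profile) %/% 2L
  structure(list(approx = co[seq_len(half)], detail = co[half + seq_len(half)],
                 combined = co, basis = basis),
            class = "freq_vector")
}

#' Invert a level-1 discrete wavelet transform
#'
#' Exact inverse of [dwt_level1()] (the synthesis operator is the transpose
#' of the orthogonal analysis matrix).
#'
#' @param fv A `"freq_vector"`, or a list with `approx` and `detail` vectors
#'   of equal length.
#' @param basis Wavelet basis; defaults to the one recorded in `fv`.
#' @return Numeric vector of length `2 * length(approx)`.
#' @export
idwt_level1 <- function(fv, basis = NULL) {
  if (length(fv$approx) != length(fv$detail))
    stop("approx and detail coefficient vectors must have equal length")
  if (is.null(basis)) basis <- if (!is.null(fv$basis)) fv$basis else "haar"
  n <- 2L * length(fv$approx)
  as.vector(crossprod(dwt_matrix(n, basis), c(fv$approx, fv$detail)))
}

#' Frequency vectors for every probe in every condition
#'
#' Applies the level-1 transform to each normalized profile and stacks the
#' combined `[approx, detail]` vectors, one matrix per condition with
#' identical probe order, ready for frequency-domain correlation.
#'
#' @param dataset A normalized, replicate-averaged `expr_dataset` (typically
#'   the screened subset of probes).
#' @param basis Wavelet basis name; see [wavelet].
#' @return Object of class `"freq_vectors"`: named list of
#'   `probes x (2 * timepoints/2)` coefficient matrices (columns
#'   `c1..c6, d1..d6` for 12 timepoints), with attributes `basis` and
#'   `probe_ids`.
#' @export
build_frequency_vectors <- function(dataset, basis = "haar") {
  stopifnot(inherits(dataset, "expr_dataset"))
  n <- length(dataset$timepoints)
  W <- dwt_matrix(n, basis)
  half <- n %/% 2L
  out <- lapply(dataset$conditions, function(cn) {
    m <- profile_matrix(dataset, cn) %*% t(W)
    colnames(m) <- c(paste0("c", seq_len(half)), paste0("d", seq_len(half)))
    m
  })
  names(out) <- dataset$conditions
  structure(out, basis = basis, probe_ids = dataset$probe_ids,
            class = "freq_vectors")
}
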