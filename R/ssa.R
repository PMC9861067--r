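# Singular spectrum analysis: Hankel embedding, SVD, leading-group selection,
# diagonal-averaging reconstruction. Used to denoise the slow-time vital-sign
# signal before mode decomposition.

#' Default SSA window length for a series of length N
#'
#' 400 for the canonical 1000-sample (50 s at 20 Hz) record; otherwise
#' `round(0.4 * N)` capped at `floor(N/2) - 1`, preserving the same window
#' to record ratio while keeping L below N/2.
#'
#' @param N series length.
#' @return window length L.
#' @export
ssa_default_window <- function(N) {
  min(round(0.4 * N), floor(N / 2) - 1)
}

#' Number of SSA components retained by the critical-value rule
#'
#' The singular value at position `0.1 * L` of the (sorted) singular spectrum
#' marks the transition to the noise floor, so the leading `round(0.1 * L)`
#' components are kept (round-half-up). For the canonical L = 400 this gives
#' r = 40.
#'
#' @param L window length (>= 10).
#' @return integer r.
#' @export
ssa_group_count <- function(L) {
  if (L < 10) stop("the 0.1*L grouping rule needs L >= 10")
  as.integer(floor(0.1 * L + 0.5))
}

#' Hankel (trajectory-matrix) embedding of a series
#'
#' @param x numeric series of length N, or a [slow_time_signal()].
#' @param L window length, `2 <= L <= N/2`.
#' @return L x K trajectory matrix, K = N - L + 1, with
#'   `X[i, j] = x[i + j - 1]` (constant anti-diagonals).
#' @export
ssa_embed <- function(x, L) {
  if (inherits(x, "slow_time_signal")) x <- x$values
  N <- length(x)
  if (L < 2 || L > N / 2)
    stop(sprintf("window length L must satisfy 2 <= L <= N/2 (N = %d)", N))
  K <- N - L + 1
  X <- matrix(0, L, K)
  for (j in seq_len(K)) X[, j] <- x[j:(j + L - 1)]
  X
}

#' SVD of a trajectory matrix
#'
#' @param trajectory L x K Hankel matrix from [ssa_embed()].
#' @return object of class `ssa_decomposition`: `singulars` (nonincreasing),
#'   `left_vectors`, `right_vectors`, `d` (number of numerically nonzero
#'   singular values), `L`, `K`, `N`.
#' @export
ssa_decompose <- function(trajectory) {
  if (!all(is.finite(trajectory))) stop("non-finite entries in trajectory matrix")
  s <- svd(trajectory)
  tol <- max(dim(trajectory)) * .Machine$double.eps * max(s$d, 0)
  d <- sum(s$d > tol)
  structure(list(singulars = s$d, left_vectors = s$u, right_vectors = s$v,
                 d = d, L = nrow(trajectory), K = ncol(trajectory),
                 N = nrow(trajectory) + ncol(trajectory) - 1),
            class = "ssa_decomposition")
}

#' @export
print.ssa_decomposition <- function(x, ...) {
  cat(sprintf("<ssa_decomposition> L=%d, K=%d, d=%d nonzero singular values\n",
              x$L, x$K, x$d))
  invisible(x)
}

#' Reconstruct a series from selected SSA components
#'
#' Forms the low-rank matrix `sum_i s_i u_i v_i'` over the chosen components
#' and Hankelizes it back to a length-N series by averaging anti-diagonals
#' (edge diagonals are shorter, hence averaged over fewer terms).
#'
#' @param decomposition an `ssa_decomposition`.
#' @param r keep the leading r components (ignored when `components` given).
#' @param components explicit 1-based component indices.
#' @return numeric series of length N.
#' @export
ssa_reconstruct <- function(decomposition, r = NULL, components = NULL) {
  if (is.null(components)) {
    if (is.null(r)) stop("give r or components")
    if (r < 1 || r > decomposition$d)
      stop(sprintf("r must lie in 1..%d", decomposition$d))
    components <- seq_len(r)
  }
  if (any(components < 1 | components > length(decomposition$singulars)))
    stop("component index out of range")
  u <- decomposition$left_vectors[, components, drop = FALSE]
  v <- decomposition$right_vectors[, components, drop = FALSE]
  Y <- u %*% (decomposition$singulars[components] * t(v))
  diag_average(Y)
}

# Anti-diagonal (Hankel) averaging of an L x K matrix to a length-N series.
diag_average <- function(Y) {
  L <- nrow(Y); K <- ncol(Y); N <- L + K - 1
  out <- numeric(N); cnt <- numeric(N)
  for (j in seq_len(K)) {
    idx <- j:(j + L - 1)
    out[idx] <- out[idx] + Y[, j]
    cnt[idx] <- cnt[idx] + 1
  }
  out / cnt
}

#' SSA denoising of a slow-time signal
#'
#' Embed with window `L`, decompose, keep the leading `r` components
#' (defaulting to the 0.1*L critical-value rule), reconstruct.
#'
#' @param signal a [slow_time_signal()] or numeric vector.
#' @param L window length; default [ssa_default_window()] of the series
#'   length (400 for N = 1000).
#' @param r number of retained components; default [ssa_group_count()] of L,
#'   capped at the numerical rank.
#' @return same type as the input (`slow_time_signal` in, `slow_time_signal`
#'   out).
#' @export
ssa_denoise <- function(signal, L = NULL, r = NULL) {
  x <- if (inherits(signal, "slow_time_signal")) signal$values else signal
  if (is.null(L)) L <- ssa_default_window(length(x))
  dec <- ssa_decompose(ssa_embed(x, L))
  if (is.null(r)) r <- min(ssa_group_count(L), dec$d)
  y <- ssa_reconstruct(dec, r = r)
  if (inherits(signal, "slow_time_signal")) slow_time_signal(y, signal$Ts) else y
}
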