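# Clutter suppression by singular-value selection and maximum-energy range
# gate extraction.

#' One-dimensional slow-time vital-sign signal
#'
#' @param values numeric vector of length N (>= 2), the time series of one
#'   range gate.
#' @param Ts slow-time sampling interval (s).
#' @return object of class `slow_time_signal`.
#' @export
slow_time_signal <- function(values, Ts) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("a slow-time signal needs at least 2 samples")
  if (!all(is.finite(values))) stop("slow-time signal must be finite")
  stopifnot(Ts > 0)
  structure(list(values = values, Ts = Ts), class = "slow_time_signal")
}

#' @export
print.slow_time_signal <- function(x, ...) {
  cat(sprintf("<slow_time_signal> %d samples at %.1f Hz (%.1f s)\n",
              length(x$values), 1 / x$Ts, length(x$values) * x$Ts))
  invisible(x)
}

as_matrix_values <- function(x) {
  if (inherits(x, "echo_matrix")) x$values else as.matrix(x)
}

#' Singular value decomposition of an echo matrix
#'
#' Economy SVD `R = U diag(s) V'` with a fixed sign convention (the
#' largest-magnitude entry of each left singular vector is positive) so that
#' reconstructions are reproducible across linear-algebra backends.
#'
#' @param echo an [echo_matrix()] or plain numeric matrix.
#' @return object of class `svd_factors`: `left_vectors` (M x A),
#'   `singulars` (length A, nonincreasing), `right_vectors` (N x A),
#'   A = min(M, N), plus the input's metadata for reconstruction.
#' @export
svd_factorize <- function(echo) {
  vals <- as_matrix_values(echo)
  if (!all(is.finite(vals))) stop("non-finite entries in input matrix")
  s <- svd(vals)
  for (i in seq_along(s$d)) {
    j <- which.max(abs(s$u[, i]))
    if (s$u[j, i] < 0) {
      s$u[, i] <- -s$u[, i]
      s$v[, i] <- -s$v[, i]
    }
  }
  structure(list(left_vectors = s$u, singulars = s$d, right_vectors = s$v,
                 delta_T = if (inherits(echo, "echo_matrix")) echo$delta_T else NULL,
                 Ts = if (inherits(echo, "echo_matrix")) echo$Ts else NULL,
                 motion = if (inherits(echo, "echo_matrix")) echo$motion else NULL),
            class = "svd_factors")
}

#' @export
print.svd_factors <- function(x, ...) {
  cat(sprintf("<svd_factors> %d x %d, %d singular values (top: %s)\n",
              nrow(x$left_vectors), nrow(x$right_vectors),
              length(x$singulars),
              paste(signif(utils::head(x$singulars, 4), 4), collapse = ", ")))
  invisible(x)
}

#' Reconstruct an echo matrix from selected singular components
#'
#' Sums the kept rank-1 components `s_i u_i v_i'`. The default `keep = 2`
#' retains only the second singular component: the first carries static
#' clutter plus DC, the trailing ones carry noise, so this single component
#' is the standard clutter-suppressed echo. `keep = 2:4` is also meaningful
#' when the chest return spreads over several components.
#'
#' @param factors an `svd_factors` object from [svd_factorize()].
#' @param keep integer vector of 1-based singular-value indices to retain.
#' @return an [echo_matrix()] when the factors carry metadata, otherwise a
#'   plain matrix.
#' @export
svd_reconstruct <- function(factors, keep = 2L) {
  keep <- as.integer(keep)
  A <- length(factors$singulars)
  if (length(keep) == 0L) stop("keep set must not be empty")
  if (any(keep < 1L | keep > A))
    stop(sprintf("keep indices must lie in 1..%d", A))
  u <- factors$left_vectors[, keep, drop = FALSE]
  v <- factors$right_vectors[, keep, drop = FALSE]
  vals <- u %*% (factors$singulars[keep] * t(v))
  if (!is.null(factors$delta_T))
    echo_matrix(vals, factors$delta_T, factors$Ts, motion = factors$motion)
  else vals
}

#' Clutter-suppress an echo matrix in one step
#'
#' @inheritParams svd_factorize
#' @inheritParams svd_reconstruct
#' @return same as [svd_reconstruct()].
#' @export
clutter_suppress <- function(echo, keep = 2L) {
  svd_reconstruct(svd_factorize(echo), keep = keep)
}

#' Maximum distance gate selection
#'
#' After clutter suppression the vital-sign return dominates the echo's
#' energy. Each fast-time row's energy is `E_m = sum_i R[m,i]^2`; the row
#' attaining the maximum (smallest index on ties) is the selected range gate
#' and its slow-time slice is the one-dimensional vital-sign signal.
#'
#' @param echo an [echo_matrix()] or numeric matrix (then `Ts` is required).
#' @param Ts slow-time interval, only for plain-matrix input.
#' @return object of class `gate_selection`: `energies`, `gate_index`
#'   (1-based), `range_m` (when metadata available) and `signal`
#'   (a [slow_time_signal()]).
#' @export
select_max_gate <- function(echo, Ts = NULL) {
  vals <- as_matrix_values(echo)
  if (inherits(echo, "echo_matrix")) Ts <- echo$Ts
  if (is.null(Ts)) stop("Ts required for plain-matrix input")
  energies <- rowSums(vals^2)
  if (all(energies == 0)) stop("all-zero matrix: no range gate defined")
  gate <- which.max(energies)  # which.max returns the first maximum
  structure(list(
    energies = energies,
    gate_index = gate,
    range_m = if (inherits(echo, "echo_matrix")) range_axis(echo)[gate] else NA_real_,
    signal = slow_time_signal(vals[gate, ], Ts)
  ), class = "gate_selection")
}

#' @export
print.gate_selection <- function(x, ...) {
  cat(sprintf("<gate_selection> gate %d (%.3f m), energy %.4g\n",
              x$gate_index, x$range_m, x$energies[x$gate_index]))
  invisible(x)
}
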