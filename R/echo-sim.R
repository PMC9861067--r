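# Physics-based UWB impulse-radar echo simulator: dual-sinusoid chest motion,
# first-order Gaussian pulse, static reflectors, DC offset, additive noise.

#' Speed of light used throughout the package (m/s)
#' @keywords internal
C_LIGHT <- 2.998e8

#' Chest motion parameters
#'
#' Ground-truth kinematics of a simulated subject's thorax: the instantaneous
#' antenna-to-chest distance is
#' \deqn{d(t) = d_0 + A_r \sin(2\pi f_r t) + A_h \sin(2\pi f_h t)}
#' the superposition of a respiration and a (much weaker) heartbeat
#' displacement.
#'
#' @param d0 mean antenna-to-thorax distance (m), > 0.
#' @param Ar respiration displacement amplitude (m). Default 4 mm, a typical
#'   resting chest excursion.
#' @param fr respiration frequency (Hz).
#' @param Ah heartbeat displacement amplitude (m). Default 0.3 mm: heartbeat
#'   chest motion is roughly an order of magnitude weaker than breathing,
#'   which is what makes heart-rate extraction hard.
#' @param fh heartbeat frequency (Hz).
#' @return object of class `chest_motion`.
#' @export
chest_motion <- function(d0 = 0.6, Ar = 0.004, fr = 0.267, Ah = 3e-4, fh = 1.5) {
  stopifnot(d0 > 0, Ar >= 0, Ah >= 0, fr >= 0, fh >= 0)
  if (Ar + Ah >= d0)
    stop("total displacement amplitude Ar + Ah must be smaller than d0")
  structure(list(d0 = d0, Ar = Ar, fr = fr, Ah = Ah, fh = fh),
            class = "chest_motion")
}

#' Static environment of a simulated measurement
#'
#' @param av reflection coefficient of the thorax (dimensionless amplitude
#'   scale of the chest return).
#' @param statics list of static reflectors, each `c(range_m, coefficient)`;
#'   constant along slow time, removed later by clutter suppression.
#' @param dc_offset constant additive level on every matrix entry (receiver
#'   baseline drift).
#' @param noise_sigma standard deviation of i.i.d. additive white Gaussian
#'   noise per matrix entry; see [snr_to_noise_sigma()] to derive it from a
#'   target chest-return SNR.
#' @return object of class `radar_scene`.
#' @export
radar_scene <- function(av = 1, statics = list(c(0.3, 1.5)), dc_offset = 0.02,
                        noise_sigma = 0) {
  stopifnot(is.numeric(av), length(av) == 1L, noise_sigma >= 0)
  statics <- lapply(statics, function(s) {
    s <- as.numeric(s)
    if (length(s) != 2L || s[1] < 0)
      stop("each static reflector must be c(range_m >= 0, coefficient)")
    s
  })
  structure(list(av = av, statics = statics, dc_offset = dc_offset,
                 noise_sigma = noise_sigma),
            class = "radar_scene")
}

#' Radar acquisition configuration
#'
#' Defaults follow a 7.29 GHz centre-frequency UWB module observed over a
#' 1.5 m range window for 50 s: fast-time sampling at 23.328 GHz (Nyquist-safe
#' for the RF pulse), 234 fast-time rows covering 0--1.5 m, and a 20 Hz
#' slow-time frame rate giving N = 1000 frames.
#'
#' @param delta_T fast-time sampling interval (s).
#' @param Ts slow-time sampling interval (s).
#' @param M number of fast-time samples (rows).
#' @param N number of slow-time frames (columns).
#' @param fc pulse centre frequency (Hz).
#' @param pulse_sigma Gaussian envelope width parameter (s); the default
#'   0.345 ns gives roughly a 1.4 GHz -10 dB bandwidth.
#' @return object of class `radar_config`.
#' @export
radar_config <- function(delta_T = 1 / 23.328e9, Ts = 0.05, M = 234L,
                         N = 1000L, fc = 7.29e9, pulse_sigma = 3.45e-10) {
  stopifnot(M >= 2, N >= 2, delta_T > 0, Ts > 0, pulse_sigma > 0, fc >= 0)
  if (1 / delta_T <= 2 * fc)
    stop("fast-time rate 1/delta_T must exceed 2*fc (RF Nyquist)")
  structure(list(delta_T = delta_T, Ts = Ts, M = as.integer(M),
                 N = as.integer(N), fc = fc, pulse_sigma = pulse_sigma,
                 c = C_LIGHT),
            class = "radar_config")
}

#' Fast-time range window covered by a configuration (m)
#' @param config a [radar_config()].
#' @return maximum one-way range, `M * delta_T * c / 2`.
#' @export
range_window <- function(config) config$M * config$delta_T * config$c / 2

#' Instantaneous antenna-to-chest distance
#'
#' @param t time (s), vectorised.
#' @param motion a [chest_motion()].
#' @return distance(s) in metres.
#' @export
chest_distance <- function(t, motion) {
  motion$d0 + motion$Ar * sin(2 * pi * motion$fr * t) +
    motion$Ah * sin(2 * pi * motion$fh * t)
}

#' First-order Gaussian radar pulse
#'
#' Derivative-of-Gaussian envelope modulated to the carrier:
#' \deqn{s(\tau) = -\frac{\tau}{\sigma^2} e^{-\tau^2/(2\sigma^2)}
#'       \cos(2\pi f_c \tau)}
#'
#' @param tau fast-time offset from the pulse centre (s), vectorised.
#' @param config a [radar_config()] supplying `fc` and `pulse_sigma`.
#' @return pulse amplitude(s).
#' @export
pulse_waveform <- function(tau, config) {
  s2 <- config$pulse_sigma^2
  -(tau / s2) * exp(-tau^2 / (2 * s2)) * cos(2 * pi * config$fc * tau)
}

#' Echo matrix container
#'
#' The central exchange format between pipeline stages: an M (fast-time) by
#' N (slow-time) real matrix with its two sampling intervals and, for
#' simulated data, the ground-truth motion.
#'
#' @param values M x N numeric matrix, rows = fast-time (range), columns =
#'   slow-time (frames).
#' @param delta_T fast-time sampling interval (s).
#' @param Ts slow-time sampling interval (s).
#' @param motion optional [chest_motion()] ground truth carried as metadata.
#' @return object of class `echo_matrix`.
#' @export
echo_matrix <- function(values, delta_T, Ts, motion = NULL) {
  values <- as.matrix(values)
  if (!all(is.finite(values))) stop("echo matrix entries must be finite")
  stopifnot(delta_T > 0, Ts > 0)
  structure(list(values = values, delta_T = delta_T, Ts = Ts,
                 motion = motion),
            class = "echo_matrix")
}

#' Per-row range axis of an echo matrix (m)
#' @param echo an [echo_matrix()].
#' @return numeric vector, row m (1-based) maps to `(m-1) * delta_T * c / 2`.
#' @export
range_axis <- function(echo) {
  (seq_len(nrow(echo$values)) - 1) * echo$delta_T * C_LIGHT / 2
}

#' @export
print.echo_matrix <- function(x, ...) {
  cat(sprintf("<echo_matrix> %d fast-time rows x %d slow-time frames\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  range window %.3f m (%.2f mm/row), frame rate %.1f Hz, %.1f s record\n",
              nrow(x$values) * x$delta_T * C_LIGHT / 2,
              x$delta_T * C_LIGHT / 2 * 1e3, 1 / x$Ts,
              ncol(x$values) * x$Ts))
  if (!is.null(x$motion))
    cat(sprintf("  ground truth: d0=%.2f m, fr=%.3f Hz, fh=%.3f Hz\n",
                x$motion$d0, x$motion$fr, x$motion$fh))
  invisible(x)
}

# Noiseless deterministic part of the echo (chest + statics + DC).
echo_deterministic <- function(config, scene, motion) {
  ft <- (0:(config$M - 1)) * config$delta_T
  st <- (0:(config$N - 1)) * config$Ts
  delays <- 2 * chest_distance(st, motion) / config$c
  vals <- scene$av * outer(ft, delays, function(a, b) pulse_waveform(a - b, config))
  static_col <- rep(0, config$M)
  for (s in scene$statics)
    static_col <- static_col + s[2] * pulse_waveform(ft - 2 * s[1] / config$c, config)
  vals + static_col + scene$dc_offset
}

#' Synthesize a UWB radar echo matrix
#'
#' Entry `[m, n]` is the chest return
#' `av * s(m*delta_T - 2*d(n*Ts)/c)` plus the static reflector returns, a DC
#' offset, and i.i.d. Gaussian noise drawn reproducibly from `seed`. The
#' caller's RNG state is left untouched.
#'
#' @param config a [radar_config()].
#' @param scene a [radar_scene()].
#' @param motion a [chest_motion()].
#' @param seed integer seed for the noise draw.
#' @return an [echo_matrix()] carrying `motion` as ground-truth metadata.
#' @export
synthesize_echo <- function(config, scene, motion, seed = 1L) {
  rmax <- motion$d0 + motion$Ar + motion$Ah
  for (s in scene$statics) rmax <- max(rmax, s[1])
  if (rmax > range_window(config))
    stop(sprintf("scene range %.2f m exceeds the fast-time window %.2f m",
                 rmax, range_window(config)))
  vals <- echo_deterministic(config, scene, motion)
  if (scene$noise_sigma > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old_seed)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old_seed, envir = globalenv())
    })
    set.seed(as.integer(seed))
    vals <- vals + matrix(stats::rnorm(length(vals), 0, scene$noise_sigma),
                          nrow(vals), ncol(vals))
  }
  echo_matrix(vals, config$delta_T, config$Ts, motion = motion)
}

#' Noise level for a target chest-return SNR
#'
#' The signal of interest is the slow-time *modulation* of the chest return,
#' not its static pedestal, so SNR is defined against the mean-removed power
#' of the noiseless chest-only echo at its most strongly modulated range
#' gate: `sigma = sqrt(P_ac / 10^(snr_db/10))`.
#'
#' @param snr_db target chest-return SNR in dB (0 dB: per-sample noise power
#'   equals the motion-modulated chest power).
#' @param config a [radar_config()].
#' @param motion a [chest_motion()].
#' @param av chest reflection coefficient.
#' @return noise standard deviation in matrix units.
#' @export
snr_to_noise_sigma <- function(snr_db, config, motion, av = 1) {
  chest_only <- echo_deterministic(config, radar_scene(av = av, statics = list(),
                                                       dc_offset = 0,
                                                       noise_sigma = 0),
                                   motion)
  ac <- chest_only - rowMeans(chest_only)
  p_ac <- max(rowMeans(ac^2))
  sqrt(p_ac / 10^(snr_db / 10))
}

#' Write / read an echo matrix as headerless CSV plus JSON sidecar
#'
#' Rows are fast-time, columns slow-time. The sidecar (`<path>.json`) stores
#' `delta_T`, `Ts` and any ground-truth motion so the matrix can be
#' round-tripped losslessly in plain text.
#'
#' @param echo an [echo_matrix()].
#' @param path CSV file path.
#' @return `write_echo_csv` returns `path` invisibly; `read_echo_csv` returns
#'   an [echo_matrix()].
#' @export
write_echo_csv <- function(echo, path) {
  utils::write.table(echo$values, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  meta <- list(delta_T = echo$delta_T, Ts = echo$Ts)
  if (!is.null(echo$motion)) meta$motion <- unclass(echo$motion)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_echo_csv
#' @param delta_T,Ts sampling intervals, required when no JSON sidecar exists.
#' @export
read_echo_csv <- function(path, delta_T = NULL, Ts = NULL) {
  vals <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(vals) <- NULL
  sidecar <- paste0(path, ".json")
  motion <- NULL
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(delta_T)) delta_T <- meta$delta_T
    if (is.null(Ts)) Ts <- meta$Ts
    if (!is.null(meta$motion)) motion <- do.call(chest_motion, meta$motion)
  }
  if (is.null(delta_T) || is.null(Ts))
    stop("delta_T and Ts must be given when there is no JSON sidecar")
  echo_matrix(vals, delta_T, Ts, motion = motion)
}

#' Binary echo container (RDS)
#'
#' Run-time convenience format holding the matrix plus all metadata in one
#' file.
#' @param echo an [echo_matrix()].
#' @param path file path.
#' @export
write_echo_rds <- function(echo, path) {
  saveRDS(echo, path)
  invisible(path)
}

#' @rdname write_echo_rds
#' @export
read_echo_rds <- function(path) {
  echo <- readRDS(path)
  if (!inherits(echo, "echo_matrix")) stop("file does not hold an echo_matrix")
  echo
}
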