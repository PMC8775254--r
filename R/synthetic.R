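#' Specification of a synthetic sEMG recording
#'
#' Describes a repetition-protocol recording in the style of the NinaPro
#' acquisitions: each gesture class is executed `reps` times, movements are
#' separated by rest, and every class is characterised by a per-channel
#' amplitude envelope that modulates zero-mean unit-variance Gaussian noise
#' (the standard surrogate model for surface EMG interference patterns).
#' Background Gaussian noise is added everywhere at the requested
#' signal-to-noise ratio. No motor-unit action-potential trains are
#' simulated: the generator targets amplitude/temporal structure, not
#' physiological waveform realism.
#'
#' @param G Number of gesture classes (`>= 2`).
#' @param C Number of channels (`>= 1`).
#' @param fs Sampling rate in Hz.
#' @param reps Movement repetitions per class.
#' @param movement_ms,rest_ms Movement and rest durations in milliseconds.
#' @param envelopes Either `NULL` (a deterministic default assignment of
#'   distinct per-class, per-channel envelopes) or a list of `G` lists of `C`
#'   descriptors `list(shape, peak, period_ms)` with
#'   `shape` in `"flat"`, `"ramp_up"`, `"ramp_down"`, `"burst"`; `period_ms`
#'   (optional) makes ramp envelopes periodic sawtooths instead of a single
#'   ramp across the movement.
#' @param snr_db Signal-to-noise ratio in dB between mean movement envelope
#'   power and background-noise power (default 20, a clean laboratory-grade
#'   surface recording).
#' @param seed Integer seed; the generator is pure — identical specs produce
#'   bit-identical recordings.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(G = 6L, C = 4L, fs = 200, reps = 6L,
                           movement_ms = 1000, rest_ms = 500,
                           envelopes = NULL, snr_db = 20, seed = 1L) {
  if (G < 2L) stop("need G >= 2 classes")
  if (C < 1L) stop("need C >= 1 channels")
  if (fs <= 0) stop("fs must be > 0")
  if (movement_ms <= 0 || rest_ms <= 0)
    stop("movement_ms and rest_ms must be > 0")
  if (is.null(envelopes)) envelopes <- default_envelopes(G, C)
  stopifnot(length(envelopes) == G, all(lengths(envelopes) == C))
  for (g in seq_len(G)) for (c in seq_len(C))
    if (envelopes[[g]][[c]]$peak <= 0) stop("envelope peaks must be > 0")
  structure(list(G = as.integer(G), C = as.integer(C), fs = fs,
                 reps = as.integer(reps), movement_ms = movement_ms,
                 rest_ms = rest_ms, envelopes = envelopes,
                 snr_db = snr_db, seed = as.integer(seed)),
            class = "synthetic_spec")
}

## deterministic distinct envelope assignment: shapes cycle with class,
## peaks vary with both class and channel so amplitude alone separates classes
default_envelopes <- function(G, C) {
  shapes <- c("flat", "burst", "ramp_up", "ramp_down")
  lapply(seq_len(G), function(g) {
    lapply(seq_len(C), function(c) {
      list(shape = shapes[(g + c - 2L) %% length(shapes) + 1L],
           peak = 0.5 + 1.5 * (((g - 1L) * C + (c - 1L)) %% (G * C)) / (G * C),
           period_ms = NULL)
    })
  })
}

#' Amplitude envelope of one class over one movement block
#'
#' @param spec A [synthetic_spec()].
#' @param g Class id in `1..G`.
#' @return Numeric `n_mov x C` matrix of envelope values, where `n_mov` is
#'   the movement duration in samples.
#' @export
class_envelope <- function(spec, g) {
  n <- as.integer(round(spec$movement_ms * spec$fs / 1000))
  env <- matrix(NA_real_, n, spec$C)
  for (c in seq_len(spec$C)) {
    d <- spec$envelopes[[g]][[c]]
    env[, c] <- envelope_shape(d$shape, d$peak, n, d$period_ms, spec$fs)
  }
  env
}

envelope_shape <- function(shape, peak, n, period_ms = NULL, fs = NULL) {
  t <- seq_len(n)
  if (shape %in% c("ramp_up", "ramp_down")) {
    P <- if (is.null(period_ms)) n else max(2L, as.integer(round(period_ms * fs / 1000)))
    phase <- ((t - 1L) %% P) / (P - 1L)           # 0..1 sawtooth
    if (shape == "ramp_down") phase <- 1 - phase
    0.1 * peak + 0.9 * peak * phase
  } else if (shape == "flat") {
    rep(peak, n)
  } else if (shape == "burst") {
    bump <- exp(-0.5 * ((t - (n + 1) / 2) / (n / 6))^2)
    0.05 * peak + 0.95 * peak * bump
  } else {
    stop("unknown envelope shape: ", shape)
  }
}

#' Generate a synthetic labeled recording
#'
#' Block layout: for each class `1..G`, `reps` repetitions of
#' (movement, rest). Movement samples carry the class label and an
#' incrementing per-class repetition number; rest samples carry label 0 and
#' repetition 0. The signal is `envelope x N(0,1)` noise during movements
#' plus background Gaussian noise everywhere, scaled so that the ratio of
#' mean movement envelope power to background power equals `snr_db`.
#'
#' @param spec A [synthetic_spec()].
#' @param subject Subject identifier stored in the recording.
#' @return A [raw_recording()].
#' @export
generate_recording <- function(spec, subject = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n_mov <- as.integer(round(spec$movement_ms * spec$fs / 1000))
  n_rest <- as.integer(round(spec$rest_ms * spec$fs / 1000))
  n_block <- n_mov + n_rest
  T_n <- spec$G * spec$reps * n_block
  envs <- lapply(seq_len(spec$G), function(g) class_envelope(spec, g))
  mean_power <- mean(vapply(envs, function(e) mean(e^2), numeric(1)))
  sd_bg <- sqrt(mean_power / 10^(spec$snr_db / 10))

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(spec$seed)

  signal <- matrix(stats::rnorm(T_n * spec$C, sd = sd_bg), T_n, spec$C)
  labels <- integer(T_n); repetition <- integer(T_n)
  pos <- 0L
  for (g in seq_len(spec$G)) {
    for (r in seq_len(spec$reps)) {
      idx <- pos + seq_len(n_mov)
      signal[idx, ] <- signal[idx, ] +
        envs[[g]] * matrix(stats::rnorm(n_mov * spec$C), n_mov, spec$C)
      labels[idx] <- g
      repetition[idx] <- r
      pos <- pos + n_block
    }
  }
  raw_recording(signal, spec$fs, labels, repetition, subject)
}

#' Derive an order-confusable two-class spec
#'
#' Builds a two-class spec whose classes share identical per-window amplitude
#' content but differ in temporal order: class 1 uses periodic rising-ramp
#' envelopes, class 2 the time-reversed falling ramps, with equal peaks on
#' every channel. The ramp period is set to the analysis window length, so
#' every full analysis window contains exactly the same multiset of envelope
#' values for both classes regardless of its offset — amplitude summaries
#' (per-window maxima, mean absolute value) cannot separate the pair, while
#' models that read temporal order can.
#'
#' @param base A [synthetic_spec()] supplying channels, rates, durations,
#'   repetitions, SNR and seed.
#' @param period_ms Ramp period in milliseconds; should equal the analysis
#'   window duration (default 250).
#' @param peak Common envelope peak for both classes on all channels.
#' @return A two-class `synthetic_spec`.
#' @export
make_confusable_pair <- function(base, period_ms = 250, peak = 1.5) {
  stopifnot(inherits(base, "synthetic_spec"))
  env <- list(
    lapply(seq_len(base$C), function(c)
      list(shape = "ramp_up", peak = peak, period_ms = period_ms)),
    lapply(seq_len(base$C), function(c)
      list(shape = "ramp_down", peak = peak, period_ms = period_ms))
  )
  synthetic_spec(G = 2L, C = base$C, fs = base$fs, reps = base$reps,
                 movement_ms = base$movement_ms, rest_ms = base$rest_ms,
                 envelopes = env, snr_db = base$snr_db, seed = base$seed)
}

#' Generate a pooled multi-subject recording set
#'
#' Emulates inter-subject variability by jittering every envelope peak by a
#' multiplicative factor drawn uniformly from `1 +/- jitter`, with a distinct
#' sub-seed per subject.
#'
#' @param spec A [synthetic_spec()] (the population-level conditions).
#' @param n_subjects Number of subjects.
#' @param jitter Relative envelope-peak jitter (default 0.2 = +/-20%).
#' @return A list of [raw_recording()]s, one per subject.
#' @export
generate_subjects <- function(spec, n_subjects = 3L, jitter = 0.2) {
  stopifnot(inherits(spec, "synthetic_spec"))
  lapply(seq_len(n_subjects), function(s) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(spec$seed + 7919L * s)
    env <- spec$envelopes
    for (g in seq_along(env)) for (c in seq_along(env[[g]]))
      env[[g]][[c]]$peak <- env[[g]][[c]]$peak * stats::runif(1, 1 - jitter, 1 + jitter)
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
    sub_spec <- spec
    sub_spec$envelopes <- env
    sub_spec$seed <- spec$seed + 104729L * s
    generate_recording(sub_spec, subject = s)
  })
}
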