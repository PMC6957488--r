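# In-memory event log. Generation and pipeline stages record structured
# events (clipped samples, skipped subjects, auto-reduced scales) here; the
# pipeline copies them into its run manifest.
.log_env <- new.env(parent = emptyenv())
.log_env$events <- list()

log_event <- function(type, ...) {
  .log_env$events[[length(.log_env$events) + 1L]] <-
    c(list(type = type), list(...))
  invisible(NULL)
}

#' Retrieve (and optionally clear) the structured event log
#'
#' @param clear reset the log after reading.
#' @return A list of events, each a named list with at least a `type` field.
#' @export
thermosat_log <- function(clear = FALSE) {
  ev <- .log_env$events
  if (clear) .log_env$events <- list()
  ev
}

TEMPS <- c("38", "40", "42", "44")

# named-over-temperature parameter: accept a scalar or a named vector
temp_map <- function(x, name) {
  if (length(x) == 1L && is.null(names(x)))
    x <- stats::setNames(rep(as.numeric(x), 4L), TEMPS)
  if (!all(TEMPS %in% names(x)))
    stop("`", name, "` must be a scalar or named over ", toString(TEMPS))
  as.numeric(x[TEMPS]) |> stats::setNames(TEMPS)
}

#' Configuration of the synthetic cohort generator
#'
#' Describes the recording protocol (sampling rate, epoch durations), the
#' temperature-dependent mean oxygen-saturation response, the noise model
#' (a white / 1-over-f mixture with tunable complexity), and the target rank
#' coupling between each perfusion speed component and oxygen saturation.
#'
#' The response shape is: flat baseline; saturating exponential rise of
#' height `response_amplitude_pct[T]` during stimulation, with time constant
#' `time_to_peak_s[T] / 3` (so the rise is ~95% complete at the nominal time
#' to peak); exponential return towards baseline at `post_decay_rate_per_s[T]`
#' after the stimulus ends. A zero decay rate freezes the post epoch at the
#' stimulation-end level (the high-temperature "no decay" regime). The blank
#' control is flat throughout.
#'
#' Coupling targets are Spearman correlations; internally they are converted
#' to mixing weights via the Gaussian rank-correlation identity
#' `lambda = 2 sin(pi * rho / 6)`, and each perfusion channel mixes the
#' normal-scores transform of the realised oxygen signal (weight `lambda`)
#' with private Gaussian noise. Because both streams are standard normal the
#' mapping weight -> rank correlation is exact in population, whatever the
#' thermal trend.
#'
#' @param sampling_rate_hz sampling rate (default 3 Hz).
#' @param epoch_minutes durations of baseline/stimulation/post in minutes
#'   (default 30/30/30); each epoch must contain a whole number (>= 2) of
#'   samples.
#' @param baseline_oxy_pct resting oxygen saturation level, percent.
#' @param response_amplitude_pct rise height per temperature (scalar or
#'   named vector over "38","40","42","44").
#' @param time_to_peak_s nominal time to peak per temperature, seconds.
#' @param post_decay_rate_per_s post-stimulus decay rate per temperature,
#'   per second (0 = no decay).
#' @param white_fraction weight of white noise in the white/1-over-f mixture,
#'   in \[0, 1\]; a scalar, or a named vector over conditions
#'   ("BC","38","40","42","44") to give conditions different complexity.
#' @param white_fraction_jitter_sd SD of a per-subject perturbation of
#'   `white_fraction` (clamped to \[0, 1\]); gives subjects individual signal
#'   complexity.
#' @param white_fraction_jitter `"shared"` applies one draw per subject to
#'   all channels (complexity co-varies across channels), `"independent"`
#'   draws per channel.
#' @param noise_sd SD of the oxygen-saturation noise, percentage points.
#' @param coupling target Spearman correlation between each perfusion
#'   component and oxygen saturation: a scalar, a named vector over
#'   conditions, or a named list condition -> named vector over V1/V2/V3.
#' @param perfusion_baseline mean perfusion level per channel, arbitrary
#'   perfusion units.
#' @param skin_temp_c unheated probe temperature trace level.
#' @param seed master seed for the generator.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(
    sampling_rate_hz = 3,
    epoch_minutes = c(30, 30, 30),
    baseline_oxy_pct = 50,
    response_amplitude_pct = c("38" = 4, "40" = 7, "42" = 9, "44" = 10),
    time_to_peak_s = c("38" = 1800, "40" = 900, "42" = 300, "44" = 300),
    post_decay_rate_per_s = c("38" = 1 / 300, "40" = 1 / 600,
                              "42" = 1 / 900, "44" = 0),
    white_fraction = 0.5,
    white_fraction_jitter_sd = 0,
    white_fraction_jitter = c("shared", "independent"),
    noise_sd = 2,
    coupling = c("BC" = 0.2, "38" = 0.5, "40" = 0.3, "42" = 0, "44" = -0.2),
    perfusion_baseline = c(V1 = 100, V2 = 50, V3 = 25),
    skin_temp_c = 32,
    seed = 1L) {
  white_fraction_jitter <- match.arg(white_fraction_jitter)
  stopifnot(is.finite(sampling_rate_hz), sampling_rate_hz > 0,
            length(epoch_minutes) == 3L, all(is.finite(epoch_minutes)),
            all(epoch_minutes > 0),
            is.finite(baseline_oxy_pct), baseline_oxy_pct > 0,
            baseline_oxy_pct < 100,
            is.finite(noise_sd), noise_sd > 0,
            is.finite(white_fraction_jitter_sd),
            white_fraction_jitter_sd >= 0)
  n_per <- epoch_minutes * 60 * sampling_rate_hz
  if (any(abs(n_per - round(n_per)) > 1e-9) || any(n_per < 2))
    stop("each epoch must contain a whole number (>= 2) of samples")

  amp <- temp_map(response_amplitude_pct, "response_amplitude_pct")
  ttp <- temp_map(time_to_peak_s, "time_to_peak_s")
  dec <- temp_map(post_decay_rate_per_s, "post_decay_rate_per_s")
  stopifnot(all(amp >= 0), all(ttp > 0), all(dec >= 0))

  wf <- if (length(white_fraction) == 1L && is.null(names(white_fraction)))
    stats::setNames(rep(white_fraction, 5L), CONDITIONS)
  else {
    if (!all(CONDITIONS %in% names(white_fraction)))
      stop("`white_fraction` must be scalar or named over ",
           toString(CONDITIONS))
    white_fraction[CONDITIONS]
  }
  if (any(wf < 0 | wf > 1)) stop("white_fraction must lie in [0, 1]")

  cpl <- coupling
  if (!is.list(cpl)) {
    if (length(cpl) == 1L && is.null(names(cpl)))
      cpl <- stats::setNames(rep(as.numeric(cpl), 5L), CONDITIONS)
    if (!all(CONDITIONS %in% names(cpl)))
      stop("`coupling` must be scalar, named over conditions, or a list")
    cpl <- lapply(stats::setNames(CONDITIONS, CONDITIONS),
                  function(cd) stats::setNames(rep(as.numeric(cpl[cd]), 3L),
                                               c("V1", "V2", "V3")))
  } else {
    cpl <- lapply(stats::setNames(CONDITIONS, CONDITIONS), function(cd) {
      v <- cpl[[cd]]
      if (is.null(v)) stop("coupling list missing condition ", cd)
      if (length(v) == 1L) v <- rep(as.numeric(v), 3L)
      stats::setNames(as.numeric(v)[1:3], c("V1", "V2", "V3"))
    })
  }
  if (any(abs(unlist(cpl)) > 1)) stop("coupling values must lie in [-1, 1]")

  stopifnot(all(c("V1", "V2", "V3") %in% names(perfusion_baseline)),
            all(perfusion_baseline > 0))

  structure(list(sampling_rate_hz = sampling_rate_hz,
                 epoch_minutes = as.numeric(epoch_minutes),
                 baseline_oxy_pct = baseline_oxy_pct,
                 response_amplitude_pct = amp, time_to_peak_s = ttp,
                 post_decay_rate_per_s = dec,
                 white_fraction = wf,
                 white_fraction_jitter_sd = white_fraction_jitter_sd,
                 white_fraction_jitter = white_fraction_jitter,
                 noise_sd = noise_sd, coupling = cpl,
                 perfusion_baseline = perfusion_baseline[c("V1", "V2", "V3")],
                 skin_temp_c = skin_temp_c, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Study design: groups, sizes and per-subject stimulation order
#'
#' The thermal-stimulation (TS) group contributes one recording per subject
#' per temperature (38/40/42/44), applied in a per-subject random order; the
#' blank-control (BC) group contributes one unheated recording per subject.
#'
#' @param ts_subjects number of TS subjects (default 29).
#' @param bc_subjects number of BC subjects (default 30).
#' @param seed seed for the per-subject stimulation-order permutations.
#' @return An object of class `study_design` with subject ids and each TS
#'   subject's stimulation order.
#' @export
study_design <- function(ts_subjects = 29L, bc_subjects = 30L, seed = 1L) {
  ts_subjects <- as.integer(ts_subjects)
  bc_subjects <- as.integer(bc_subjects)
  stopifnot(ts_subjects >= 1L, bc_subjects >= 1L)
  ts_ids <- sprintf("TS%02d", seq_len(ts_subjects))
  bc_ids <- sprintf("BC%02d", seq_len(bc_subjects))
  order <- lapply(seq_len(ts_subjects), function(i) {
    local_seed(derive_seed(seed, 1L, i), sample(TEMPS))
  })
  names(order) <- ts_ids
  structure(list(ts_ids = ts_ids, bc_ids = bc_ids,
                 conditions = CONDITIONS,
                 stimulation_order = order, seed = as.integer(seed)),
            class = "study_design")
}

#' Seeded white / 1-over-f noise mixture
#'
#' Returns `w * white + (1 - w) * pink`, where both components are
#' independently generated Gaussian streams (the 1/f component by spectral
#' shaping: the FFT of white noise is multiplied by a `1/sqrt(f)` amplitude
#' envelope with the DC bin zeroed). Each component is standardised to unit
#' sample SD before mixing and the mixture is centred and rescaled so the
#' output has sample mean 0 and sample SD exactly `sd`.
#'
#' @param n_samples number of samples (>= 2).
#' @param white_fraction mixing weight `w` in \[0, 1\]: 1 = pure white,
#'   0 = pure 1/f.
#' @param sd target sample SD of the output.
#' @param seed integer seed.
#' @return Numeric vector of length `n_samples`.
#' @export
generate_noise <- function(n_samples, white_fraction, sd = 1, seed = 1L) {
  n <- as.integer(n_samples)
  stopifnot(is.finite(n), n >= 2L,
            is.finite(white_fraction), white_fraction >= 0,
            white_fraction <= 1, is.finite(sd), sd > 0)
  local_seed(seed, {
    white <- rnorm(n)
    pink <- pink_noise(n)
    raw <- white_fraction * scale_unit(white) +
      (1 - white_fraction) * scale_unit(pink)
    raw <- raw - mean(raw)
    raw * (sd / stats::sd(raw))
  })
}

scale_unit <- function(x) x / stats::sd(x)

# 1/f noise by spectral shaping of Gaussian white noise. The symmetric
# 1/sqrt(f) amplitude envelope preserves the conjugate symmetry of the FFT,
# so the inverse transform is real up to rounding.
pink_noise <- function(n) {
  w <- rnorm(n)
  freq <- pmin(0:(n - 1), n - 0:(n - 1))
  amp <- ifelse(freq == 0, 0, 1 / sqrt(freq))
  Re(fft(fft(w) * amp, inverse = TRUE)) / n
}

#' Deterministic mean oxygen-saturation trajectory for one condition
#'
#' The noiseless response template evaluated on a time grid covering the
#' whole recording: flat at `baseline_oxy_pct` during baseline, a saturating
#' exponential rise during stimulation, exponential decay (or none) during
#' the post epoch. The BC condition returns the flat baseline throughout.
#'
#' @param condition `"BC"`, `"38"`, `"40"`, `"42"` or `"44"`.
#' @param t time grid in seconds from recording start.
#' @param config a [synthetic_config()].
#' @return Numeric vector, same length as `t`.
#' @export
response_curve <- function(condition, t, config) {
  stopifnot(inherits(config, "synthetic_config"))
  condition <- as.character(condition)
  if (!condition %in% CONDITIONS)
    stop("unknown condition `", condition, "`")
  base <- config$baseline_oxy_pct
  if (condition == "BC") return(rep(base, length(t)))
  t_stim <- config$epoch_minutes[1] * 60
  t_post <- t_stim + config$epoch_minutes[2] * 60
  amp <- config$response_amplitude_pct[condition]
  tau <- config$time_to_peak_s[condition] / 3
  k <- config$post_decay_rate_per_s[condition]
  v_end <- base + amp * (1 - exp(-(t_post - t_stim) / tau))
  out <- rep(base, length(t))
  stim <- t >= t_stim & t < t_post
  out[stim] <- base + amp * (1 - exp(-(t[stim] - t_stim) / tau))
  post <- t >= t_post
  out[post] <- base + (v_end - base) * exp(-k * (t[post] - t_post))
  out
}

clamp01 <- function(x) pmin(1, pmax(0, x))

#' Generate all channels for one subject under one condition
#'
#' Produces five coupled [signal_record()]s: oxygen saturation (response
#' template plus noise, clipped to \[0, 100\] with clip events logged), the
#' three perfusion components V1/V2/V3, and the programmed probe-temperature
#' trace. Each perfusion channel is a mixture of a latent stream shared with
#' the oxygen channel (its normal-scores transform, so the thermal response
#' is transmitted through the coupling) and private noise, with the mixing
#' weight chosen so the population Spearman correlation with oxygen
#' saturation approaches the configured coupling — including negative
#' couplings during a rising thermal response.
#'
#' @param subject_id a subject id from `design`.
#' @param condition a condition consistent with the subject's group.
#' @param design a [study_design()].
#' @param config a [synthetic_config()].
#' @return A `signal_dataset` with the five records.
#' @export
generate_subject <- function(subject_id, condition, design, config) {
  stopifnot(inherits(design, "study_design"),
            inherits(config, "synthetic_config"))
  condition <- as.character(condition)
  if (!condition %in% design$conditions)
    stop("unknown condition `", condition, "`")
  is_bc <- subject_id %in% design$bc_ids
  if (!is_bc && !subject_id %in% design$ts_ids)
    stop("subject `", subject_id, "` not in design")
  if (is_bc != (condition == "BC"))
    stop("subject `", subject_id, "` cannot be recorded under condition `",
         condition, "`")
  group <- if (is_bc) "BC" else "TS"
  sub_idx <- if (is_bc) length(design$ts_ids) + match(subject_id, design$bc_ids)
             else match(subject_id, design$ts_ids)
  cond_idx <- match(condition, CONDITIONS)

  fs <- config$sampling_rate_hz
  n_epoch <- round(config$epoch_minutes * 60 * fs)
  n <- sum(n_epoch)
  t <- (seq_len(n) - 1) / fs

  # per-subject complexity: white_fraction with optional jitter
  wf0 <- config$white_fraction[condition]
  jit_seed <- derive_seed(config$seed, 90L, sub_idx)
  wf_for <- function(chan_idx) {
    if (config$white_fraction_jitter_sd == 0) return(wf0)
    s <- if (config$white_fraction_jitter == "shared") jit_seed
         else derive_seed(config$seed, 90L, sub_idx, chan_idx)
    clamp01(wf0 + local_seed(s, rnorm(1, 0, config$white_fraction_jitter_sd)))
  }

  resp <- response_curve(condition, t, config)
  z <- generate_noise(n, wf_for(0L), 1,
                      derive_seed(config$seed, sub_idx, cond_idx, 0L))
  oxy_raw <- resp + config$noise_sd * z
  n_clip <- sum(oxy_raw < 0 | oxy_raw > 100)
  if (n_clip > 0)
    log_event("clipped_samples", subject = subject_id,
              condition = condition, n = n_clip)
  oxy <- pmin(100, pmax(0, oxy_raw))

  records <- list(signal_record(subject_id, group, condition, "oxy_sat",
                                oxy, fs, 0))
  # Shared latent stream: the normal-scores transform of the realised
  # oxygen signal (thermal response included). Mixing against it rather
  # than against the raw noise keeps the configured Spearman coupling in
  # force even when the deterministic thermal trend dominates the ranks,
  # and lets negative couplings coexist with a rising response.
  g <- stats::qnorm(rank(oxy, ties.method = "average") / (n + 1))
  for (ch_i in 1:3) {
    ch <- c("V1", "V2", "V3")[ch_i]
    rho <- config$coupling[[condition]][ch]
    lambda <- 2 * sin(pi * rho / 6)  # Gaussian rank-correlation identity
    e <- generate_noise(n, wf_for(ch_i), 1,
                        derive_seed(config$seed, sub_idx, cond_idx, ch_i))
    mixed <- lambda * g + sqrt(1 - lambda^2) * e
    scale <- config$perfusion_baseline[ch] / config$baseline_oxy_pct
    v <- scale * (config$baseline_oxy_pct + config$noise_sd * mixed)
    records[[length(records) + 1L]] <-
      signal_record(subject_id, group, condition, ch, v, fs, 0)
  }

  temp <- rep(config$skin_temp_c, n)
  if (condition != "BC") {
    stim <- t >= config$epoch_minutes[1] * 60 &
      t < (config$epoch_minutes[1] + config$epoch_minutes[2]) * 60
    temp[stim] <- as.numeric(condition)
  }
  records[[length(records) + 1L]] <-
    signal_record(subject_id, group, condition, "temperature", temp, fs, 0)

  new_dataset(records)
}

#' Generate a full synthetic cohort
#'
#' One recording per BC subject and one per TS subject per temperature,
#' following the design's per-subject stimulation order (metadata only: each
#' condition's recording is generated independently of its position in the
#' order).
#'
#' @param design a [study_design()].
#' @param config a [synthetic_config()].
#' @return A `signal_dataset` covering the whole cohort.
#' @export
generate_cohort <- function(design = study_design(),
                            config = synthetic_config()) {
  records <- list()
  for (sub in design$ts_ids) {
    for (cond in design$stimulation_order[[sub]]) {
      ds <- generate_subject(sub, cond, design, config)
      records <- c(records, unclass(ds))
    }
  }
  for (sub in design$bc_ids) {
    ds <- generate_subject(sub, "BC", design, config)
    records <- c(records, unclass(ds))
  }
  new_dataset(records)
}

#' Epoch spec matching a generator configuration
#'
#' @param config a [synthetic_config()].
#' @return The [epoch_spec()] implied by the configured epoch durations.
#' @export
config_epochs <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  e <- config$epoch_minutes * 60
  epoch_spec(baseline = c(0, e[1]),
             stimulation = c(e[1], e[1] + e[2]),
             post = c(e[1] + e[2], sum(e)))
}
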