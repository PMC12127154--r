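## Synthetic confounded ECG populations. Beats are sums of five Gaussian
## wavelets (P, Q, R, S, T); classes differ by template offsets (ST baseline
## offset, T-wave timing, RR irregularity); confounding processes (baseline
## wander, lead gain, additive noise) have an intensity coupled to a
## designated class indicator at a controllable correlation rho.

#' Beat template: five Gaussian wave components
#'
#' @param amplitudes,centers,widths numeric length-5 vectors (mV, s, s) for
#'   waves P, Q, R, S, T. Centers must be strictly increasing, widths > 0.
#' @return a `beat_template`.
#' @export
beat_template <- function(amplitudes = c(P = 0.15, Q = -0.10, R = 1.00,
                                         S = -0.15, T = 0.30),
                          centers = c(0.10, 0.20, 0.22, 0.24, 0.45),
                          widths = c(0.025, 0.010, 0.012, 0.010, 0.050)) {
  if (length(amplitudes) != 5L || length(centers) != 5L || length(widths) != 5L)
    stop("templates have exactly five components (P, Q, R, S, T)",
         call. = FALSE)
  if (any(widths <= 0))
    stop("wave widths must be positive", call. = FALSE)
  if (any(diff(centers) <= 0))
    stop("wave centers must be strictly increasing (P < Q < R < S < T)",
         call. = FALSE)
  structure(list(amplitudes = unname(as.numeric(amplitudes)),
                 centers = unname(as.numeric(centers)),
                 widths = unname(as.numeric(widths))),
            class = "beat_template")
}

#' Class specification: template offsets and rhythm parameters
#'
#' @param class_id integer class identity (1-based).
#' @param amp_delta,center_delta,width_delta length-5 offsets added to the
#'   base template.
#' @param st_offset ST-segment baseline offset in mV, rendered as a broad
#'   Gaussian between the S and T waves.
#' @param rr_mean mean RR interval in seconds.
#' @param rr_cv coefficient of variation of RR intervals (>= 0).
#' @return a `class_spec`.
#' @export
class_spec <- function(class_id, amp_delta = numeric(5),
                       center_delta = numeric(5), width_delta = numeric(5),
                       st_offset = 0, rr_mean = 0.8, rr_cv = 0.05) {
  stop_if_not_scalar_num(rr_mean, "rr_mean", lo = .Machine$double.eps)
  stop_if_not_scalar_num(rr_cv, "rr_cv", lo = 0)
  structure(list(class_id = as.integer(class_id),
                 amp_delta = as.numeric(amp_delta),
                 center_delta = as.numeric(center_delta),
                 width_delta = as.numeric(width_delta),
                 st_offset = as.numeric(st_offset),
                 rr_mean = as.numeric(rr_mean), rr_cv = as.numeric(rr_cv)),
            class = "class_spec")
}

#' Apply a class's template offsets to a base beat template
#' @param template a [beat_template()].
#' @param spec a [class_spec()].
#' @return a `beat_template` (validated after offsetting).
#' @export
class_template <- function(template, spec) {
  beat_template(template$amplitudes + spec$amp_delta,
                template$centers + spec$center_delta,
                template$widths + spec$width_delta)
}

#' Confounding-process specification
#'
#' @param baseline_amp_max maximum baseline-wander amplitude, mV.
#' @param baseline_freq baseline-wander frequency, Hz.
#' @param gain_range multiplicative lead-gain interval, e.g. `c(0.7, 1.3)`.
#' @param noise_sd_max maximum additive white-noise SD, mV.
#' @param rho correlation in `[-1, 1]` between confounder intensity and the
#'   designated class indicator.
#' @return a `confounder_spec`.
#' @export
confounder_spec <- function(baseline_amp_max = 0.5, baseline_freq = 0.33,
                            gain_range = c(0.7, 1.3), noise_sd_max = 0.2,
                            rho = 0.8) {
  stop_if_not_scalar_num(baseline_amp_max, "baseline_amp_max", lo = 0)
  stop_if_not_scalar_num(noise_sd_max, "noise_sd_max", lo = 0)
  stop_if_not_scalar_num(rho, "rho", lo = -1, hi = 1)
  if (length(gain_range) != 2L || any(gain_range <= 0) ||
      gain_range[2L] < gain_range[1L])
    stop("`gain_range` must be a positive interval (lo, hi)", call. = FALSE)
  structure(list(baseline_amp_max = baseline_amp_max,
                 baseline_freq = baseline_freq,
                 gain_range = as.numeric(gain_range),
                 noise_sd_max = noise_sd_max, rho = rho),
            class = "confounder_spec")
}

#' Default class population: four classes with distinct morphology
#'
#' Class 1: normal. Class 2: ST elevation (+0.2 mV) with taller T.
#' Class 3: long QT (T wave shifted +0.08 s and broadened).
#' Class 4: irregular rhythm (RR CV 0.30) with reduced R amplitude.
#' @return list of four [class_spec()] objects.
#' @export
default_class_specs <- function() {
  list(
    class_spec(1L),
    class_spec(2L, amp_delta = c(0, 0, 0, 0, 0.15), st_offset = 0.20),
    class_spec(3L, center_delta = c(0, 0, 0, 0, 0.08),
               width_delta = c(0, 0, 0, 0, 0.02)),
    class_spec(4L, amp_delta = c(0, 0, -0.30, 0, 0), rr_cv = 0.30))
}

#' Full parameterization of a synthetic confounded ECG population
#'
#' @param n_leads number of leads (default 12).
#' @param class_specs list of [class_spec()]; K = its length.
#' @param confounder a [confounder_spec()].
#' @param template the base [beat_template()].
#' @param duration record duration, s.
#' @param fs sampling rate, Hz.
#' @param lead_projection length-`n_leads` vector of per-lead gains applied to
#'   the beat train; defaults to fixed gains in [0.5, 1.5].
#' @param confounded_class the class whose indicator is coupled to the
#'   confounder intensity.
#' @param seed integer seed fixing every random draw.
#' @return a `synth_config`.
#' @export
synth_config <- function(n_leads = 12, class_specs = default_class_specs(),
                         confounder = confounder_spec(),
                         template = beat_template(),
                         duration = 10, fs = 100, lead_projection = NULL,
                         confounded_class = 1L, seed = 1L) {
  if (length(class_specs) < 2L)
    stop("need at least K = 2 classes", call. = FALSE)
  stop_if_not_scalar_num(duration, "duration", lo = .Machine$double.eps)
  stop_if_not_scalar_num(fs, "fs", lo = 1)
  if (is.null(lead_projection))
    lead_projection <- 0.5 + cumsum(rep(1 / n_leads, n_leads))
  if (length(lead_projection) != n_leads)
    stop("`lead_projection` must have length n_leads", call. = FALSE)
  rr_min <- min(vapply(class_specs, `[[`, numeric(1), "rr_mean"))
  if (duration * fs < rr_min * fs)
    stop("duration must cover at least one beat", call. = FALSE)
  structure(list(n_leads = as.integer(n_leads), K = length(class_specs),
                 class_specs = class_specs, confounder = confounder,
                 template = template, duration = duration, fs = fs,
                 lead_projection = as.numeric(lead_projection),
                 confounded_class = as.integer(confounded_class),
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Render one beat as a sampled sum of Gaussian wavelets
#'
#' `s(t) = sum_w a_w exp(-(t - mu_w)^2 / (2 sigma_w^2))`, sampled at `fs`;
#' output length is `round(duration * fs)`.
#'
#' @param template a [beat_template()].
#' @param fs sampling rate, Hz.
#' @param duration beat duration, s (must cover all component centers).
#' @return numeric vector of length `round(duration * fs)`.
#' @export
render_beat <- function(template, fs, duration) {
  stopifnot(inherits(template, "beat_template"))
  if (duration < max(template$centers))
    stop("`duration` must cover all component centers", call. = FALSE)
  n <- round(duration * fs)
  t <- (seq_len(n) - 1L) / fs
  s <- numeric(n)
  for (w in seq_len(5L))
    s <- s + template$amplitudes[w] *
      exp(-(t - template$centers[w])^2 / (2 * template$widths[w]^2))
  s
}

## beat span used when tiling: last center + 4 sd of the last wave
beat_span <- function(template) max(template$centers + 4 * template$widths)

## ST offset rendered as a broad plateau-like Gaussian between S and T
st_wave <- function(spec, template) {
  if (spec$st_offset == 0) return(NULL)
  ctr <- mean(template$centers[4:5])
  list(amp = spec$st_offset, center = ctr, width = 0.06)
}

#' Render one confounded multi-lead recording
#'
#' Beats are tiled at Gamma-distributed RR intervals (mean `rr_mean`,
#' coefficient of variation `rr_cv`; degenerate at `rr_cv = 0`). Each lead is
#' `lead_projection[i] * beat_train`, then the confounding processes are added
#' at strength `confounder_intensity`: a baseline sinusoid, a multiplicative
#' gain perturbation, and white Gaussian noise.
#'
#' @param class_id 1-based class index (`<= K`).
#' @param confounder_intensity real in `[0, 1]`.
#' @param config a [synth_config()].
#' @param seed integer seed for this record's draws.
#' @return an [ecg_record()] with one-hot `labels`.
#' @export
render_record <- function(class_id, confounder_intensity, config, seed = 1L) {
  stopifnot(inherits(config, "synth_config"))
  if (class_id < 1L || class_id > config$K)
    stop("`class_id` must be in 1..K", call. = FALSE)
  stop_if_not_scalar_num(confounder_intensity, "confounder_intensity", 0, 1)
  spec <- config$class_specs[[class_id]]
  tmpl <- class_template(config$template, spec)
  stw <- st_wave(spec, tmpl)
  fs <- config$fs
  L <- round(config$duration * fs)
  with_seed(seed, {
    ## beat onsets from RR draws
    onsets <- 0
    repeat {
      rr <- if (spec$rr_cv == 0) spec$rr_mean else {
        shape <- 1 / spec$rr_cv^2
        rgamma(1L, shape = shape, scale = spec$rr_mean / shape)
      }
      nxt <- onsets[length(onsets)] + rr
      if (nxt >= config$duration) break
      onsets <- c(onsets, nxt)
    }
    span <- beat_span(tmpl)
    bl <- round(span * fs)
    beat <- render_beat(tmpl, fs, span)
    if (!is.null(stw)) {
      t <- (seq_len(bl) - 1L) / fs
      beat <- beat + stw$amp * exp(-(t - stw$center)^2 / (2 * stw$width^2))
    }
    train <- numeric(L)
    for (on in onsets) {
      i0 <- round(on * fs)
      n_fit <- min(bl, L - i0)
      if (n_fit > 0)
        train[i0 + seq_len(n_fit)] <- train[i0 + seq_len(n_fit)] +
          beat[seq_len(n_fit)]
    }
    sig <- outer(config$lead_projection, train)   # n_leads x L
    ci <- confounder_intensity
    cf <- config$confounder
    if (ci > 0) {
      tvec <- (seq_len(L) - 1L) / fs
      phase <- runif(config$n_leads, 0, 2 * pi)
      amp <- ci * cf$baseline_amp_max
      baseline <- amp * sin(outer(phase, rep(1, L)) +
                            2 * pi * cf$baseline_freq *
                              outer(rep(1, config$n_leads), tvec))
      g_raw <- runif(config$n_leads, cf$gain_range[1L], cf$gain_range[2L])
      gains <- 1 + ci * (g_raw - 1)
      sig <- sig * gains + baseline
      if (cf$noise_sd_max > 0)
        sig <- sig + matrix(rnorm(length(sig), sd = ci * cf$noise_sd_max),
                            nrow = config$n_leads)
    }
    labels <- numeric(config$K)
    labels[class_id] <- 1
    ecg_record(sig, fs = fs, labels = labels,
               record_id = sprintf("synth_c%d_s%d", class_id, seed))
  })
}

#' Couple confounder intensities to a binary class indicator
#'
#' `intensity = (rho * z + sqrt(1 - rho^2) * u) / (|rho| + sqrt(1 - rho^2))`
#' with `u ~ U(0, 1)`; for negative `rho` the indicator is flipped. Exact at
#' `rho` in `{-1, 0, 1}` (deterministic 0/1 at `|rho| = 1`, independent
#' uniform at 0) and monotone in between.
#'
#' @param z binary indicator vector.
#' @param rho target correlation in `[-1, 1]`.
#' @param u uniform(0,1) draws, same length as `z`.
#' @return intensities in `[0, 1]`.
#' @keywords internal
couple_intensity <- function(z, rho, u) {
  if (abs(rho) > 1) stop("|rho| must be <= 1", call. = FALSE)
  zz <- if (rho < 0) 1 - z else z
  a <- abs(rho); s <- sqrt(1 - rho^2)
  (a * zz + s * u) / (a + s)
}

#' Generate a confounded synthetic ECG dataset
#'
#' Class labels are uniform over 1..K; confounder intensities are coupled to
#' the indicator of `config$confounded_class` at correlation `rho` (see
#' [couple_intensity()]). Identical `(config, n, rho, seed)` always yield the
#' identical dataset.
#'
#' @param config a [synth_config()].
#' @param n number of records (>= K).
#' @param rho label-confounder correlation; defaults to
#'   `config$confounder$rho`.
#' @param seed integer seed; defaults to `config$seed`.
#' @return list with `records` (list of [ecg_record()]), `class_ids`,
#'   `intensities`, and the generating `rho` and `seed`.
#' @export
generate_dataset <- function(config, n, rho = NULL, seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  rho <- rho %||% config$confounder$rho
  seed <- seed %||% config$seed
  stop_if_not_scalar_num(rho, "rho", lo = -1, hi = 1)
  if (n < config$K)
    stop("need n >= K records", call. = FALSE)
  draws <- with_seed(seed, {
    cls <- sample.int(config$K, n, replace = TRUE)
    u <- runif(n)
    rec_seeds <- sample.int(2147483000L, n)
    list(cls = cls, u = u, rec_seeds = rec_seeds)
  })
  z <- as.numeric(draws$cls == config$confounded_class)
  intens <- couple_intensity(z, rho, draws$u)
  records <- vector("list", n)
  for (i in seq_len(n))
    records[[i]] <- render_record(draws$cls[i], intens[i], config,
                                  seed = draws$rec_seeds[i])
  list(records = records, class_ids = draws$cls, intensities = intens,
       rho = rho, seed = as.integer(seed))
}
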