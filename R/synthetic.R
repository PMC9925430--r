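# Synthetic labeled EEG with the statistical structure the analysis assumes:
# 1/f background, band-limited oscillations whose gains depend on workload
# class and scalp region, inter-subject amplitude variability, frontal eye
# blinks, optional line noise and dead channels.

#' Default workload effect profile
#'
#' Multiplicative gains on band-limited component amplitude per
#' (region, band, class), plus baseline band amplitudes and the 1/f
#' background shape. The default encodes the canonical workload signature:
#' frontal theta increasing, parietal/occipital alpha decreasing, and beta
#' mildly increasing with workload. Effect sizes are tens-of-percent
#' amplitude steps between adjacent classes.
#'
#' @param frontal_theta_gain,posterior_alpha_gain,beta_gain Length-3 numeric
#'   (low, medium, high) multiplicative amplitude gains.
#' @param baseline_rms Named numeric: baseline RMS amplitude (microvolts) of
#'   each band's oscillatory component before gains.
#' @param background_exponent Spectral exponent of the 1/f background.
#' @param background_rms Broadband RMS (microvolts) of the background.
#' @return An `ewl_profile` list; `$gain` is a region x band x class array.
#' @export
default_class_profile <- function(frontal_theta_gain = c(0.80, 1.00, 1.25),
                                  posterior_alpha_gain = c(1.30, 1.00, 0.75),
                                  beta_gain = c(0.90, 1.00, 1.15),
                                  baseline_rms = c(delta = 6, theta = 5,
                                                   alpha = 6, beta = 3),
                                  background_exponent = 1.0,
                                  background_rms = 10) {
  stopifnot(length(frontal_theta_gain) == 3, length(posterior_alpha_gain) == 3,
            length(beta_gain) == 3,
            all(c(frontal_theta_gain, posterior_alpha_gain, beta_gain) > 0))
  regions <- c("frontal", "central", "temporal", "parietal",
               "parieto-occipital", "occipital")
  gain <- array(1, dim = c(length(regions), 4, 3),
                dimnames = list(regions, standard_bands()$name,
                                workload_levels()))
  gain["frontal", "theta", ] <- frontal_theta_gain
  for (r in c("parietal", "parieto-occipital", "occipital")) {
    gain[r, "alpha", ] <- posterior_alpha_gain
  }
  for (cl in workload_levels()) {
    gain[, "beta", cl] <- gain[, "beta", cl] *
      beta_gain[match(cl, workload_levels())]
  }
  structure(
    list(gain = gain, baseline_rms = baseline_rms,
         background_exponent = background_exponent,
         background_rms = background_rms),
    class = "ewl_profile"
  )
}

#' Default artifact configuration
#'
#' @param blink_rate Eye blinks per minute on Fp1/Fp2.
#' @param blink_amplitude Peak blink amplitude (microvolts) at Fp1/Fp2.
#' @param blink_decay Multiplicative amplitude decay per step back from the
#'   prefrontal source (Fp1/Fp2 step 0, other frontal 1, central/temporal 2,
#'   parietal 3, parieto-occipital 4, occipital 5).
#' @param line_freq,line_amplitude Power-line frequency (Hz) and amplitude
#'   (microvolts); amplitude 0 disables it.
#' @param dead_channel_prob Per-channel probability of a dead (flat) channel.
#' @param subject_sigma Lognormal sigma of the per-subject gain jitter.
#' @return An `ewl_artifacts` list.
#' @export
default_artifact_config <- function(blink_rate = 8, blink_amplitude = 80,
                                    blink_decay = 0.2,
                                    line_freq = 60, line_amplitude = 0,
                                    dead_channel_prob = 0,
                                    subject_sigma = 0.2) {
  stopifnot(blink_rate >= 0, blink_amplitude >= 0, line_amplitude >= 0,
            dead_channel_prob >= 0, dead_channel_prob <= 1,
            subject_sigma >= 0)
  structure(
    list(blink_rate = blink_rate, blink_amplitude = blink_amplitude,
         blink_decay = blink_decay, line_freq = line_freq,
         line_amplitude = line_amplitude,
         dead_channel_prob = dead_channel_prob,
         subject_sigma = subject_sigma),
    class = "ewl_artifacts"
  )
}

#' Band-limited Gaussian noise
#'
#' Zero-mean Gaussian noise whose spectral power is confined to
#' `[lo, hi]` Hz, rescaled to a requested RMS. Oscillations are modelled as
#' filtered noise rather than sinusoids so downstream spectral estimators
#' face realistic variance and leakage.
#'
#' @param lo,hi Band edges in Hz; must satisfy `0 < lo < hi < fs/2`.
#' @param rms Target RMS amplitude (microvolts); 0 yields an all-zero signal.
#' @param n Number of samples; must exceed `2 * fs / lo` so the band holds
#'   at least two Fourier bins.
#' @param fs Sampling rate (Hz).
#' @return Numeric vector of length `n`.
#' @export
band_limited_noise <- function(lo, hi, rms, n, fs) {
  if (lo <= 0 || hi >= fs / 2 || lo >= hi) {
    stop("band [", lo, ", ", hi, "] outside (0, fs/2)")
  }
  if (n <= 2 * fs / lo) stop("n too small for band lower edge")
  if (rms == 0) return(numeric(n))
  x <- stats::rnorm(n)
  spec <- stats::fft(x)
  freq <- seq(0, n - 1) * fs / n
  freq <- pmin(freq, fs - freq)   # fold to [0, fs/2]
  spec[freq < lo | freq > hi] <- 0
  y <- Re(stats::fft(spec, inverse = TRUE)) / n
  y <- y - mean(y)
  y * rms / sqrt(mean(y^2))
}

# 1/f^a background noise, scaled to a broadband RMS.
one_over_f_noise <- function(exponent, rms, n, fs) {
  if (rms == 0) return(numeric(n))
  x <- stats::rnorm(n)
  spec <- stats::fft(x)
  freq <- seq(0, n - 1) * fs / n
  freq <- pmin(freq, fs - freq)
  shape <- ifelse(freq > 0, freq^(-exponent / 2), 0)
  y <- Re(stats::fft(spec * shape, inverse = TRUE)) / n
  y <- y - mean(y)
  y * rms / sqrt(mean(y^2))
}

# 400 ms raised-cosine blink pulse, unit peak.
blink_pulse <- function(fs, width_s = 0.4) {
  n <- round(width_s * fs)
  0.5 * (1 - cos(2 * pi * seq(0, n - 1) / (n - 1)))
}

# Distance from the prefrontal blink source, in steps, for blink amplitude
# decay: full amplitude at Fp1/Fp2, then one step per region toward the back.
blink_step <- function(name, region) {
  steps <- c("frontal" = 1, "central" = 2, "temporal" = 2,
             "parietal" = 3, "parieto-occipital" = 4, "occipital" = 5)
  out <- unname(steps[region])
  out[name %in% c("Fp1", "Fp2")] <- 0
  out
}

#' Simulate one labeled maneuver segment
#'
#' Each channel is a 1/f background plus one band-limited Gaussian component
#' per band, with the component amplitude scaled by the profile gain for the
#' channel's (region, band, class), plus configured artifacts.
#'
#' @param label Workload class, one of [workload_levels()].
#' @param montage An `ewl_montage`.
#' @param profile An `ewl_profile` from [default_class_profile()].
#' @param artifacts An `ewl_artifacts` from [default_artifact_config()].
#' @param fs Sampling rate (Hz).
#' @param duration_s Segment duration in seconds (120 for the standard
#'   pipeline contract of 30,720 samples at 256 Hz).
#' @param maneuver_id,subject_id Identifiers.
#' @param seed Optional integer; seeds the generator for this segment.
#' @return An `ewl_segment`.
#' @export
simulate_segment <- function(label, montage = standard_montage(),
                             profile = default_class_profile(),
                             artifacts = default_artifact_config(),
                             fs = 256, duration_s = 120,
                             maneuver_id = "M01", subject_id = "S01",
                             seed = NULL) {
  label <- match.arg(label, workload_levels())
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration_s * fs)
  elec <- montage$electrodes
  bands <- standard_bands()
  data <- matrix(0, nrow = nrow(elec), ncol = n)

  for (ch in seq_len(nrow(elec))) {
    sig <- one_over_f_noise(profile$background_exponent,
                            profile$background_rms, n, fs)
    for (b in seq_len(nrow(bands))) {
      g <- profile$gain[elec$region[ch], bands$name[b], label]
      amp <- profile$baseline_rms[[bands$name[b]]] * g
      sig <- sig + band_limited_noise(bands$lo[b], bands$hi[b], amp, n, fs)
    }
    data[ch, ] <- sig
  }

  if (artifacts$blink_rate > 0 && artifacts$blink_amplitude > 0) {
    n_blinks <- stats::rpois(1, artifacts$blink_rate * duration_s / 60)
    if (n_blinks > 0) {
      pulse <- blink_pulse(fs)
      starts <- sort(sample.int(n - length(pulse), n_blinks, replace = TRUE))
      decay <- artifacts$blink_decay^blink_step(elec$name, elec$region)
      for (s in starts) {
        idx <- s:(s + length(pulse) - 1)
        data[, idx] <- data[, idx] +
          outer(artifacts$blink_amplitude * decay, pulse)
      }
    }
  }

  if (artifacts$line_amplitude > 0) {
    t <- seq_len(n) / fs
    line <- artifacts$line_amplitude * sin(2 * pi * artifacts$line_freq * t)
    data <- sweep(data, 2, line, "+")
  }

  if (artifacts$dead_channel_prob > 0) {
    dead <- stats::runif(nrow(elec)) < artifacts$dead_channel_prob
    data[dead, ] <- 0
  }

  maneuver_segment(data, label, fs, montage, maneuver_id, subject_id)
}

#' Generate a balanced labeled dataset
#'
#' Simulates `n_subjects x 3 classes x segments_per_class` maneuver segments
#' with a per-subject lognormal gain applied uniformly across channels
#' (inter-individual amplitude variability), and the matching events table.
#' All randomness flows from `seed`: the same seed and configuration yield
#' an identical dataset.
#'
#' @param n_subjects Number of simulated subjects.
#' @param segments_per_class Segments per class per subject.
#' @param profile,artifacts See [simulate_segment()].
#' @param montage An `ewl_montage`.
#' @param fs Sampling rate (Hz).
#' @param duration_s Segment duration (s).
#' @param seed Integer seed.
#' @return List with `segments` (list of `ewl_segment`) and `events`
#'   (data.frame: subject_id, maneuver_id, onset_s, offset_s, label), where
#'   onsets place a subject's segments back to back.
#' @export
make_dataset <- function(n_subjects = 10, segments_per_class = 2,
                         profile = default_class_profile(),
                         artifacts = default_artifact_config(),
                         montage = standard_montage(),
                         fs = 256, duration_s = 120, seed = 1) {
  stopifnot(n_subjects >= 1, segments_per_class >= 1)
  set.seed(seed)
  segments <- list()
  events <- list()
  for (s in seq_len(n_subjects)) {
    subject <- sprintf("S%02d", s)
    gain <- stats::rlnorm(1, 0, artifacts$subject_sigma)
    k <- 0
    for (cls in workload_levels()) {
      for (r in seq_len(segments_per_class)) {
        k <- k + 1
        mid <- sprintf("%s_%s_%d", subject, cls, r)
        seg <- simulate_segment(cls, montage, profile, artifacts, fs,
                                duration_s, maneuver_id = mid,
                                subject_id = subject)
        seg$data <- seg$data * gain
        segments[[length(segments) + 1]] <- seg
        events[[length(events) + 1]] <- data.frame(
          subject_id = subject, maneuver_id = mid,
          onset_s = (k - 1) * duration_s, offset_s = k * duration_s,
          label = cls, stringsAsFactors = FALSE
        )
      }
    }
  }
  list(segments = segments, events = do.call(rbind, events))
}
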