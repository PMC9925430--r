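# Feature extraction: Welch band powers, the three band-ratio families, and
# log energy entropy -- 228 named features per segment on the full montage.

#' Cut one labeled segment out of a recording
#'
#' Returns exactly `round(duration_s * fs)` samples starting at the maneuver
#' onset (30,720 samples for the standard 120 s at 256 Hz), with the label
#' copied from the event row. Maneuvers shorter than the requested duration
#' are rejected, not padded, so the sample-count contract stays exact.
#'
#' @param rec An `ewl_recording`.
#' @param event A list or one-row data.frame with `onset_s`, `offset_s`,
#'   `label`, and optionally `maneuver_id`, `subject_id`.
#' @param duration_s Analysis window length in seconds.
#' @return An `ewl_segment`.
#' @export
extract_segment <- function(rec, event, duration_s = 120) {
  onset <- event$onset_s
  offset <- event$offset_s
  if (offset - onset < duration_s) {
    stop("maneuver ", event$maneuver_id %||% "?", " lasts ",
         offset - onset, " s, shorter than the ", duration_s,
         " s analysis window")
  }
  start <- round(onset * rec$fs) + 1L
  n <- round(duration_s * rec$fs)
  if (start + n - 1L > ncol(rec$data)) {
    stop("maneuver window extends past the end of the recording")
  }
  maneuver_segment(rec$data[, start:(start + n - 1L), drop = FALSE],
                   label = event$label, fs = rec$fs, montage = rec$montage,
                   maneuver_id = event$maneuver_id %||% "M??",
                   subject_id = event$subject_id %||% rec$subject_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Welch power spectral density
#'
#' Average of modified periodograms: 1 s Hamming windows with 50 percent
#' overlap, per-window mean removal, one-sided density scaling. With the
#' window length equal to `fs` samples the frequency resolution is exactly
#' 1 Hz, which makes band-edge handling exact under the half-open band rule.
#'
#' @param x Single-channel sample vector; length must be at least `2 * fs`.
#' @param fs Sampling rate (Hz).
#' @param window_s Window length in seconds (default 1).
#' @param overlap Fractional window overlap (default 0.5).
#' @return List with `freq` (Hz, 0 to fs/2) and `psd` (density,
#'   microvolts^2 / Hz).
#' @export
welch_psd <- function(x, fs, window_s = 1, overlap = 0.5) {
  nwin <- round(window_s * fs)
  if (length(x) < 2 * nwin) {
    stop("input too short for Welch averaging (need >= ", 2 * nwin,
         " samples)")
  }
  w <- 0.54 - 0.46 * cos(2 * pi * seq(0, nwin - 1) / (nwin - 1))
  step <- max(1L, round(nwin * (1 - overlap)))
  starts <- seq(1L, length(x) - nwin + 1L, by = step)
  nfreq <- nwin %/% 2 + 1L
  acc <- numeric(nfreq)
  scale <- 1 / (fs * sum(w^2))
  for (s in starts) {
    seg <- x[s:(s + nwin - 1L)]
    seg <- (seg - mean(seg)) * w
    spec <- stats::fft(seg)[seq_len(nfreq)]
    p <- scale * (Re(spec)^2 + Im(spec)^2)
    p[2:(nfreq - 1L)] <- 2 * p[2:(nfreq - 1L)]  # one-sided: fold negatives
    acc <- acc + p
  }
  list(freq = seq(0, nfreq - 1L) * fs / nwin, psd = acc / length(starts))
}

#' Average band power from a PSD
#'
#' Arithmetic mean of the density bins inside the band: `lo <= f < hi`, with
#' beta's upper edge inclusive so the four bands tile `[1, 30]` exactly.
#'
#' @param psd List with `freq` and `psd` as from [welch_psd()].
#' @param lo,hi Band edges (Hz).
#' @param hi_inclusive Include the upper edge bin (used for beta).
#' @return Mean density (microvolts^2 / Hz).
#' @export
band_average <- function(psd, lo, hi, hi_inclusive = FALSE) {
  sel <- psd$freq >= lo & (if (hi_inclusive) psd$freq <= hi
                           else psd$freq < hi)
  if (!any(sel)) stop("no PSD bins inside band [", lo, ", ", hi, ")")
  mean(psd$psd[sel])
}

#' Band-power table for a segment
#'
#' @param segment An `ewl_segment`.
#' @param window_s,overlap Welch parameters.
#' @return electrodes x bands numeric matrix of average band densities.
#' @export
band_power_table <- function(segment, window_s = 1, overlap = 0.5) {
  bands <- standard_bands()
  elec <- segment$montage$electrodes$name
  out <- matrix(NA_real_, nrow = length(elec), ncol = nrow(bands),
                dimnames = list(elec, bands$name))
  for (ch in seq_along(elec)) {
    psd <- welch_psd(segment$data[ch, ], segment$fs, window_s, overlap)
    for (b in seq_len(nrow(bands))) {
      out[ch, b] <- band_average(psd, bands$lo[b], bands$hi[b],
                                 hi_inclusive = bands$name[b] == "beta")
    }
  }
  out
}

#' Band-ratio features
#'
#' The three ratio families: frontal theta over parietal/parieto-occipital
#' alpha (every frontal x posterior electrode pair, the workload index),
#' theta/beta per electrode (attention index), and the engagement index
#' beta / (alpha + theta) per electrode. Denominators are guarded by machine
#' epsilon; a guarded division triggers a warning rather than an Inf.
#'
#' @param bpt Band-power matrix from [band_power_table()].
#' @param montage An `ewl_montage`.
#' @return Named numeric vector of 28 + 20 + 20 = 68 ratio features on the
#'   full montage, in canonical order (thetaF_alphaP, engagement,
#'   theta_beta).
#' @export
ratio_features <- function(bpt, montage) {
  guard <- function(d) {
    if (any(d < .Machine$double.eps)) {
      warning("ratio denominator guarded by machine epsilon")
    }
    pmax(d, .Machine$double.eps)
  }
  elec <- montage$electrodes$name
  out <- numeric(0)
  for (f in montage$frontal_set) {
    for (p in montage$posterior_set) {
      out[sprintf("ratio:thetaF_alphaP:%s:%s", f, p)] <-
        bpt[f, "theta"] / guard(bpt[p, "alpha"])
    }
  }
  for (e in elec) {
    out[sprintf("ratio:engagement:%s", e)] <-
      bpt[e, "beta"] / guard(bpt[e, "alpha"] + bpt[e, "theta"])
  }
  for (e in elec) {
    out[sprintf("ratio:theta_beta:%s", e)] <-
      bpt[e, "theta"] / guard(bpt[e, "beta"])
  }
  out
}

#' Log energy entropy
#'
#' `E = sum_n log(w_n^2)` over the coefficients of a signal's band
#' representation, with squared coefficients floored at `eps` so the sum
#' stays finite at exact zeros. Natural logarithm; a different base only
#' rescales every entropy feature by a constant and cannot change
#' standardized selection or classification behaviour.
#'
#' @param x Coefficient vector (band-filtered samples by default upstream).
#' @param eps Floor applied to the squared coefficients.
#' @return Scalar entropy value.
#' @export
log_energy_entropy <- function(x, eps = 1e-12) {
  if (length(x) == 0) stop("empty coefficient vector")
  if (eps <= 0) stop("eps must be positive")
  sum(log(pmax(x^2, eps)))
}

# --- wavelet-packet backend -------------------------------------------------

# Daubechies-4 decomposition filters (8 taps).
db4_filters <- function() {
  lo <- c(-0.010597401784997278, 0.032883011666982945,
          0.030841381835986965, -0.18703481171888114,
          -0.02798376941698385, 0.6308807679295904,
          0.7148465705525415, 0.23037781330885523)
  hi <- rev(lo) * (-1)^(seq_along(lo) - 1)
  list(lo = lo, hi = hi)
}

# One periodic filter-and-downsample step.
wp_step <- function(x, h) {
  n <- length(x)
  L <- length(h)
  # periodic convolution then dyadic downsample
  idx <- outer(seq(1, n, by = 2) - 1, seq_len(L) - 1, "-") %% n + 1
  as.numeric(matrix(x[idx], ncol = L) %*% h)
}

# Full wavelet-packet decomposition to `depth`, returning coefficient
# vectors in frequency (sequency) order: after a high-pass branch the
# child frequency ordering flips.
wavelet_packet <- function(x, depth = 5) {
  f <- db4_filters()
  nodes <- list(x)            # frequency-ordered nodes at current level
  for (lev in seq_len(depth)) {
    nxt <- vector("list", 2 * length(nodes))
    for (i in seq_along(nodes)) {
      a <- wp_step(nodes[[i]], f$lo)
      d <- wp_step(nodes[[i]], f$hi)
      if ((i - 1) %% 2 == 0) {          # even frequency index: lo first
        nxt[[2 * i - 1]] <- a; nxt[[2 * i]] <- d
      } else {                          # odd: ordering flips
        nxt[[2 * i - 1]] <- d; nxt[[2 * i]] <- a
      }
    }
    nodes <- nxt
  }
  nodes
}

# Union of depth-5 wavelet-packet node coefficients whose frequency interval
# centre falls inside the band.
wp_band_coefficients <- function(x, fs, lo, hi, hi_inclusive = FALSE,
                                 depth = 5) {
  nodes <- wavelet_packet(x, depth)
  width <- (fs / 2) / length(nodes)
  centres <- (seq_along(nodes) - 0.5) * width
  sel <- centres >= lo & (if (hi_inclusive) centres <= hi else centres < hi)
  unlist(nodes[sel])
}

# ---------------------------------------------------------------------------

#' Canonical feature names for a montage
#'
#' Block order: PSD band powers, frontal-theta/posterior-alpha ratios,
#' engagement index, theta/beta ratio, log energy entropy. Within blocks,
#' ordering is by canonical band order (delta, theta, alpha, beta) then
#' montage electrode order; ratio pairs are frontal-major. 228 names on the
#' full 20-electrode montage.
#'
#' @param montage An `ewl_montage`.
#' @return Character vector of feature names.
#' @export
feature_names <- function(montage = standard_montage()) {
  bands <- standard_bands()$name
  elec <- montage$electrodes$name
  c(
    as.vector(t(outer(bands, elec, function(b, e) sprintf("psd:%s:%s", b, e)))),
    as.vector(t(outer(montage$frontal_set, montage$posterior_set,
                      function(f, p) sprintf("ratio:thetaF_alphaP:%s:%s", f, p)))),
    sprintf("ratio:engagement:%s", elec),
    sprintf("ratio:theta_beta:%s", elec),
    as.vector(t(outer(bands, elec, function(b, e) sprintf("lee:%s:%s", b, e))))
  )
}

#' Extract the full named feature vector from one segment
#'
#' Concatenates, in canonical order: one Welch band power per
#' (band, electrode); the three ratio families; and one log energy entropy
#' per (band, electrode), computed on the band representation of the channel.
#' The default entropy backend band-filters the channel (zero-phase) and
#' treats the filtered samples as the coefficients; the `"wavelet"` backend
#' uses Daubechies-4 wavelet-packet node coefficients (depth 5) unioned to
#' best match each band, for sensitivity analysis.
#'
#' @param segment An `ewl_segment`.
#' @param lee_backend `"bandpass"` (default) or `"wavelet"`.
#' @param lee_eps Epsilon guard for [log_energy_entropy()].
#' @param window_s,overlap Welch parameters.
#' @return Named numeric vector (228 entries on the full montage).
#' @export
extract_features <- function(segment, lee_backend = c("bandpass", "wavelet"),
                             lee_eps = 1e-12, window_s = 1, overlap = 0.5) {
  lee_backend <- match.arg(lee_backend)
  montage <- segment$montage
  bands <- standard_bands()
  elec <- montage$electrodes$name
  bpt <- band_power_table(segment, window_s, overlap)

  psd_feats <- numeric(0)
  for (b in bands$name) {
    for (e in elec) psd_feats[sprintf("psd:%s:%s", b, e)] <- bpt[e, b]
  }

  ratios <- ratio_features(bpt, montage)

  lee_feats <- numeric(0)
  for (b in seq_len(nrow(bands))) {
    bname <- bands$name[b]
    for (ch in seq_along(elec)) {
      coeffs <- if (lee_backend == "bandpass") {
        bandpass(segment$data[ch, ], bands$lo[b], bands$hi[b], fs = segment$fs)
      } else {
        wp_band_coefficients(segment$data[ch, ], segment$fs,
                             bands$lo[b], bands$hi[b],
                             hi_inclusive = bname == "beta")
      }
      lee_feats[sprintf("lee:%s:%s", bname, elec[ch])] <-
        log_energy_entropy(coeffs, lee_eps)
    }
  }

  out <- c(psd_feats, ratios, lee_feats)
  out[feature_names(montage)]
}

#' Build the segments x features matrix
#'
#' One row per segment, columns in canonical feature order, with
#' `subject_id`, `maneuver_id` and `label` carried through as leading
#' columns. Row order equals input order.
#'
#' @param segments List of `ewl_segment` sharing one montage.
#' @param ... Passed to [extract_features()].
#' @return data.frame of class `ewl_features`: subject_id, maneuver_id,
#'   label, then the named feature columns.
#' @export
build_feature_matrix <- function(segments, ...) {
  if (length(segments) == 0) stop("no segments supplied")
  ref <- segments[[1]]$montage$electrodes$name
  for (s in segments) {
    if (!identical(s$montage$electrodes$name, ref)) {
      stop("segments use inconsistent montages")
    }
  }
  feats <- t(vapply(segments, extract_features,
                    numeric(length(feature_names(segments[[1]]$montage))),
                    ...))
  meta <- data.frame(
    subject_id = vapply(segments, function(s) s$subject_id, character(1)),
    maneuver_id = vapply(segments, function(s) s$maneuver_id, character(1)),
    label = vapply(segments, function(s) s$label, character(1)),
    stringsAsFactors = FALSE
  )
  out <- cbind(meta, as.data.frame(feats))
  # preserve the canonical names verbatim (":" would otherwise be mangled)
  colnames(out) <- c(names(meta), colnames(feats))
  class(out) <- c("ewl_features", "data.frame")
  out
}

#' Split a feature matrix into X, y and metadata
#'
#' @param fm An `ewl_features` data.frame.
#' @return List with `X` (numeric matrix), `y` (factor with levels
#'   low/medium/high) and `meta` (data.frame of ids).
#' @export
feature_xy <- function(fm) {
  meta_cols <- c("subject_id", "maneuver_id", "label")
  X <- as.matrix(fm[, setdiff(colnames(fm), meta_cols), drop = FALSE])
  list(X = X,
       y = factor(fm$label, levels = workload_levels()),
       meta = fm[, intersect(meta_cols, colnames(fm)), drop = FALSE])
}

#' Write a feature matrix to CSV (+ JSON schema)
#'
#' @param fm An `ewl_features` data.frame.
#' @param path Output CSV path; a `.schema.json` sidecar is written next to
#'   it with the canonical column order and label alphabet.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  utils::write.csv(fm, path, row.names = FALSE)
  schema <- list(columns = colnames(fm), labels = workload_levels())
  jsonlite::write_json(schema, sub("\\.csv$", ".schema.json", path),
                       auto_unbox = TRUE)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param path CSV path.
#' @return An `ewl_features` data.frame.
#' @export
read_feature_matrix <- function(path) {
  fm <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  class(fm) <- c("ewl_features", "data.frame")
  fm
}
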