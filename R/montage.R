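# Montage, scalp regions and frequency bands shared by every pipeline stage.

#' The 20-electrode 10-20 montage used throughout the pipeline
#'
#' Returns the fixed recording montage: 20 electrodes of the international
#' 10-20 layout in canonical order, each with its scalp region, idealized
#' unit-sphere 3-D position, plus the electrode sets entering the
#' theta/alpha workload ratio (7 frontal numerator electrodes x 4
#' parietal / parieto-occipital denominator electrodes = 28 ratio features).
#'
#' The electrode order is fixed and identical on every call, so feature
#' column ordering downstream is reproducible bit-exactly.
#'
#' @return An object of class `ewl_montage`: a list with
#'   `electrodes` (data.frame: name, region, x, y, z on the unit sphere),
#'   `frontal_set` (character, length 7) and `posterior_set`
#'   (character, length 4).
#' @examples
#' m <- standard_montage()
#' nrow(m$electrodes)   # 20
#' m$frontal_set        # Fp1 Fp2 F7 F3 Fz F4 F8
#' @export
standard_montage <- function() {
  tab <- electrode_table()
  structure(
    list(
      electrodes = tab,
      frontal_set = c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8"),
      posterior_set = c("P3", "Pz", "P4", "POz")
    ),
    class = "ewl_montage"
  )
}

# Static electrode lookup: 10-20 name, scalp region, and idealized spherical
# coordinates (inclination from the vertex, azimuth from the nasion midline,
# positive toward the right ear). Only relative geometry matters: the
# spherical-spline interpolation consumes the unit-sphere (x, y, z).
electrode_table <- function() {
  def <- rbind(
    c("Fp1", "frontal",           72, -18),
    c("Fp2", "frontal",           72,  18),
    c("F7",  "frontal",           72, -54),
    c("F3",  "frontal",           48, -29),
    c("Fz",  "frontal",           36,   0),
    c("F4",  "frontal",           48,  29),
    c("F8",  "frontal",           72,  54),
    c("T3",  "temporal",          72, -90),
    c("C3",  "central",           36, -90),
    c("Cz",  "central",            0,   0),
    c("C4",  "central",           36,  90),
    c("T4",  "temporal",          72,  90),
    c("T5",  "temporal",          72, -126),
    c("P3",  "parietal",          48, -151),
    c("Pz",  "parietal",          36, 180),
    c("P4",  "parietal",          48, 151),
    c("T6",  "temporal",          72, 126),
    c("O1",  "occipital",         72, -162),
    c("POz", "parieto-occipital", 54, 180),
    c("O2",  "occipital",         72, 162)
  )
  incl <- as.numeric(def[, 3]) * pi / 180
  azim <- as.numeric(def[, 4]) * pi / 180
  data.frame(
    name = def[, 1],
    region = def[, 2],
    x = sin(incl) * sin(azim),
    y = sin(incl) * cos(azim),
    z = cos(incl),
    stringsAsFactors = FALSE
  )
}

#' Scalp region of an electrode
#'
#' @param name Character vector of 10-20 electrode names.
#' @return Character vector of regions (`frontal`, `central`, `temporal`,
#'   `parietal`, `parieto-occipital`, `occipital`).
#' @export
electrode_region <- function(name) {
  tab <- electrode_table()
  idx <- match(name, tab$name)
  if (anyNA(idx)) {
    stop("unknown electrode name(s): ",
         paste(name[is.na(idx)], collapse = ", "))
  }
  tab$region[idx]
}

#' Canonical EEG frequency bands
#'
#' Delta 1-4, theta 4-8, alpha 8-13, beta 13-30 Hz. Band intervals are
#' half-open `[lo, hi)` except beta, whose upper edge is inclusive, so the
#' four bands partition `[1, 30]` with no frequency double-counted.
#'
#' @return data.frame with columns `name`, `lo`, `hi` in canonical order.
#' @export
standard_bands <- function() {
  data.frame(
    name = c("delta", "theta", "alpha", "beta"),
    lo = c(1, 4, 8, 13),
    hi = c(4, 8, 13, 30),
    stringsAsFactors = FALSE
  )
}

#' Map a frequency to its EEG band
#'
#' @param f Frequency in Hz, non-negative scalar or vector.
#' @return Character vector: band name, or `NA` outside `[1, 30]`.
#'   Edges follow the half-open rule (`13` is beta, not alpha); beta's upper
#'   edge 30 is inclusive.
#' @examples
#' band_for_frequency(5)    # "theta"
#' band_for_frequency(13)   # "beta"
#' band_for_frequency(0.5)  # NA
#' @export
band_for_frequency <- function(f) {
  if (any(f < 0)) stop("frequency must be non-negative")
  bands <- standard_bands()
  out <- rep(NA_character_, length(f))
  for (i in seq_len(nrow(bands))) {
    inside <- f >= bands$lo[i] & f < bands$hi[i]
    out[inside] <- bands$name[i]
  }
  out[f == 30] <- "beta"
  out
}

#' Construct a raw multichannel recording
#'
#' Lightweight container for a channels x samples matrix with sampling-rate
#' and montage metadata; the physical input of the pipeline.
#'
#' @param data Numeric matrix, channels x samples, in microvolts. Row order
#'   must follow `montage$electrodes$name`.
#' @param fs Sampling rate in Hz; must exceed twice the highest band edge.
#' @param montage An `ewl_montage`.
#' @param subject_id Opaque identifier.
#' @return An `ewl_recording` object.
#' @export
raw_recording <- function(data, fs, montage = standard_montage(),
                          subject_id = "S01") {
  stopifnot(is.matrix(data), is.numeric(data))
  if (!all(is.finite(data))) stop("recording contains non-finite samples")
  if (nrow(data) != nrow(montage$electrodes)) {
    stop("recording has ", nrow(data), " channels but montage has ",
         nrow(montage$electrodes))
  }
  if (fs <= 2 * max(standard_bands()$hi)) {
    stop("sampling rate ", fs, " Hz too low for the band set")
  }
  rownames(data) <- montage$electrodes$name
  structure(
    list(data = data, fs = fs, montage = montage, subject_id = subject_id),
    class = "ewl_recording"
  )
}

#' Construct a labeled maneuver segment
#'
#' One analysis window cut from a recording and tagged with a workload class.
#' At the standard 120 s duration and 256 Hz this is exactly 30,720 samples.
#'
#' @param data Channels x samples matrix (microvolts).
#' @param label One of `"low"`, `"medium"`, `"high"`.
#' @param fs Sampling rate (Hz).
#' @param montage An `ewl_montage`.
#' @param maneuver_id,subject_id Identifiers carried into the feature matrix.
#' @return An `ewl_segment` object.
#' @export
maneuver_segment <- function(data, label, fs, montage = standard_montage(),
                             maneuver_id = "M01", subject_id = "S01") {
  label <- match.arg(label, workload_levels())
  stopifnot(is.matrix(data))
  if (nrow(data) != nrow(montage$electrodes)) {
    stop("segment channel count does not match montage")
  }
  rownames(data) <- montage$electrodes$name
  structure(
    list(data = data, label = label, fs = fs, montage = montage,
         maneuver_id = maneuver_id, subject_id = subject_id),
    class = "ewl_segment"
  )
}

#' Workload class alphabet
#'
#' @return `c("low", "medium", "high")`, the ordered label alphabet.
#' @export
workload_levels <- function() c("low", "medium", "high")

#' Serialize montage + band definitions to a JSON config block
#'
#' @param montage An `ewl_montage`.
#' @return A JSON string.
#' @export
montage_to_json <- function(montage = standard_montage()) {
  jsonlite::toJSON(
    list(
      electrodes = montage$electrodes,
      frontal_set = montage$frontal_set,
      posterior_set = montage$posterior_set,
      bands = standard_bands()
    ),
    auto_unbox = TRUE, digits = NA
  )
}

#' Rebuild a montage from its JSON config block
#'
#' @param json JSON string produced by [montage_to_json()].
#' @return An `ewl_montage`.
#' @export
montage_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  structure(
    list(electrodes = x$electrodes,
         frontal_set = x$frontal_set,
         posterior_set = x$posterior_set),
    class = "ewl_montage"
  )
}
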