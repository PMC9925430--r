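test_that("extract_segment honors the sample-count and onset contracts", {
  m <- standard_montage()
  n_s <- 135
  set.seed(8)
  data <- matrix(rnorm(20 * n_s * 256), nrow = 20)
  # channel 1 carries the sample index so onset indexing is observable
  data[1, ] <- seq_len(n_s * 256)
  rec <- raw_recording(data, fs = 256, montage = m)
  ev <- list(onset_s = 10, offset_s = 132, label = "high",
             maneuver_id = "M1", subject_id = "S1")
  seg <- extract_segment(rec, ev)
  expect_equal(ncol(seg$data), 30720)
  expect_equal(unname(seg$data[1, 1]), round(10 * 256) + 1)
  expect_equal(seg$label, "high")
  expect_error(
    extract_segment(rec, list(onset_s = 0, offset_s = 119, label = "low",
                              maneuver_id = "Mx")),
    "shorter"
  )
  expect_error(
    extract_segment(rec, list(onset_s = 30, offset_s = 160, label = "low",
                              maneuver_id = "My")),
    "past the end"
  )
})

test_that("Welch PSD satisfies energy conservation and tone localization", {
  set.seed(5)
  w <- rnorm(30720)
  p <- welch_psd(w, 256)
  expect_equal(p$freq, 0:128)
  expect_equal(sum(p$psd) * 1, 1, tolerance = 0.10)  # unit variance, df 1 Hz
  t <- seq_len(30720) / 256
  a <- 3
  p2 <- welch_psd(a * sin(2 * pi * 10 * t), 256)
  expect_equal(p2$freq[which.max(p2$psd)], 10)
  expect_equal(sum(p2$psd), a^2 / 2, tolerance = 0.02)
  expect_identical(max(welch_psd(numeric(1024), 256)$psd), 0)
  expect_error(welch_psd(numeric(100), 256), "too short")
})

test_that("doubling segment length reduces Welch band-average variance", {
  est <- function(n, seeds) {
    sapply(seeds, function(s) {
      set.seed(s)
      x <- band_limited_noise(8, 13, 2, n, 256)
      band_average(welch_psd(x, 256), 8, 13)
    })
  }
  v_short <- stats::var(est(10 * 256, 1:25))
  v_long <- stats::var(est(40 * 256, 1:25))
  expect_lt(v_long, v_short)
})

test_that("band averages follow the half-open binning rule", {
  flat <- list(freq = 0:128, psd = rep(4, 129))
  expect_equal(band_average(flat, 1, 4), 4)
  expect_equal(band_average(flat, 13, 30, hi_inclusive = TRUE), 4)
  # alpha holds bins 8..12 at 1 Hz resolution: 5 bins
  marked <- list(freq = 0:128, psd = as.numeric(0:128))
  expect_equal(band_average(marked, 8, 13), mean(8:12))
  t <- seq_len(30720) / 256
  p <- welch_psd(sin(2 * pi * 10 * t), 256)
  alpha <- band_average(p, 8, 13)
  others <- c(band_average(p, 1, 4), band_average(p, 4, 8),
              band_average(p, 13, 30, hi_inclusive = TRUE))
  expect_true(all(alpha / others > 10))
})

test_that("ratio features implement the three families exactly", {
  m <- standard_montage()
  bpt <- matrix(2, nrow = 20, ncol = 4,
                dimnames = list(m$electrodes$name, standard_bands()$name))
  r <- ratio_features(bpt, m)
  expect_length(r, 68)
  expect_true(all(r[grep("thetaF_alphaP", names(r))] == 1))
  expect_true(all(r[grep("theta_beta", names(r))] == 1))
  expect_true(all(r[grep("engagement", names(r))] == 0.5))
  bpt["Fz", "theta"] <- 4
  bpt["P3", "alpha"] <- 2
  r2 <- ratio_features(bpt, m)
  expect_equal(unname(r2["ratio:thetaF_alphaP:Fz:P3"]), 2)
  # zero denominator is guarded, not Inf
  bpt["O1", "beta"] <- 0
  expect_warning(r3 <- ratio_features(bpt, m), "guarded")
  expect_true(all(is.finite(r3)))
})

test_that("log energy entropy matches closed forms and a naive-loop oracle", {
  expect_equal(log_energy_entropy(rep(3, 50)), 50 * log(9), tolerance = 1e-12)
  expect_equal(log_energy_entropy(numeric(100), eps = 1e-12),
               100 * log(1e-12))
  set.seed(6)
  x <- rnorm(64)
  naive <- 0
  for (v in x) naive <- naive + log(max(v^2, 1e-12))
  expect_equal(log_energy_entropy(x), naive, tolerance = 1e-9)
  expect_error(log_energy_entropy(numeric(0)), "empty")
  expect_error(log_energy_entropy(1:3, eps = 0), "positive")
})

test_that("the full montage yields the 228-feature inventory", {
  fv <- extract_features(quick_segment(seed = 31))
  expect_length(fv, 228)
  expect_true(all(is.finite(fv)))
  expect_identical(names(fv), feature_names(standard_montage()))
  blocks <- c(psd = sum(startsWith(names(fv), "psd:")),
              workload_ratio = sum(startsWith(names(fv), "ratio:thetaF_alphaP:")),
              engagement = sum(startsWith(names(fv), "ratio:engagement:")),
              theta_beta = sum(startsWith(names(fv), "ratio:theta_beta:")),
              lee = sum(startsWith(names(fv), "lee:")))
  expect_equal(unname(blocks), c(80, 28, 20, 20, 80))
  expect_equal(sum(blocks) - blocks[["lee"]], 148)  # PSD-derived features
})

test_that("feature count follows 10m + f*p on reduced montages", {
  full <- standard_montage()
  for (spec in list(list(keep = c("Fp1", "Fz", "Cz", "P3", "Pz", "O1"),
                         frontal = c("Fp1", "Fz"), posterior = c("P3", "Pz")),
                    list(keep = c("F3", "F4", "C3", "C4", "Pz"),
                         frontal = c("F3", "F4"), posterior = "Pz"))) {
    sub <- full
    sub$electrodes <- full$electrodes[full$electrodes$name %in% spec$keep, ]
    sub$frontal_set <- spec$frontal
    sub$posterior_set <- spec$posterior
    m <- nrow(sub$electrodes)
    seg <- quick_segment(duration_s = 4, seed = 17, montage = sub)
    fv <- extract_features(seg)
    expect_length(fv, 10 * m + length(spec$frontal) * length(spec$posterior))
  }
})

test_that("scaling a segment scales PSD by k^2, ratios not at all, and lee by n log k^2", {
  seg <- quick_segment(duration_s = 4, seed = 12)
  # tiny eps so no coefficient is floored and the shift identity is exact
  fv1 <- extract_features(seg, lee_eps = 1e-300)
  k <- 2.5
  seg2 <- seg
  seg2$data <- seg$data * k
  fv2 <- extract_features(seg2, lee_eps = 1e-300)
  is_psd <- startsWith(names(fv1), "psd:")
  is_ratio <- startsWith(names(fv1), "ratio:")
  is_lee <- startsWith(names(fv1), "lee:")
  expect_equal(fv2[is_psd], fv1[is_psd] * k^2, tolerance = 1e-6)
  expect_equal(fv2[is_ratio], fv1[is_ratio], tolerance = 1e-6)
  n <- ncol(seg$data)
  expect_equal(fv2[is_lee] - fv1[is_lee],
               stats::setNames(rep(n * log(k^2), sum(is_lee)),
                               names(fv1)[is_lee]),
               tolerance = 1e-6)
})

test_that("wavelet-packet entropy backend is finite and energy-preserving", {
  seg <- quick_segment(duration_s = 4, seed = 13)
  fv <- extract_features(seg, lee_backend = "wavelet")
  expect_length(fv, 228)
  expect_true(all(is.finite(fv)))
  # the underlying packet transform is orthogonal: energy is conserved
  x <- seg$data[1, 1:1024]
  nodes <- eegworkload:::wavelet_packet(x, depth = 5)
  expect_equal(sum(unlist(nodes)^2), sum(x^2), tolerance = 1e-8)
})

test_that("feature matrices are stable, ordered and validated", {
  segs <- lapply(1:4, function(i) {
    quick_segment(label = workload_levels()[(i %% 3) + 1], duration_s = 4,
                  seed = 40 + i)
  })
  fm <- build_feature_matrix(segs)
  expect_equal(dim(fm), c(4, 3 + 228))
  expect_identical(colnames(fm)[1:3], c("subject_id", "maneuver_id", "label"))
  expect_identical(colnames(fm)[-(1:3)], feature_names(standard_montage()))
  # row order equals input order
  expect_identical(fm$label,
                   vapply(segs, function(s) s$label, character(1)))
  expect_error(build_feature_matrix(list()), "no segments")
  sub <- standard_montage()
  sub$electrodes <- sub$electrodes[1:5, ]
  segs2 <- c(segs[1], list(quick_segment(duration_s = 4, montage = sub)))
  expect_error(build_feature_matrix(segs2), "inconsistent")
  # CSV round trip preserves values and canonical column order
  p <- file.path(tempdir(), "fm.csv")
  write_feature_matrix(fm, p)
  fm2 <- read_feature_matrix(p)
  expect_identical(colnames(fm2), colnames(fm))
  expect_equal(feature_xy(fm2)$X, feature_xy(fm)$X, tolerance = 1e-12)
  unlink(c(p, sub("\\.csv$", ".schema.json", p)))
})
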