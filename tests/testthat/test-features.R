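test_that("windowing arithmetic matches the enumeration oracle", {
  fs <- 2000
  ws <- window_spec(256, 0.25)
  geo <- window_geometry(ws, fs)
  expect_equal(geo$W, 512L)
  expect_equal(geo$step, 384L)

  rec <- signal_record(matrix(rnorm(80000 * 2), ncol = 2), fs)
  wins <- segment(rec, ws)
  starts <- oracle_window_starts(80000, geo$W, geo$step)
  expect_length(wins, 208L)
  expect_equal(vapply(wins, `[[`, numeric(1), "start"), as.numeric(starts))
  expect_true(all(vapply(wins, function(w) nrow(w$values), integer(1)) == 512L))

  # randomized lengths against the oracle
  set.seed(11)
  for (n in sample(600:5000, 10)) {
    r <- signal_record(matrix(rnorm(n), ncol = 1), fs)
    expect_length(segment(r, ws), length(oracle_window_starts(n, 512, 384)))
  }
})

test_that("segmentation boundaries: one window, tiling, too short", {
  fs <- 1000
  ws <- window_spec(100, 0)          # W = 100, step = 100
  rec1 <- signal_record(matrix(rnorm(100), ncol = 1), fs)
  expect_length(segment(rec1, ws), 1L)
  rec3 <- signal_record(matrix(rnorm(300), ncol = 1), fs)
  wins <- segment(rec3, ws)
  expect_length(wins, 3L)
  expect_equal(vapply(wins, `[[`, numeric(1), "start"), c(1, 101, 201))
  short <- signal_record(matrix(rnorm(99), ncol = 1), fs)
  expect_error(segment(short, ws), "shorter than one")
})

test_that("windows inherit the record labels", {
  rec <- signal_record(matrix(rnorm(1024), ncol = 2), 2000,
                       gesture = "g2", subject = "sub1", session = "S3")
  w <- segment(rec, window_spec())[[1]]
  expect_identical(w$gesture, "g2")
  expect_identical(w$session, "S3")
})

test_that("time-domain features reproduce hand-computed values", {
  cfg <- feature_config()
  f1 <- time_features(c(1, -1, 1, -1), cfg)
  expect_equal(f1[["MAV"]], 1)
  expect_equal(f1[["RMS"]], 1)
  expect_equal(f1[["ZC"]], 3)
  expect_equal(f1[["iEMG"]], 4)

  fc <- time_features(rep(2.5, 6), cfg)
  expect_equal(fc[["RMS"]], 2.5)
  expect_equal(fc[["LOG"]], 2.5, tolerance = 1e-9)
  expect_equal(fc[["AAC"]], 0)
  expect_equal(fc[["DASDV"]], 0)
  expect_equal(fc[["ZC"]], 0)

  cfg2 <- feature_config(wamp_threshold = 0.5, myop_threshold = 1.5)
  f3 <- time_features(c(1, 2, 3), cfg2)
  expect_equal(f3[["AAC"]], 2 / 3)
  expect_equal(f3[["DASDV"]], 1)
  expect_equal(f3[["VAR"]], 7)      # uncentered sum of squares / (N - 1)
  expect_equal(f3[["WAMP"]], 2)
  expect_equal(f3[["MYOP"]], 2 / 3)

  expect_error(time_features(1), "at least 2")
  expect_error(time_features(c(1, NA)), "non-finite")
})

test_that("waveform-length conventions: conventional vs as-printed", {
  x <- c(1, 3, 0, -2)
  conv <- time_features(x, feature_config())
  expect_equal(conv[["WL"]], 2 + 3 + 2)
  printed <- time_features(x, feature_config(wl_convention = "as-printed"))
  expect_equal(printed[["WL"]], printed[["VAR"]])  # printed formula duplicates VAR
})

test_that("all 17 features match the naive-loop oracles on random windows", {
  set.seed(101)
  cfg <- feature_config()
  for (i in 1:100) {
    x <- rnorm(512, sd = runif(1, 0.1, 3))
    got_t <- time_features(x, cfg)
    want_t <- oracle_time_features(x)
    expect_equal(got_t, want_t, tolerance = 1e-10)

    ps <- power_spectrum(x, fs = 2000)
    got_f <- freq_features(ps, cfg)
    want_f <- oracle_freq_features(ps$power, ps$freqs)
    expect_equal(got_f, want_f, tolerance = 1e-8)
  }
})

test_that("power spectrum peaks at the tone bin and satisfies Parseval", {
  fs <- 2000
  n <- 512
  t <- (0:(n - 1)) / fs
  ps <- power_spectrum(sin(2 * pi * 125 * t), fs)
  expect_equal(ps$freqs[which.max(ps$power)], 125)  # exactly bin 32

  set.seed(5)
  x <- rnorm(512)
  ps2 <- power_spectrum(x, fs)
  xd <- x - mean(x)
  expect_equal(sum(ps2$power), mean(xd^2), tolerance = 1e-6)

  ps0 <- power_spectrum(rep(3, 64), fs)   # constant: detrended to zero
  expect_equal(max(ps0$power), 0)
})

test_that("frequency features handle point masses, flat spectra and ties", {
  mk <- function(power, freqs)
    structure(list(power = power, freqs = freqs), class = "power_spectrum")
  # ratio bands sized to the fixtures' short frequency axes
  cfg <- feature_config(fr_low_band = c(0, 100), fr_high_band = c(100, 200))

  point <- mk(c(0, 0, 5, 0), c(0, 50, 100, 150))
  fp <- freq_features(point, cfg)
  expect_equal(fp[["MNF"]], 100)
  expect_equal(fp[["MDF"]], 100)
  expect_equal(fp[["PKF"]], 100)

  flat <- mk(rep(2, 10), seq(0, 450, by = 50))
  ff <- freq_features(flat, cfg)
  expect_equal(ff[["TP"]], 20)
  expect_equal(ff[["MNP"]], 2)

  two <- mk(c(0, 3, 0, 3, 0), c(0, 50, 100, 150, 200))
  ft <- freq_features(two, cfg)
  expect_equal(ft[["MNF"]], 100)
  expect_equal(ft[["MDF"]], 50)   # first bin reaching half total, no interpolation

  zero <- mk(rep(0, 4), c(0, 50, 100, 150))
  expect_warning(fz <- freq_features(zero, cfg), "all-zero")
  expect_true(is.na(fz[["MNF"]]))

  no_high <- mk(c(1, 1, 0, 0), c(0, 100, 300, 400))
  expect_error(freq_features(no_high, feature_config()), "high band")
})

test_that("as-printed peak frequency equals half the total power", {
  ps <- structure(list(power = c(1, 2, 3), freqs = c(0, 100, 200)),
                  class = "power_spectrum")
  f <- freq_features(ps, feature_config(pkf_convention = "as-printed",
                                        fr_low_band = c(0, 100),
                                        fr_high_band = c(100, 200)))
  expect_equal(f[["PKF"]], f[["TP"]] / 2)
})

test_that("feature matrix has 17 x channels columns in channel-major order", {
  rec <- signal_record(matrix(rnorm(80000 * 2), ncol = 2), 2000,
                       gesture = "g1", subject = "s", session = "S1")
  fm <- extract_feature_matrix(list(rec))
  expect_equal(dim(fm$values), c(208L, 34L))
  expect_equal(colnames(fm$values)[1:3], c("MAV_ch1", "RMS_ch1", "VAR_ch1"))
  expect_equal(colnames(fm$values)[18], "MAV_ch2")
  expect_true(all(is.finite(fm$values)))
})

test_that("row counts add over records and record order permutes row blocks", {
  r1 <- signal_record(matrix(rnorm(3000), ncol = 1), 2000, gesture = "a",
                      subject = "s", session = "S1")
  r2 <- signal_record(matrix(rnorm(5000), ncol = 1), 2000, gesture = "b",
                      subject = "s", session = "S1")
  f12 <- extract_feature_matrix(list(r1, r2))
  fa <- extract_feature_matrix(list(r1))
  fb <- extract_feature_matrix(list(r2))
  expect_equal(nrow(f12$values), nrow(fa$values) + nrow(fb$values))
  f21 <- extract_feature_matrix(list(r2, r1))
  expect_equal(f21$values,
               rbind(f12$values[f12$gesture == "b", ],
                     f12$values[f12$gesture == "a", ]))
  r3 <- signal_record(matrix(rnorm(3000), ncol = 3), 2000)
  expect_error(extract_feature_matrix(list(r1, r3)), "channel counts")
})

test_that("scale equivariance holds where the formulas force it", {
  set.seed(21)
  x <- rnorm(512)
  a <- 3.7
  cfg <- feature_config(wamp_threshold = 0, myop_threshold = 0)
  f1 <- time_features(x, cfg)
  fa <- time_features(a * x, cfg)
  for (nm in c("MAV", "RMS", "iEMG", "AAC", "DASDV"))
    expect_equal(fa[[nm]], a * f1[[nm]], tolerance = 1e-12)
  expect_equal(fa[["ZC"]], f1[["ZC"]])
  expect_equal(fa[["MYOP"]], f1[["MYOP"]])
})

test_that("feature extraction is deterministic", {
  rec <- signal_record(matrix(rnorm(4096), ncol = 2), 2000,
                       gesture = "g", subject = "s", session = "S1")
  f1 <- extract_feature_matrix(list(rec))
  f2 <- extract_feature_matrix(list(rec))
  expect_identical(f1$values, f2$values)
})
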