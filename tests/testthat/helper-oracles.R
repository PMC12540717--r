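# Independently coded naive-loop oracles for the 17 window features.
# Deliberately written as plain summation loops, separate from the package's
# vectorized implementations.

oracle_time_features <- function(x, wamp_thr = 0.01, myop_thr = 0.01,
                                 log_eps = 1e-12) {
  N <- length(x)
  mav <- 0; ss <- 0; iemg <- 0; logs <- 0; myop <- 0
  for (p in seq_len(N)) {
    mav <- mav + abs(x[p]) / N
    ss <- ss + x[p]^2
    iemg <- iemg + abs(x[p])
    logs <- logs + log(abs(x[p]) + log_eps) / N
    if (abs(x[p]) >= myop_thr) myop <- myop + 1 / N
  }
  aac <- 0; dsum <- 0; zc <- 0; wl <- 0; wamp <- 0
  for (p in seq_len(N - 1)) {
    d <- x[p + 1] - x[p]
    aac <- aac + abs(d) / N
    dsum <- dsum + d^2
    wl <- wl + abs(d)
    if ((x[p] > 0 && x[p + 1] < 0) || (x[p] < 0 && x[p + 1] > 0)) zc <- zc + 1
    if (abs(d) >= wamp_thr) wamp <- wamp + 1
  }
  c(MAV = mav, RMS = sqrt(ss / N), VAR = ss / (N - 1), AAC = aac,
    DASDV = sqrt(dsum / (N - 1)), ZC = zc, WL = wl, WAMP = wamp,
    iEMG = iemg, MYOP = myop, LOG = exp(logs))
}

oracle_freq_features <- function(power, freqs, lo = c(10, 250),
                                 hi = c(250, 500)) {
  M <- length(power)
  tp <- 0
  for (k in seq_len(M)) tp <- tp + power[k]
  mnf_num <- 0
  for (k in seq_len(M)) mnf_num <- mnf_num + freqs[k] * power[k]
  cum <- 0; mdf <- NA_real_
  for (k in seq_len(M)) {
    cum <- cum + power[k]
    if (is.na(mdf) && cum >= tp / 2) mdf <- freqs[k]
  }
  pkf <- freqs[1]; pmax <- power[1]
  for (k in seq_len(M)) if (power[k] > pmax) { pmax <- power[k]; pkf <- freqs[k] }
  num <- 0; den <- 0
  for (k in seq_len(M)) {
    if (freqs[k] >= lo[1] && freqs[k] <= lo[2]) num <- num + power[k]
    if (freqs[k] >= hi[1] && freqs[k] <= hi[2]) den <- den + power[k]
  }
  c(TP = tp, PKF = pkf, FR = num / den, MNF = mnf_num / tp, MDF = mdf,
    MNP = tp / M)
}

# Enumeration oracle for overlapping-window segmentation
oracle_window_starts <- function(n, W, step) {
  starts <- integer(0)
  s <- 1
  while (s + W - 1 <= n) {
    starts <- c(starts, s)
    s <- s + step
  }
  starts
}

# Brute-force entropy / mutual-information oracle for the split score
oracle_split_score <- function(left, right) {
  ent <- function(cnt) {
    p <- cnt[cnt > 0] / sum(cnt)
    -sum(p * log2(p))
  }
  n <- sum(left) + sum(right)
  h_class <- ent(left + right)
  h_split <- ent(c(sum(left), sum(right)))
  cond <- sum(left) / n * ent(left) + sum(right) / n * ent(right)
  2 * (h_class - cond) / (h_split + h_class)
}

# Reference differential evolution mirroring the engine's RNG call order but
# with the operator arithmetic written independently (plain loops).
reference_de <- function(objective, n_dim, cfg, n_gen) {
  set.seed(cfg$seed)
  NP <- cfg$np_init
  H <- cfg$memory_size
  pop <- matrix(stats::runif(NP * n_dim), nrow = NP, ncol = n_dim)
  fit <- numeric(NP)
  for (i in seq_len(NP)) fit[i] <- objective(pop[i, ])
  m_sf <- rep(0.5, H); m_cr <- rep(0.5, H); widx <- 1L
  archive <- matrix(numeric(0), 0L, n_dim)
  for (g in seq_len(n_gen)) {
    n_pb <- max(2L, ceiling(cfg$pbest_frac * NP))
    pbest_idx <- order(-fit)[seq_len(n_pb)]
    s_sf <- s_cr <- s_df <- numeric(0)
    for (i in seq_len(NP)) {
      k <- sample.int(H, 1L)
      repeat { SF <- stats::rcauchy(1L, m_sf[k], 0.1); if (SF > 0) break }
      if (SF > 1) SF <- 1
      CR <- stats::rnorm(1L, m_cr[k], 0.1)
      if (CR < 0) CR <- 0
      if (CR > 1) CR <- 1
      pb <- pbest_idx[sample.int(n_pb, 1L)]
      r1 <- sample(setdiff(seq_len(NP), i), 1L)
      pool2 <- setdiff(seq_len(NP + nrow(archive)), c(i, r1))
      r2 <- pool2[sample.int(length(pool2), 1L)]
      x2 <- if (r2 <= NP) pop[r2, ] else archive[r2 - NP, ]
      u <- numeric(n_dim)
      v <- numeric(n_dim)
      for (j in seq_len(n_dim)) {
        v[j] <- pop[i, j] + SF * (pop[pb, j] - pop[i, j]) +
          SF * (pop[r1, j] - x2[j])
        if (v[j] < 0) v[j] <- pop[i, j] / 2
        if (v[j] > 1) v[j] <- (pop[i, j] + 1) / 2
      }
      j_rand <- sample.int(n_dim, 1L)
      cr_draw <- stats::runif(n_dim)
      for (j in seq_len(n_dim))
        u[j] <- if (cr_draw[j] < CR || j == j_rand) v[j] else pop[i, j]
      fu <- objective(u)
      if (fu >= fit[i]) {
        if (fu > fit[i]) {
          s_sf <- c(s_sf, SF); s_cr <- c(s_cr, CR)
          s_df <- c(s_df, abs(fu - fit[i]))
          archive <- rbind(archive, pop[i, , drop = FALSE])
        }
        pop[i, ] <- u
        fit[i] <- fu
      }
    }
    cap <- round(cfg$archive_rate * NP)
    if (nrow(archive) > cap)
      archive <- archive[sample.int(nrow(archive), cap), , drop = FALSE]
    if (length(s_sf) > 0) {
      w <- s_df / sum(s_df)
      m_sf[widx] <- cfg$blend_c * m_sf[widx] +
        (1 - cfg$blend_c) * sum(w * s_sf^2) / sum(w * s_sf)
      m_cr[widx] <- cfg$blend_c * m_cr[widx] +
        (1 - cfg$blend_c) * sum(w * s_cr^2) / sum(w * s_cr)
      widx <- (widx %% H) + 1L
    }
  }
  list(pop = pop, fit = fit)
}

# Small, fast synthetic dataset shared across tests (short tasks)
tiny_spec <- function(seed = 1, duration = 8, jitter = 0, noise = 0.05) {
  synthetic_spec(task_duration_s = duration, session_jitter = jitter,
                 noise_floor = noise, seed = seed)
}

tiny_features <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 1, duration = 8) {
    key <- sprintf("s%d_d%g", seed, duration)
    if (!exists(key, envir = cache)) {
      recs <- generate_records(tiny_spec(seed, duration))
      recs <- lapply(recs, apply_preprocessing, spec = filter_spec(2000))
      assign(key, extract_feature_matrix(recs), envir = cache)
    }
    get(key, envir = cache)
  }
})
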