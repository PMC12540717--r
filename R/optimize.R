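#' L-SHADE configuration
#'
#' Success-history adaptation differential evolution with linear population
#' size reduction (LPSR). The engine maximizes a scalar objective over the
#' unit box; mixed integer/categorical hyperparameter spaces are handled by
#' [decode()]. Either an evaluation budget (`nf_max`) or a generation
#' budget (`max_gen`) may be given; with only `max_gen`, the evaluation
#' budget is derived from the linear population schedule as
#' `np_init + round(max_gen * (np_init + np_min) / 2)`.
#'
#' @param np_init Initial population size (NP_max).
#' @param np_min Final population size (NP_min, >= 4).
#' @param memory_size Number of success-history memory cells H.
#' @param blend_c Memory blend factor c in (0, 1]: each update sets the
#'   cell to `c * old + (1 - c) * weighted_lehmer_mean(successes)`.
#' @param nf_max Maximum number of objective evaluations.
#' @param max_gen Optional generation cap.
#' @param pbest_frac Fraction of the population eligible as pbest targets.
#' @param archive_rate External archive capacity as a multiple of the
#'   current population size.
#' @param seed Integer seed driving all stochastic choices.
#' @return An object of class `lshade_config`.
#' @export
lshade_config <- function(np_init = 100, np_min = 4, memory_size = 6,
                          blend_c = 0.5, nf_max = NULL, max_gen = NULL,
                          pbest_frac = 0.11, archive_rate = 1.4, seed = 0L) {
  if (np_min < 4) stop("lshade_config: np_min must be >= 4")
  if (np_init <= np_min) stop("lshade_config: np_init must exceed np_min")
  if (memory_size < 1) stop("lshade_config: memory_size must be >= 1")
  if (blend_c <= 0 || blend_c > 1) stop("lshade_config: blend_c must lie in (0, 1]")
  if (pbest_frac <= 0 || pbest_frac > 1)
    stop("lshade_config: pbest_frac must lie in (0, 1]")
  if (is.null(nf_max)) {
    if (is.null(max_gen))
      stop("lshade_config: give nf_max or max_gen")
    nf_max <- np_init + round(max_gen * (np_init + np_min) / 2)
  }
  if (nf_max < np_init) stop("lshade_config: nf_max must be >= np_init")
  structure(list(np_init = as.integer(np_init), np_min = as.integer(np_min),
                 memory_size = as.integer(memory_size), blend_c = blend_c,
                 nf_max = as.integer(nf_max),
                 max_gen = if (is.null(max_gen)) NULL else as.integer(max_gen),
                 pbest_frac = pbest_frac, archive_rate = archive_rate,
                 seed = as.integer(seed)),
            class = "lshade_config")
}

#' Success-history memory
#'
#' H cells for the scaling factor and crossover rate, all initialized at
#' 0.5, with a write index cycling 1..H.
#'
#' @param H Number of memory cells.
#' @return List with `m_sf`, `m_cr` and `write_index`.
#' @export
history_memory <- function(H) {
  list(m_sf = rep(0.5, H), m_cr = rep(0.5, H), write_index = 1L)
}

#' Sample (SF, CR) from the success-history memory
#'
#' A memory cell k is drawn uniformly; the scaling factor is Cauchy
#' distributed around `m_sf[k]` with scale 0.1 (resampled while <= 0,
#' clipped to 1 from above) and the crossover rate is normal around
#' `m_cr[k]` with sd 0.1, clipped to [0, 1]. Uses R's global RNG stream.
#'
#' @param mem A [history_memory()].
#' @return List with `SF` in (0, 1] and `CR` in [0, 1].
#' @export
sample_parameters <- function(mem) {
  k <- sample.int(length(mem$m_sf), 1L)
  repeat {
    SF <- stats::rcauchy(1L, mem$m_sf[k], 0.1)
    if (SF > 0) break
  }
  SF <- min(SF, 1)
  CR <- min(max(stats::rnorm(1L, mem$m_cr[k], 0.1), 0), 1)
  list(SF = SF, CR = CR)
}

#' Weighted Lehmer mean of successful control parameters
#'
#' `sum(w * S^2) / sum(w * S)` with weights proportional to the fitness
#' improvements `delta_f`. The result always lies within
#' `[min(S), max(S)]`.
#'
#' @param s Successful SF or CR values.
#' @param delta_f Positive fitness improvements, one per success.
#' @return The weighted Lehmer mean.
#' @export
weighted_lehmer_mean <- function(s, delta_f) {
  if (length(s) == 0L) stop("weighted_lehmer_mean: empty success archive")
  if (length(s) != length(delta_f))
    stop("weighted_lehmer_mean: length mismatch")
  w <- delta_f / sum(delta_f)
  sum(w * s^2) / sum(w * s)
}

#' Update one success-history memory cell
#'
#' With a non-empty success archive, the cell at the write index is
#' blended: `c * old + (1 - c) * mean_wl`, for SF and CR, after which the
#' write index advances cyclically. An empty archive leaves both the
#' memory and the index unchanged.
#'
#' @param mem A [history_memory()].
#' @param s_sf,s_cr Successful SF and CR values of the generation.
#' @param delta_f Matching fitness improvements.
#' @param c Blend factor in (0, 1].
#' @return The updated memory.
#' @export
update_memory <- function(mem, s_sf, s_cr, delta_f, c = 0.5) {
  if (c <= 0 || c > 1) stop("update_memory: c must lie in (0, 1]")
  if (length(s_sf) == 0L) return(mem)
  k <- mem$write_index
  mem$m_sf[k] <- c * mem$m_sf[k] + (1 - c) * weighted_lehmer_mean(s_sf, delta_f)
  mem$m_cr[k] <- c * mem$m_cr[k] + (1 - c) * weighted_lehmer_mean(s_cr, delta_f)
  mem$write_index <- (k %% length(mem$m_sf)) + 1L
  mem
}

#' Linear population size reduction schedule
#'
#' `NP(nf) = round((np_min - np_init) / nf_max * nf + np_init)`:
#' the population shrinks linearly in consumed objective evaluations from
#' `np_init` at nf = 0 to `np_min` at nf = nf_max.
#'
#' @param cfg An [lshade_config()].
#' @param nf Objective evaluations consumed so far.
#' @return Target population size.
#' @export
lpsr_size <- function(cfg, nf) {
  if (nf < 0 || nf > cfg$nf_max)
    stop("lpsr_size: nf must lie in [0, nf_max]")
  np <- round((cfg$np_min - cfg$np_init) / cfg$nf_max * nf + cfg$np_init)
  as.integer(min(max(np, cfg$np_min), cfg$np_init))
}

#' Generate one trial vector (current-to-pbest/1 with archive)
#'
#' Mutation `v = x_i + SF (x_pbest - x_i) + SF (x_r1 - x_r2)` where r1 is
#' drawn from the population (excluding i) and r2 from the population plus
#' the external archive (excluding i and r1), followed by binomial
#' crossover with a guaranteed inherited coordinate `j_rand`. Coordinates
#' leaving the unit box are repaired to the midpoint between the parent
#' and the violated bound.
#'
#' @param pop Population matrix (rows = individuals, unit box).
#' @param i Index of the target individual.
#' @param SF,CR Scaling factor and crossover rate for this trial.
#' @param pbest_idx Indices of the current pbest pool.
#' @param archive Matrix of archived parents (possibly 0 rows).
#' @return Trial genome vector.
#' @export
propose_trial <- function(pop, i, SF, CR, pbest_idx, archive) {
  NP <- nrow(pop)
  if (NP < 4L) stop("propose_trial: population must have at least 4 members")
  if (length(pbest_idx) == 0L) stop("propose_trial: empty pbest pool")
  D <- ncol(pop)
  pb <- pbest_idx[sample.int(length(pbest_idx), 1L)]
  r1 <- sample(setdiff(seq_len(NP), i), 1L)
  pool2 <- setdiff(seq_len(NP + nrow(archive)), c(i, r1))
  r2 <- pool2[sample.int(length(pool2), 1L)]
  x_r2 <- if (r2 <= NP) pop[r2, ] else archive[r2 - NP, ]
  x <- pop[i, ]
  v <- x + SF * (pop[pb, ] - x) + SF * (pop[r1, ] - x_r2)
  lo_bad <- v < 0
  hi_bad <- v > 1
  v[lo_bad] <- x[lo_bad] / 2
  v[hi_bad] <- (x[hi_bad] + 1) / 2
  j_rand <- sample.int(D, 1L)
  cross <- stats::runif(D) < CR
  cross[j_rand] <- TRUE
  u <- x
  u[cross] <- v[cross]
  u
}

#' Run the L-SHADE optimizer
#'
#' Maximizes `objective(genome)` over the `n_dim`-dimensional unit box.
#' Each generation samples per-individual (SF, CR) from the
#' success-history memory, builds current-to-pbest/1 trials with the
#' external archive, keeps trials that do not degrade fitness, records
#' strict improvements in the success arrays, blends them into the memory
#' via the weighted Lehmer mean, and shrinks the population on the linear
#' schedule by dropping the worst members (ties broken toward keeping
#' older indices).
#'
#' @param objective Function genome -> scalar fitness (maximized);
#'   non-finite returns are treated as worst possible and flagged with a
#'   warning.
#' @param n_dim Number of genome dimensions.
#' @param cfg An [lshade_config()].
#' @return List with `best_genome`, `best_fitness`, `nf` (evaluations
#'   used) and a per-generation `trace` data frame (generation, nf, NP,
#'   best fitness, memory snapshots).
#' @export
optimize_lshade <- function(objective, n_dim, cfg) {
  stopifnot(inherits(cfg, "lshade_config"))
  set.seed(cfg$seed)
  warned <- FALSE
  eval_f <- function(g) {
    f <- objective(g)
    if (!is.finite(f)) {
      if (!warned) {
        warning("optimize_lshade: non-finite objective value; treated as worst")
        warned <<- TRUE
      }
      f <- -Inf
    }
    f
  }
  NP <- cfg$np_init
  pop <- matrix(stats::runif(NP * n_dim), nrow = NP, ncol = n_dim)
  fit <- apply(pop, 1L, eval_f)
  nf <- NP
  mem <- history_memory(cfg$memory_size)
  archive <- matrix(numeric(0), nrow = 0L, ncol = n_dim)
  best_i <- which.max(fit)
  best_genome <- pop[best_i, ]
  best_fitness <- fit[best_i]
  gen <- 0L
  trace <- list(snapshot(gen, nf, NP, best_fitness, mem))

  while (nf < cfg$nf_max && NP >= 4L &&
         (is.null(cfg$max_gen) || gen < cfg$max_gen)) {
    gen <- gen + 1L
    n_trials <- min(NP, cfg$nf_max - nf)
    n_pb <- max(2L, ceiling(cfg$pbest_frac * NP))
    pbest_idx <- order(-fit)[seq_len(min(n_pb, NP))]
    s_sf <- s_cr <- s_df <- numeric(0)
    for (i in seq_len(n_trials)) {
      par <- sample_parameters(mem)
      u <- propose_trial(pop, i, par$SF, par$CR, pbest_idx, archive)
      fu <- eval_f(u)
      if (fu >= fit[i]) {
        if (fu > fit[i]) {
          dfi <- abs(fu - fit[i])
          # replacing a failed (-Inf) candidate: large finite improvement
          if (!is.finite(dfi)) dfi <- .Machine$double.xmax * 1e-10
          s_sf <- c(s_sf, par$SF)
          s_cr <- c(s_cr, par$CR)
          s_df <- c(s_df, dfi)
          archive <- rbind(archive, pop[i, , drop = FALSE])
        }
        pop[i, ] <- u
        fit[i] <- fu
      }
    }
    nf <- nf + n_trials
    cap <- round(cfg$archive_rate * NP)
    if (nrow(archive) > cap)
      archive <- archive[sample.int(nrow(archive), cap), , drop = FALSE]
    mem <- update_memory(mem, s_sf, s_cr, s_df, cfg$blend_c)
    if (max(fit) > best_fitness) {
      best_i <- which.max(fit)
      best_fitness <- fit[best_i]
      best_genome <- pop[best_i, ]
    }
    NP_new <- min(lpsr_size(cfg, nf), NP)
    if (NP_new < NP) {
      keep <- order(-fit)[seq_len(NP_new)]  # order() is stable: ties keep older index
      keep <- sort(keep)
      pop <- pop[keep, , drop = FALSE]
      fit <- fit[keep]
      NP <- NP_new
      cap <- round(cfg$archive_rate * NP)
      if (nrow(archive) > cap)
        archive <- archive[sample.int(nrow(archive), cap), , drop = FALSE]
    }
    trace[[length(trace) + 1L]] <- snapshot(gen, nf, NP, best_fitness, mem)
  }
  list(best_genome = best_genome, best_fitness = best_fitness, nf = nf,
       trace = do.call(rbind, trace))
}

snapshot <- function(gen, nf, NP, best, mem) {
  data.frame(generation = gen, nf = nf, NP = NP, best_fitness = best,
             m_sf = paste(sprintf("%.6f", mem$m_sf), collapse = ";"),
             m_cr = paste(sprintf("%.6f", mem$m_cr), collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Random-search baseline at an identical evaluation budget
#'
#' @inheritParams optimize_lshade
#' @return Same shape as [optimize_lshade()] (trace has one row per block
#'   of `np_init` evaluations).
#' @export
random_search <- function(objective, n_dim, cfg) {
  stopifnot(inherits(cfg, "lshade_config"))
  set.seed(cfg$seed)
  best_fitness <- -Inf
  best_genome <- NULL
  nf <- 0L
  trace <- list()
  gen <- 0L
  while (nf < cfg$nf_max) {
    gen <- gen + 1L
    nb <- min(cfg$np_init, cfg$nf_max - nf)
    block <- matrix(stats::runif(nb * n_dim), nrow = nb, ncol = n_dim)
    f <- apply(block, 1L, objective)
    f[!is.finite(f)] <- -Inf
    if (max(f) > best_fitness) {
      best_fitness <- max(f)
      best_genome <- block[which.max(f), ]
    }
    nf <- nf + nb
    trace[[gen]] <- data.frame(generation = gen, nf = nf, NP = nb,
                               best_fitness = best_fitness,
                               m_sf = NA_character_, m_cr = NA_character_,
                               stringsAsFactors = FALSE)
  }
  list(best_genome = best_genome, best_fitness = best_fitness, nf = nf,
       trace = do.call(rbind, trace))
}

#' Decode a unit-box genome into hyperparameters
#'
#' Integer dimensions map by `round(lo + g * (hi - lo))`; categorical
#' dimensions by `floor(g * n_levels)`, clamped. Decoding is deterministic
#' and total on the unit box.
#'
#' @param genome Numeric vector in [0, 1], one entry per dimension.
#' @param space A [search_space()].
#' @return Named list of decoded values.
#' @export
decode <- function(genome, space) {
  stopifnot(inherits(space, "search_space"))
  if (length(genome) != length(space$dimensions))
    stop("decode: genome length does not match the search space")
  out <- lapply(seq_along(genome), function(j) {
    d <- space$dimensions[[j]]
    g <- min(max(genome[j], 0), 1)
    if (d$kind == "integer") {
      as.integer(min(max(round(d$lo + g * (d$hi - d$lo)), d$lo), d$hi))
    } else {
      d$levels[[min(floor(g * length(d$levels)) + 1L, length(d$levels))]]
    }
  })
  names(out) <- space$names
  out
}

cv_folds_contiguous <- function(m, folds) {
  fold_of <- integer(nrow(m$values))
  for (g in unique(m$gesture)) {
    idx <- which(m$gesture == g)
    if (length(idx) < folds)
      stop(sprintf("tune: class '%s' has fewer rows than folds; degenerate folds",
                   g))
    cuts <- floor(seq(0, length(idx), length.out = folds + 1L))
    for (k in seq_len(folds))
      fold_of[idx[(cuts[k] + 1L):cuts[k + 1L]]] <- k
  }
  fold_of
}

#' Tune classifier hyperparameters with L-SHADE
#'
#' The objective is the mean validation accuracy of the backend refit at
#' each decoded candidate. Under the default `"cv"` protocol this is
#' k-fold cross-validation with contiguous per-class blocks inside the
#' training set (no leakage from the held-out test set); the `"holdout"`
#' protocol instead scores on a caller-supplied evaluation set, mirroring
#' setups that tune directly against the reserved 30 %.
#'
#' @param train A [feature_matrix()] with >= 2 rows per class.
#' @param backend_name Registered classifier backend.
#' @param space A [search_space()]; defaults to the backend's declared
#'   space with `max_features` capped at the actual feature count.
#' @param cfg An [lshade_config()].
#' @param optimizer `"lshade"` or the `"random"` search baseline.
#' @param protocol `"cv"` or `"holdout"`.
#' @param folds Number of cross-validation folds.
#' @param holdout Evaluation `feature_matrix` for the holdout protocol.
#' @param fit_seed Seed passed to every classifier fit inside the
#'   objective, keeping the objective deterministic per candidate.
#' @return List with `best_hp` (decoded), `best_fitness`, `history` (one
#'   row per objective evaluation) and the optimizer `trace`.
#' @export
tune <- function(train, backend_name = "et", space = NULL,
                 cfg = lshade_config(np_init = 20, max_gen = 20),
                 optimizer = c("lshade", "random"),
                 protocol = c("cv", "holdout"), folds = 3L, holdout = NULL,
                 fit_seed = 0L) {
  optimizer <- match.arg(optimizer)
  protocol <- match.arg(protocol)
  stopifnot(inherits(train, "feature_matrix"))
  be <- get_backend(backend_name)
  if (is.null(space)) {
    space <- be$space
    for (j in seq_along(space$dimensions)) {
      d <- space$dimensions[[j]]
      if (d$kind == "integer" && d$name == "max_features")
        space$dimensions[[j]]$hi <- min(d$hi, ncol(train$values))
    }
  }
  if (protocol == "holdout" && is.null(holdout))
    stop("tune: holdout protocol requires a holdout feature matrix")
  fold_of <- if (protocol == "cv") cv_folds_contiguous(train, folds)
  history <- new.env(parent = emptyenv())
  history$rows <- list()
  objective <- function(genome) {
    hp <- decode(genome, space)
    acc <- if (protocol == "cv") {
      mean(vapply(seq_len(folds), function(k) {
        tr <- fm_rows(train, which(fold_of != k))
        va <- fm_rows(train, which(fold_of == k))
        h <- train_classifier(backend_name, hp, tr, seed = fit_seed)
        evaluate(h, va)$accuracy
      }, numeric(1)))
    } else {
      h <- train_classifier(backend_name, hp, train, seed = fit_seed)
      evaluate(h, holdout)$accuracy
    }
    history$rows[[length(history$rows) + 1L]] <-
      c(list(fitness = acc), hp)
    acc
  }
  engine <- if (optimizer == "lshade") optimize_lshade else random_search
  res <- engine(objective, length(space$dimensions), cfg)
  hist_df <- do.call(rbind, lapply(history$rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  list(best_hp = decode(res$best_genome, space),
       best_fitness = res$best_fitness, nf = res$nf,
       history = hist_df, trace = res$trace)
}
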