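#' Hyperparameter search space
#'
#' An ordered list of typed dimensions, each either an integer range or a
#' categorical level set. The default space covers the five tunable
#' extremely-randomized-trees hyperparameters: number of estimators
#' [10, 100], split criterion {gini, entropy}, minimum samples to split a
#' node [2, 30], maximum features considered per split [2, n_features] and
#' maximum tree depth [1, 25].
#'
#' @param dimensions List of dimensions, each created with [dim_int()] or
#'   [dim_cat()].
#' @return An object of class `search_space`.
#' @export
search_space <- function(dimensions) {
  nm <- vapply(dimensions, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("search_space: duplicate dimension names")
  structure(list(dimensions = dimensions, names = nm),
            class = "search_space")
}

#' @rdname search_space
#' @param name Dimension name.
#' @param lo,hi Inclusive integer bounds, `lo <= hi`.
#' @export
dim_int <- function(name, lo, hi) {
  if (lo > hi) stop(sprintf("dim_int: %s: lo must be <= hi", name))
  list(name = name, kind = "integer", lo = as.integer(lo), hi = as.integer(hi))
}

#' @rdname search_space
#' @param levels Non-empty character vector of categorical levels.
#' @export
dim_cat <- function(name, levels) {
  if (length(levels) == 0) stop(sprintf("dim_cat: %s: empty level set", name))
  list(name = name, kind = "categorical", levels = as.character(levels))
}

#' @rdname search_space
#' @param n_features Upper bound for `max_features` (total feature count).
#' @export
default_search_space <- function(n_features = 34) {
  search_space(list(
    dim_int("n_estimators", 10, 100),
    dim_cat("criterion", c("gini", "entropy")),
    dim_int("min_samples_split", 2, 30),
    dim_int("max_features", 2, n_features),
    dim_int("max_depth", 1, 25)
  ))
}

#' Default hyperparameters (space-independent midpoints of the backend)
#' @return Named list of the extremely-randomized-trees defaults.
#' @export
default_et_params <- function() {
  list(n_estimators = 100L, criterion = "gini", min_samples_split = 2L,
       max_features = 6L, max_depth = 25L)
}

validate_hp <- function(hp, space) {
  for (d in space$dimensions) {
    if (!d$name %in% names(hp)) next
    v <- hp[[d$name]]
    if (d$kind == "integer") {
      if (!is.numeric(v) || v < d$lo || v > d$hi || v != round(v))
        stop(sprintf("hyperparameter '%s' = %s outside integer range [%d, %d]",
                     d$name, format(v), d$lo, d$hi))
    } else {
      if (!v %in% d$levels)
        stop(sprintf("hyperparameter '%s' = %s not in levels {%s}",
                     d$name, format(v), paste(d$levels, collapse = ", ")))
    }
  }
  extra <- setdiff(names(hp), space$names)
  if (length(extra))
    stop("unknown hyperparameter(s): ", paste(extra, collapse = ", "))
  invisible(TRUE)
}

# ---- classifier backend registry -------------------------------------------

backend_registry <- new.env(parent = emptyenv())

#' Register or list classifier backends
#'
#' Backends live behind a name registry so that the tuning machinery is
#' classifier-agnostic. Each backend supplies a fit function
#' `function(x, y, hp, seed)` returning a model with a working
#' `predict(model, newdata)` method via `predict_fn`, plus the search
#' space its hyperparameters are validated against.
#'
#' @param name Backend name (case-insensitive on lookup).
#' @param fit Fit function `function(x, y, hp, seed)`.
#' @param predict_fn Function `function(model, x)` returning a character
#'   vector of predicted labels.
#' @param space A [search_space()].
#' @export
register_backend <- function(name, fit, predict_fn, space) {
  assign(tolower(name),
         list(name = name, fit = fit, predict_fn = predict_fn, space = space),
         envir = backend_registry)
  invisible(name)
}

#' @rdname register_backend
#' @export
list_backends <- function() sort(ls(backend_registry))

get_backend <- function(name) {
  key <- tolower(name)
  if (!exists(key, envir = backend_registry))
    stop(sprintf("unknown classifier backend '%s'; registered backends: %s",
                 name, paste(list_backends(), collapse = ", ")))
  get(key, envir = backend_registry)
}

fit_ranger <- function(x, y, hp, seed, splitrule) {
  hp <- utils::modifyList(default_et_params(), hp)
  # criterion is carried in the space for interface fidelity; the ranger
  # backend realizes impurity as Gini for both levels
  ranger::ranger(
    x = x, y = factor(y),
    num.trees = hp$n_estimators,
    mtry = min(hp$max_features, ncol(x)),
    min.node.size = hp$min_samples_split,
    max.depth = hp$max_depth,
    splitrule = splitrule,
    num.random.splits = 1L,
    # ranger interprets seed 0 as "seed from clock"; shift to keep the
    # user-facing default seed 0 deterministic
    seed = as.integer(seed) + 1L,
    num.threads = 1L,
    verbose = FALSE
  )
}

register_default_backends <- function() {
  register_backend(
    "et",
    fit = function(x, y, hp, seed) fit_ranger(x, y, hp, seed, "extratrees"),
    predict_fn = function(model, x)
      as.character(stats::predict(model, data = x, num.threads = 1L)$predictions),
    space = default_search_space()
  )
  register_backend(
    "rf",
    fit = function(x, y, hp, seed) fit_ranger(x, y, hp, seed, "gini"),
    predict_fn = function(model, x)
      as.character(stats::predict(model, data = x, num.threads = 1L)$predictions),
    space = default_search_space()
  )
  if (requireNamespace("rpart", quietly = TRUE)) {
    register_backend(
      "dt",
      fit = function(x, y, hp, seed) {
        hp <- utils::modifyList(list(min_samples_split = 2L, max_depth = 25L), hp)
        df <- data.frame(x, .y = factor(y), check.names = FALSE)
        rpart::rpart(.y ~ ., data = df, method = "class",
                     control = rpart::rpart.control(
                       minsplit = hp$min_samples_split,
                       maxdepth = min(hp$max_depth, 30L), cp = 0))
      },
      predict_fn = function(model, x)
        as.character(stats::predict(model, newdata = as.data.frame(x),
                                    type = "class")),
      space = search_space(list(dim_int("min_samples_split", 2, 30),
                                dim_int("max_depth", 1, 25)))
    )
  }
}

#' Temporal train/test split
#'
#' Splits the feature matrix without shuffling so temporal order is kept
#' intact. By default the split is applied within each gesture's row block
#' (first `floor(train_frac * n_class)` windows train, remainder test) so
#' every class appears on both sides; `per_gesture = FALSE` splits the
#' matrix globally at one cut point.
#'
#' @param m A [feature_matrix()].
#' @param train_frac Fraction of rows for training, in (0, 1).
#' @param per_gesture Split within each gesture's block (default) or
#'   globally.
#' @return List with `feature_matrix` elements `train` and `test`.
#' @export
temporal_split <- function(m, train_frac = 0.7, per_gesture = TRUE) {
  stopifnot(inherits(m, "feature_matrix"))
  if (train_frac <= 0 || train_frac >= 1)
    stop("temporal_split: train_frac must lie strictly between 0 and 1")
  n <- nrow(m$values)
  if (per_gesture) {
    train_idx <- integer(0)
    for (g in unique(m$gesture)) {
      idx <- which(m$gesture == g)
      if (length(idx) < 2L)
        stop(sprintf("temporal_split: class '%s' has fewer than 2 windows", g))
      k <- floor(train_frac * length(idx))
      if (k < 1L || k >= length(idx))
        stop(sprintf("temporal_split: class '%s' would have an empty side", g))
      train_idx <- c(train_idx, idx[seq_len(k)])
    }
    train_idx <- sort(train_idx)
  } else {
    k <- floor(train_frac * n)
    if (k < 1L || k >= n) stop("temporal_split: empty train or test side")
    train_idx <- seq_len(k)
  }
  list(train = fm_rows(m, train_idx),
       test = fm_rows(m, setdiff(seq_len(n), train_idx)))
}

#' Train a classifier from the backend registry
#'
#' @param backend_name Registered backend name (e.g. `"et"`).
#' @param hp Named list of hyperparameters; validated against the backend's
#'   declared space. Missing entries take backend defaults.
#' @param train A [feature_matrix()] of training windows.
#' @param seed Integer seed; training is deterministic given it.
#' @return A trained model handle usable with [predict_classifier()] and
#'   [evaluate()].
#' @export
train_classifier <- function(backend_name, hp = list(), train, seed = 0L) {
  stopifnot(inherits(train, "feature_matrix"))
  be <- get_backend(backend_name)
  validate_hp(hp, be$space)
  model <- be$fit(train$values, train$gesture, hp, seed)
  structure(list(backend = be$name, model = model, hp = hp,
                 predict_fn = be$predict_fn,
                 classes = sort(unique(train$gesture)),
                 schema = colnames(train$values)),
            class = "semgrec_model")
}

#' @rdname train_classifier
#' @param handle A trained `semgrec_model`.
#' @param m A [feature_matrix()] with the training schema.
#' @export
predict_classifier <- function(handle, m) {
  stopifnot(inherits(handle, "semgrec_model"), inherits(m, "feature_matrix"))
  if (!identical(colnames(m$values), handle$schema))
    stop("predict_classifier: feature schema does not match the training schema")
  handle$predict_fn(handle$model, m$values)
}

#' Classification metrics from a confusion matrix
#'
#' Rows are true classes, columns predicted. Precision, recall and F1 are
#' support-weighted averages of the per-class values; with that averaging
#' the weighted recall is identically the accuracy. A class never
#' predicted contributes zero precision.
#'
#' @param confusion Square count matrix with identical row/col names.
#' @return List with `accuracy`, `precision`, `recall`, `f1` (fractions),
#'   `per_class` data frame and the `confusion` matrix.
#' @export
metrics_from_confusion <- function(confusion) {
  confusion <- as.matrix(confusion)
  stopifnot(nrow(confusion) == ncol(confusion), all(confusion >= 0))
  total <- sum(confusion)
  support <- rowSums(confusion)
  predicted <- colSums(confusion)
  tp <- diag(confusion)
  prec <- ifelse(predicted > 0, tp / predicted, 0)
  rec <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  w <- support / total
  list(accuracy = sum(tp) / total,
       precision = sum(w * prec),
       recall = sum(w * rec),
       f1 = sum(w * f1),
       per_class = data.frame(class = rownames(confusion), support = support,
                              precision = prec, recall = rec, f1 = f1,
                              row.names = NULL),
       confusion = confusion)
}

#' Evaluate a trained classifier on held-out windows
#'
#' @param handle A trained model from [train_classifier()].
#' @param test A non-empty [feature_matrix()].
#' @return An `eval_report`: accuracy and support-weighted
#'   precision/recall/F1 (fractions in [0, 1]), per-class metrics, the
#'   confusion matrix (rows = true class) and wall-clock inference time in
#'   milliseconds (informational).
#' @export
evaluate <- function(handle, test) {
  stopifnot(inherits(test, "feature_matrix"))
  if (nrow(test$values) == 0L) stop("evaluate: empty test set")
  t0 <- proc.time()[["elapsed"]]
  pred <- predict_classifier(handle, test)
  elapsed_ms <- (proc.time()[["elapsed"]] - t0) * 1000
  classes <- sort(unique(c(handle$classes, test$gesture)))
  confusion <- table(factor(test$gesture, levels = classes),
                     factor(pred, levels = classes))
  confusion <- matrix(as.integer(confusion), nrow = length(classes),
                      dimnames = list(classes, classes))
  rep <- metrics_from_confusion(confusion)
  rep$inference_time_ms <- elapsed_ms
  rep$n_test <- nrow(test$values)
  class(rep) <- "eval_report"
  rep
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: accuracy %.2f%%  precision %.2f%%  recall %.2f%%  F1 %.2f%%  (n=%d)\n",
              100 * x$accuracy, 100 * x$precision, 100 * x$recall,
              100 * x$f1, x$n_test))
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' Metrics are written as percentages rounded to two decimals; the
#' confusion matrix as nested integer lists.
#'
#' @param report An `eval_report`.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @export
report_to_json <- function(report, path = NULL) {
  obj <- list(
    accuracy = round(100 * report$accuracy, 2),
    precision = round(100 * report$precision, 2),
    recall = round(100 * report$recall, 2),
    f1 = round(100 * report$f1, 2),
    inference_time_ms = round(report$inference_time_ms, 3),
    classes = rownames(report$confusion),
    confusion = unname(apply(report$confusion, 1L, as.integer,
                             simplify = FALSE))
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

# ---- split-score diagnostic ------------------------------------------------

entropy_bits <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

#' Normalized information-gain score of a candidate split
#'
#' The diagnostic statistic of extremely-randomized-trees node scoring:
#' `2 * I / (H_split + H_class)` where `I` is the mutual information
#' between split side and class label, `H_split` the entropy of the
#' left/right sizes and `H_class` the class entropy of the parent, all in
#' bits. Ranges from 0 (split independent of labels) to 1 (pure, balanced
#' split).
#'
#' @param left,right Non-negative class-count vectors of the two children
#'   (same class order); their sum is the parent distribution.
#' @return The score in [0, 1].
#' @export
split_score <- function(left, right) {
  stopifnot(length(left) == length(right), all(left >= 0), all(right >= 0))
  nL <- sum(left)
  nR <- sum(right)
  if (nL == 0 || nR == 0) stop("split_score: both children must be non-empty")
  parent <- left + right
  n <- nL + nR
  if (n < 2) stop("split_score: parent must have at least 2 items")
  h_class <- entropy_bits(parent)
  h_split <- entropy_bits(c(nL, nR))
  info <- h_class - (nL / n * entropy_bits(left) + nR / n * entropy_bits(right))
  2 * info / (h_split + h_class)
}

#' Two-sided paired t-test on matched accuracy vectors
#'
#' @param a,b Equal-length numeric vectors (>= 2) of paired observations,
#'   e.g. per-subject accuracies under two methods.
#' @return List with `t`, `p` and `df`.
#' @export
paired_ttest <- function(a, b) {
  if (length(a) != length(b)) stop("paired_ttest: unequal lengths")
  if (length(a) < 2L) stop("paired_ttest: need at least 2 pairs")
  d <- a - b
  # constant shifts leave only floating-point residue in the differences
  if (stats::sd(d) <= 1e-10 * max(abs(mean(d)), .Machine$double.eps))
    stop("paired_ttest: zero variance of paired differences; t undefined")
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter))
}

#' Cross-session evaluation
#'
#' Trains once on all windows of one recording session and evaluates on
#' each of the remaining sessions separately, probing robustness to
#' session-to-session drift (electrode shift, fatigue). No test row is
#' drawn from the training session.
#'
#' @param m A [feature_matrix()] with per-row `session` labels.
#' @param train_session Session id used for training.
#' @param test_sessions Session ids to evaluate on (default: all others).
#' @param backend_name,hp,seed Passed to [train_classifier()].
#' @return Named list of `eval_report`s, one per test session, named
#'   `"<train>-><test>"`.
#' @export
cross_session_eval <- function(m, train_session,
                               test_sessions = setdiff(unique(m$session),
                                                       train_session),
                               backend_name = "et", hp = list(), seed = 0L) {
  stopifnot(inherits(m, "feature_matrix"))
  present <- unique(m$session)
  missing <- setdiff(c(train_session, test_sessions), present)
  if (length(missing))
    stop("cross_session_eval: session id(s) not present: ",
         paste(missing, collapse = ", "))
  if (length(test_sessions) == 0L)
    stop("cross_session_eval: no test sessions distinct from the training session")
  train <- fm_rows(m, which(m$session == train_session))
  handle <- train_classifier(backend_name, hp, train, seed = seed)
  reports <- lapply(test_sessions, function(s)
    evaluate(handle, fm_rows(m, which(m$session == s))))
  names(reports) <- paste0(train_session, "->", test_sessions)
  reports
}
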