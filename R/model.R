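#' Label balance confidence from an ABC score
#'
#' Activities-specific Balance Confidence (ABC) scores of 80% or greater
#' are labelled high confidence; lower scores are low confidence.
#'
#' @param abc_score Numeric vector of ABC scores in percent, 0-100.
#' @param threshold Threshold in percent (default 80, inclusive).
#' @return Factor with levels `low`, `high` (low first: the clinically
#'   conservative class).
#' @export
label_confidence <- function(abc_score, threshold = 80) {
  if (any(!is.finite(abc_score)) || any(abc_score < 0 | abc_score > 100))
    stop("abc_score must lie in [0, 100]")
  factor(ifelse(abc_score >= threshold, "high", "low"),
         levels = c("low", "high"))
}

#' Total ABC score from the 16 item responses
#'
#' The ABC questionnaire has 16 activity items, each rated 0-100%; the
#' final score is the arithmetic mean of the items.
#'
#' @param item_scores Numeric vector of exactly 16 item scores in
#'   \[0, 100\].
#' @return The total score in percent.
#' @export
abc_total <- function(item_scores) {
  if (length(item_scores) != 16)
    stop("ABC has exactly 16 items, got ", length(item_scores))
  if (any(!is.finite(item_scores)) ||
      any(item_scores < 0 | item_scores > 100))
    stop("item scores must lie in [0, 100]")
  mean(item_scores)
}

# Absolute feature-class (point-biserial) and feature-feature (Pearson)
# correlations on standardized columns; zero-variance features get 0.
cfs_correlations <- function(X, y) {
  yf <- factor(y)
  yb <- as.numeric(yf == levels(yf)[2])
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    message("zero-variance feature(s) treated as uncorrelated: ",
            paste(colnames(X)[sds == 0], collapse = ", "))
  Xs <- X
  Xs[, sds == 0] <- 0
  rcf <- suppressWarnings(abs(as.vector(stats::cor(Xs, yb))))
  rcf[!is.finite(rcf)] <- 0
  rff <- suppressWarnings(abs(stats::cor(Xs)))
  rff[!is.finite(rff)] <- 0
  diag(rff) <- 1
  list(rcf = rcf, rff = rff)
}

cfs_merit_from_cors <- function(subset, rcf, rff) {
  k <- length(subset)
  mean_rcf <- mean(rcf[subset])
  mean_rff <- if (k > 1) {
    s <- rff[subset, subset, drop = FALSE]
    (sum(s) - k) / (k * (k - 1))
  } else 0
  k * mean_rcf / sqrt(k + k * (k - 1) * mean_rff)
}

#' CFS merit of a feature subset
#'
#' The correlation-based feature selection merit
#' `k * rbar_cf / sqrt(k + k (k - 1) * rbar_ff)`, where `rbar_cf` is the
#' mean absolute feature-class (point-biserial) correlation of the subset
#' and `rbar_ff` the mean absolute pairwise feature-feature correlation
#' within it. High merit rewards subsets that correlate with the class but
#' not with each other.
#'
#' @param subset Column indices or names of the subset (non-empty).
#' @param X Numeric feature matrix, participants by features.
#' @param y Class labels (two classes).
#' @return The merit (scalar).
#' @export
cfs_merit <- function(subset, X, y) {
  if (length(subset) == 0) stop("subset must be non-empty")
  if (is.character(subset)) subset <- match(subset, colnames(X))
  cors <- cfs_correlations(X, y)
  cfs_merit_from_cors(subset, cors$rcf, cors$rff)
}

#' Correlation-based feature selection with best-first search
#'
#' Forward best-first search over feature subsets maximizing the CFS merit,
#' starting from the empty set and stopping after `max_stale` consecutive
#' expansions that fail to improve the best merit found. Deterministic for
#' a given column order (ties expand the earlier-added, lower-index
#' subset).
#'
#' @param X Numeric feature matrix, participants by features (named
#'   columns).
#' @param y Class labels; both classes must be present with at least 2
#'   members.
#' @param max_stale Consecutive non-improving expansions allowed before
#'   stopping (default 5).
#' @return A list of class `cfs_result`: `selected` (feature names),
#'   `merit`, and `trace` (data.frame of expanded subsets and merits).
#' @export
cfs_select <- function(X, y, max_stale = 5) {
  y <- factor(y)
  if (nlevels(y) < 2 || any(table(y) < 2))
    stop("need at least 2 participants in each of 2 classes")
  p <- ncol(X)
  cors <- cfs_correlations(X, y)
  key <- function(s) paste(s, collapse = ",")
  evaluated <- new.env(parent = emptyenv())
  open_sets <- list(integer(0))
  open_merits <- -Inf
  best_subset <- integer(0)
  best_merit <- -Inf
  stale <- 0L
  trace <- list()
  while (length(open_sets) > 0 && stale < max_stale) {
    pick <- which.max(open_merits)
    node <- open_sets[[pick]]
    node_merit <- open_merits[pick]
    open_sets <- open_sets[-pick]
    open_merits <- open_merits[-pick]
    trace[[length(trace) + 1L]] <-
      data.frame(subset = key(node), merit = node_merit)
    improved <- FALSE
    for (j in setdiff(seq_len(p), node)) {
      child <- sort(c(node, j))
      k <- key(child)
      if (!is.null(evaluated[[k]])) next
      m <- cfs_merit_from_cors(child, cors$rcf, cors$rff)
      evaluated[[k]] <- m
      open_sets[[length(open_sets) + 1L]] <- child
      open_merits <- c(open_merits, m)
      if (m > best_merit + 1e-12) {
        best_merit <- m
        best_subset <- child
        improved <- TRUE
      }
    }
    stale <- if (improved) 0L else stale + 1L
  }
  structure(list(
    selected = colnames(X)[best_subset],
    merit = best_merit,
    trace = do.call(rbind, trace)
  ), class = "cfs_result")
}

#' Random-forest configuration
#'
#' Defaults mirror common desktop machine-learning tool conventions: 100
#' trees, `floor(log2(p)) + 1` candidate features per split, bootstrap
#' samples of size n with replacement, unlimited depth.
#'
#' @param n_trees Number of trees.
#' @param features_per_split Candidate features per split; `NULL` means
#'   `floor(log2(p)) + 1`.
#' @param seed Integer seed controlling tree growth.
#' @return A list of class `forest_config`.
#' @export
forest_config <- function(n_trees = 100, features_per_split = NULL,
                          seed = 1L) {
  stopifnot(n_trees >= 1)
  structure(list(n_trees = n_trees, features_per_split = features_per_split,
                 seed = as.integer(seed)),
            class = "forest_config")
}

#' Fit a random-forest balance-confidence classifier
#'
#' An ensemble of decision trees, each grown on a bootstrap sample with a
#' random subset of candidate features at every split; classification is by
#' majority vote over trees, with exact vote ties broken toward low
#' confidence (the clinically conservative class).
#'
#' @param X Numeric feature matrix, participants by features.
#' @param y Class labels (`low`/`high`), both classes present.
#' @param cfg A [forest_config()].
#' @return A model of class `confidence_forest`.
#' @export
fit_forest <- function(X, y, cfg = forest_config()) {
  y <- factor(y, levels = c("low", "high"))
  if (any(table(y) == 0))
    stop("training data must contain both classes")
  mtry <- cfg$features_per_split
  if (is.null(mtry)) mtry <- floor(log2(ncol(X))) + 1
  mtry <- max(1L, min(mtry, ncol(X)))
  set.seed(cfg$seed)
  rf <- randomForest::randomForest(x = as.data.frame(X), y = y,
                                   ntree = cfg$n_trees, mtry = mtry)
  structure(list(rf = rf, feature_names = colnames(X), cfg = cfg),
            class = "confidence_forest")
}

#' @export
predict.confidence_forest <- function(object, newdata, ...) {
  nd <- as.data.frame(newdata)[, object$feature_names, drop = FALSE]
  votes <- stats::predict(object$rf, nd, type = "vote", norm.votes = TRUE)
  factor(ifelse(votes[, "high"] > votes[, "low"], "high", "low"),
         levels = c("low", "high"))
}

#' Confusion matrix from labels
#'
#' @param truth,predicted Factors/vectors of `low`/`high` labels; positive
#'   class = high confidence.
#' @return A list of class `confusion_matrix` with counts `tp`, `fn`,
#'   `fp`, `tn`.
#' @export
confusion_matrix <- function(truth, predicted) {
  truth <- factor(truth, levels = c("low", "high"))
  predicted <- factor(predicted, levels = c("low", "high"))
  structure(list(
    tp = sum(truth == "high" & predicted == "high"),
    fn = sum(truth == "high" & predicted == "low"),
    fp = sum(truth == "low" & predicted == "high"),
    tn = sum(truth == "low" & predicted == "low")
  ), class = "confusion_matrix")
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy, sensitivity (recall of the high-confidence class),
#' specificity, and precision, in percent rounded to one decimal, with the
#' positive class being high confidence. Ratios with zero denominators are
#' returned as `NA` with a message.
#'
#' @param cm A [confusion_matrix()] or a list with counts `tp`, `fn`,
#'   `fp`, `tn`.
#' @return A list of class `confidence_metrics`: the four metrics (percent,
#'   1 decimal), `n`, and `n_correct`.
#' @export
compute_metrics <- function(cm) {
  n <- cm$tp + cm$fn + cm$fp + cm$tn
  if (n <= 0) stop("confusion matrix counts sum to zero")
  ratio <- function(num, den, what) {
    if (den == 0) {
      message(what, " undefined (zero denominator)")
      return(NA_real_)
    }
    round(100 * num / den, 1)
  }
  structure(list(
    accuracy = ratio(cm$tp + cm$tn, n, "accuracy"),
    sensitivity = ratio(cm$tp, cm$tp + cm$fn, "sensitivity"),
    specificity = ratio(cm$tn, cm$tn + cm$fp, "specificity"),
    precision = ratio(cm$tp, cm$tp + cm$fp, "precision"),
    n = n, n_correct = cm$tp + cm$tn
  ), class = "confidence_metrics")
}

#' Participant-level leave-one-out cross-validation
#'
#' For each participant, a model is trained on all other participants and
#' used to predict the held-out one; the confusion matrix accumulates over
#' all n folds, so exactly n models are trained. Feature selection is
#' either `global` (CFS once on the full cohort before cross-validation,
#' matching a single reported global selection) or `nested` (CFS re-run
#' inside every training fold; leakage-safe).
#'
#' @param X Numeric feature matrix, participants by features.
#' @param y Class labels (`low`/`high`); at least 3 per class.
#' @param cfg A [forest_config()]; fold seeds are derived from `cfg$seed`.
#' @param selection `"global"`, `"nested"`, or `"none"`.
#' @param max_stale Best-first stopping patience passed to [cfs_select()].
#' @return A list of class `loocv_result`: `confusion`
#'   ([confusion_matrix()]), `metrics`, `predictions` (data.frame),
#'   `selected` (global mode) or `selected_per_fold` (nested mode),
#'   `n_models`.
#' @export
loocv <- function(X, y, cfg = forest_config(), selection = c("global",
                  "nested", "none"), max_stale = 5) {
  selection <- match.arg(selection)
  y <- factor(y, levels = c("low", "high"))
  if (any(table(y) < 3))
    stop("need at least 3 participants per class for LOOCV")
  n <- nrow(X)
  selected <- NULL
  selected_per_fold <- vector("list", n)
  if (selection == "global") {
    sel <- cfs_select(X, y, max_stale = max_stale)
    selected <- sel$selected
    X <- X[, selected, drop = FALSE]
  }
  pred <- factor(rep(NA_character_, n), levels = c("low", "high"))
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]
    ytr <- y[-i]
    if (selection == "nested") {
      sel <- cfs_select(Xtr, ytr, max_stale = max_stale)
      selected_per_fold[[i]] <- sel$selected
      Xtr <- Xtr[, sel$selected, drop = FALSE]
    }
    fold_cfg <- cfg
    fold_cfg$seed <- cfg$seed + i
    fit <- fit_forest(Xtr, ytr, fold_cfg)
    pred[i] <- predict(fit, X[i, , drop = FALSE])
  }
  cm <- confusion_matrix(y, pred)
  structure(list(
    confusion = cm,
    metrics = compute_metrics(cm),
    predictions = data.frame(row = seq_len(n), truth = y, predicted = pred),
    selected = selected,
    selected_per_fold = if (selection == "nested") selected_per_fold,
    n_models = n
  ), class = "loocv_result")
}
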