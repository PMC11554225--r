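#' Candidate trajectory features
#'
#' The eleven candidate predictors computed by [window_features()], in the
#' order used throughout the package.
#' @export
candidate_features <- function() {
  c("sog_avg", "sog_std", "crow_flies_km", "total_dist_km", "depth_avg",
    "depth_std", "cog_avg_abs_d", "d_cog_startend", "moon", "month",
    "day_of_week")
}

#' Fit a random-forest fishing classifier
#'
#' Grows `n_trees` classification trees, each on a bootstrap sample of size
#' N (the training size), choosing the best of `m_try` randomly drawn
#' candidate features at each split and growing nodes down to `min_node`
#' observations. Prediction is by majority vote over trees; out-of-bag (OOB)
#' misclassification is estimated from the votes of trees whose bootstrap
#' sample excluded each observation. The ensemble is backed by
#' \pkg{ranger}.
#'
#' @param formula Model formula, e.g. `fishing ~ sog_avg + sog_std + ...`.
#'   The response may be logical or a two-level factor; the positive
#'   (fishing) class is `TRUE` / the `"fishing"` level / the second level.
#' @param data Data frame of labeled feature vectors (no missing values in
#'   the model frame).
#' @param n_trees Number of trees K (default 500).
#' @param max_depth Maximum tree depth; `NULL` or `Inf` for unlimited.
#' @param m_try Features drawn per split; default `floor(sqrt(p))`.
#' @param min_node Minimum node size (default 1).
#' @param seed Integer seed; fixing it makes the fit bit-reproducible.
#' @param importance Importance measure passed to ranger
#'   (default `"impurity"`).
#' @return An object of class `"fishing_forest"` with elements `forest`
#'   (the ranger object), `features`, `config`, `oob_error`, `importance`
#'   (normalized to sum to 1) and `levels`.
#' @seealso [predict.fishing_forest()], [tune_forest()], [select_features()]
#' @export
fishing_forest <- function(formula, data, n_trees = 500, max_depth = NULL,
                           m_try = NULL, min_node = 1, seed = NULL,
                           importance = "impurity") {
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  y <- fishing_factor(stats::model.response(mf))
  if (nlevels(droplevels(y)) < 2)
    stop("training data contain a single class")
  x <- mf[, -1, drop = FALSE]
  p <- ncol(x)
  if (is.null(m_try)) m_try <- max(1L, floor(sqrt(p)))
  stopifnot(m_try >= 1, m_try <= p)
  depth_arg <- if (is.null(max_depth) || !is.finite(max_depth)) 0
               else as.integer(max_depth)
  fit <- ranger::ranger(
    x = x, y = y, num.trees = n_trees, mtry = m_try,
    min.node.size = min_node, max.depth = depth_arg,
    importance = importance, seed = seed,
    respect.unordered.factors = "order", num.threads = 1
  )
  imp <- fit$variable.importance
  imp <- pmax(imp, 0)
  imp <- if (sum(imp) > 0) imp / sum(imp) else rep(1 / p, p)
  structure(list(
    forest = fit,
    features = colnames(x),
    config = list(n_trees = n_trees,
                  max_depth = if (depth_arg == 0) Inf else depth_arg,
                  m_try = m_try, min_node = min_node, seed = seed),
    oob_error = fit$prediction.error,
    importance = imp,
    levels = levels(y),
    call = match.call()
  ), class = "fishing_forest")
}

# Coerce labels to factor c("transit", "fishing"); fishing is the positive
# class throughout.
fishing_factor <- function(y) {
  if (is.logical(y)) {
    factor(ifelse(y, "fishing", "transit"), levels = c("transit", "fishing"))
  } else if (is.factor(y)) {
    if (all(levels(y) %in% c("transit", "fishing")))
      factor(y, levels = c("transit", "fishing"))
    else
      factor(y, levels = levels(y))
  } else {
    fishing_factor(as.logical(y))
  }
}

#' @export
print.fishing_forest <- function(x, ...) {
  cat("Random-forest fishing classifier\n")
  cat(sprintf("  trees: %d  m_try: %d  min node: %d  max depth: %s\n",
              x$config$n_trees, x$config$m_try, x$config$min_node,
              if (is.finite(x$config$max_depth))
                as.character(x$config$max_depth) else "unlimited"))
  cat(sprintf("  features (%d): %s\n", length(x$features),
              paste(x$features, collapse = ", ")))
  cat(sprintf("  OOB error: %.4f\n", x$oob_error))
  invisible(x)
}

#' @export
summary.fishing_forest <- function(object, ...) {
  imp <- sort(object$importance, decreasing = TRUE)
  structure(list(config = object$config, oob_error = object$oob_error,
                 importance = imp, n_features = length(object$features)),
            class = "summary.fishing_forest")
}

#' @export
print.summary.fishing_forest <- function(x, ...) {
  cat(sprintf("Fishing forest: %d trees, OOB error %.4f\n",
              x$config$n_trees, x$oob_error))
  cat("Feature importance (normalized):\n")
  print(round(x$importance, 4))
  invisible(x)
}

#' Importance barplot for a fitted fishing forest
#' @param x A `"fishing_forest"`.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.fishing_forest <- function(x, ...) {
  imp <- sort(x$importance)
  graphics::barplot(imp, horiz = TRUE, las = 1,
                    xlab = "normalized importance",
                    main = "Fishing forest feature importance", ...)
  invisible(x)
}

#' Predict fishing state with a fitted forest
#'
#' Majority vote over trees; the returned `vote` is the fraction of trees
#' voting fishing. Exact 0.5 ties classify as fishing (conservative for
#' value attribution: value is over-attributed rather than dropped).
#'
#' @param object A `"fishing_forest"`.
#' @param newdata Data frame containing the model's feature columns.
#' @param chunk Rows predicted per block (bounds the per-tree vote matrix).
#' @param ... Unused.
#' @return Data frame with logical `fishing` and numeric `vote` in `[0, 1]`.
#' @export
predict.fishing_forest <- function(object, newdata, chunk = 20000L, ...) {
  missing <- setdiff(object$features, names(newdata))
  if (length(missing))
    stop("missing feature column(s): ", paste(missing, collapse = ", "))
  x <- newdata[, object$features, drop = FALSE]
  n <- nrow(x)
  vote <- numeric(n)
  # predict.all values index the forest's level set
  fish_lvl <- match("fishing", object$forest$forest$levels)
  starts <- seq(1L, n, by = chunk)
  for (s in starts) {
    e <- min(s + chunk - 1L, n)
    pr <- stats::predict(object$forest, data = x[s:e, , drop = FALSE],
                         predict.all = TRUE, num.threads = 1)
    vote[s:e] <- rowMeans(pr$predictions == fish_lvl)
  }
  data.frame(fishing = vote >= 0.5, vote = vote)
}

#' Grouped k-fold assignment by trip
#'
#' Trips (not pings) are shuffled and dealt into `k` folds, so no trip
#' contributes pings to both the training and test side of any fold; at
#' one-minute resolution adjacent pings are near-duplicates and ungrouped
#' folds would leak.
#'
#' @param trip_id Character vector, one entry per row.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer fold id per row.
#' @export
grouped_folds <- function(trip_id, k = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  trips <- unique(trip_id)
  k <- min(k, length(trips))
  fold_of <- sample(rep_len(seq_len(k), length(trips)))
  names(fold_of) <- trips
  unname(fold_of[trip_id])
}

#' Tune forest hyperparameters by grouped cross-validation
#'
#' Scores every configuration in `grid` by mean cross-validated AUC over
#' trip-grouped folds and returns the best, breaking ties toward fewer
#' trees, then shallower depth. Folds whose test side holds one class are
#' skipped with a warning.
#'
#' @param formula,data As in [fishing_forest()]; `data` must carry
#'   `trip_id`.
#' @param grid Data frame with columns `n_trees` and `max_depth` (`Inf` for
#'   unlimited).
#' @param k Number of grouped folds (default 5).
#' @param seed Integer seed (folds and forests).
#' @param ... Extra arguments for [fishing_forest()].
#' @return List with `n_trees`, `max_depth` and a `scores` data frame of
#'   fold-mean AUC per configuration.
#' @export
tune_forest <- function(formula, data, grid, k = 5, seed = NULL, ...) {
  stopifnot(nrow(grid) >= 1, all(c("n_trees", "max_depth") %in% names(grid)))
  fold <- grouped_folds(data$trip_id, k, seed)
  k <- max(fold)
  y <- fishing_factor(stats::model.response(
    stats::model.frame(formula, data, na.action = stats::na.fail)))
  auc <- matrix(NA_real_, nrow(grid), k)
  for (f in seq_len(k)) {
    test <- fold == f
    ytest <- y[test]
    if (nlevels(droplevels(ytest)) < 2 ||
        nlevels(droplevels(y[!test])) < 2) {
      warning("fold ", f, " holds a single class; skipped")
      next
    }
    for (g in seq_len(nrow(grid))) {
      fit <- fishing_forest(formula, data[!test, , drop = FALSE],
                            n_trees = grid$n_trees[g],
                            max_depth = grid$max_depth[g],
                            seed = seed, ...)
      v <- predict(fit, data[test, , drop = FALSE])$vote
      auc[g, f] <- as.numeric(pROC::auc(
        pROC::roc(response = ytest, predictor = v,
                  levels = c("transit", "fishing"), direction = "<",
                  quiet = TRUE)))
    }
  }
  score <- rowMeans(auc, na.rm = TRUE)
  ord <- order(-score, grid$n_trees, grid$max_depth)
  best <- ord[1]
  list(n_trees = grid$n_trees[best], max_depth = grid$max_depth[best],
       scores = cbind(grid, mean_auc = score))
}

#' Recursive feature elimination with grouped cross-validation
#'
#' Starting from all candidate features, repeatedly drops the least
#' important feature (impurity importance of a forest fit on the full data)
#' and records grouped-CV accuracy at each subset size, then returns the
#' smallest subset whose accuracy is within `tol` of the best.
#'
#' @param formula Full-model formula (response ~ candidates).
#' @param data Labeled feature data frame with `trip_id`.
#' @param k Grouped folds for the accuracy curve (default 5).
#' @param tol Accuracy tolerance for the subset-size choice (default 0.005).
#' @param seed Integer seed.
#' @param ... Extra arguments for [fishing_forest()].
#' @return List with `selected` (character vector, most important first),
#'   `curve` (data frame of subset size, accuracy, features) and
#'   `elimination_order` (first-dropped first).
#' @export
select_features <- function(formula, data, k = 5, tol = 0.005, seed = NULL,
                            ...) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  response <- names(mf)[1]
  feats <- colnames(mf)[-1]
  stopifnot(length(feats) >= 2)
  fold <- grouped_folds(data$trip_id, k, seed)
  cv_acc <- function(fs) {
    acc <- numeric(0)
    fml <- stats::reformulate(fs, response)
    for (f in seq_len(max(fold))) {
      test <- fold == f
      fit <- fishing_forest(fml, data[!test, , drop = FALSE], seed = seed,
                            ...)
      pr <- predict(fit, data[test, , drop = FALSE])
      truth <- fishing_factor(mf[[response]][test]) == "fishing"
      acc <- c(acc, mean(pr$fishing == truth))
    }
    mean(acc)
  }
  dropped <- character(0)
  cur <- feats
  sizes <- integer(0); accs <- numeric(0); sets <- list()
  while (length(cur) >= 1) {
    sizes <- c(sizes, length(cur))
    accs <- c(accs, cv_acc(cur))
    sets[[length(sets) + 1]] <- cur
    if (length(cur) == 1) break
    fit <- fishing_forest(stats::reformulate(cur, response), data,
                          seed = seed, ...)
    worst <- names(which.min(fit$importance))
    dropped <- c(dropped, worst)
    cur <- setdiff(cur, worst)
  }
  best <- max(accs)
  ok <- which(accs >= best - tol)
  pick <- ok[which.max(ok)]  # curve is ordered large -> small subsets
  sel <- sets[[pick]]
  full_fit <- fishing_forest(stats::reformulate(sel, response), data,
                             seed = seed, ...)
  list(selected = names(sort(full_fit$importance, decreasing = TRUE)),
       curve = data.frame(
         size = sizes, cv_accuracy = accs,
         features = vapply(sets, paste, "", collapse = "+")),
       elimination_order = dropped)
}

#' Speed-cutoff fishing classifier
#'
#' The baseline rule: a location is fishing iff speed over ground is at or
#' below the cutoff (5 knots for scallop dredge; presets `"otter_trawl"`
#' uses 4 knots and `"sink_gillnet"` 1.3 knots).
#'
#' @param sog Speed over ground, knots.
#' @param cutoff Cutoff in knots, or a preset name.
#' @return Logical vector; `TRUE` = fishing. Exactly at the cutoff
#'   classifies as fishing.
#' @export
speed_cutoff <- function(sog, cutoff = 5) {
  if (is.character(cutoff)) {
    cutoff <- switch(cutoff,
                     scallop_dredge = 5, otter_trawl = 4, sink_gillnet = 1.3,
                     stop("unknown cutoff preset: ", cutoff))
  }
  sog <= cutoff
}

#' Classification metrics against truth labels
#'
#' @param truth,predicted Equal-length logical vectors (`TRUE` = fishing).
#' @return List of class `"fishing_metrics"`: `confusion` (2x2 counts with
#'   fishing positive), `accuracy`, `balanced_accuracy`.
#' @export
classification_metrics <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stop("truth and predicted lengths differ")
  truth <- as.logical(truth)
  predicted <- as.logical(predicted)
  tp <- sum(truth & predicted)
  fp <- sum(!truth & predicted)
  fn <- sum(truth & !predicted)
  tn <- sum(!truth & !predicted)
  n <- tp + fp + fn + tn
  recalls <- c(if (tp + fn > 0) tp / (tp + fn),
               if (tn + fp > 0) tn / (tn + fp))
  structure(list(
    confusion = matrix(c(tp, fn, fp, tn), 2, 2,
                       dimnames = list(truth = c("fishing", "transit"),
                                       predicted = c("fishing", "transit"))),
    accuracy = (tp + tn) / n,
    balanced_accuracy = mean(recalls)
  ), class = "fishing_metrics")
}

#' @export
print.fishing_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.4f, balanced accuracy %.4f\n",
              x$accuracy, x$balanced_accuracy))
  print(x$confusion)
  invisible(x)
}

#' Persist / restore a fitted forest
#'
#' Writes the model with its configuration, feature list, importances and
#' OOB error to a versioned RDS file.
#' @param model A `"fishing_forest"`.
#' @param path File path.
#' @export
save_forest <- function(model, path) {
  stopifnot(inherits(model, "fishing_forest"))
  saveRDS(list(format = "dredgetrack-forest-1", model = model), path)
  invisible(path)
}

#' @rdname save_forest
#' @export
load_forest <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "dredgetrack-forest-1"))
    stop("not a dredgetrack forest file")
  obj$model
}
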