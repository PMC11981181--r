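# Linear-SVM screening of high vs low trait groups: leave-one-out
# cross-validation, joint feature-subset and cost selection, Platt
# probability calibration, and confusion metrics.

.as_group_factor <- function(labels) {
  f <- factor(as.character(labels), levels = c("high", "low"))
  if (any(is.na(f))) stop("labels must be 'high' or 'low'")
  f
}

# fit a linear soft-margin SVM and return weights oriented so that
# the decision function f(x) = x . w + b is positive for "high"
.fit_linear_svm <- function(x, y, cost) {
  m <- e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE)
  w <- drop(t(m$coefs) %*% m$SV)
  b <- -m$rho
  pr <- predict(m, x[1, , drop = FALSE], decision.values = TRUE)
  pos <- strsplit(colnames(attr(pr, "decision.values")), "/")[[1]][1]
  if (pos != "high") { w <- -w; b <- -b }
  list(w = w, b = b)
}

.standardizer <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl)
}

.apply_std <- function(x, std) {
  sweep(sweep(x, 2, std$center, "-"), 2, std$scale, "/")
}

# Platt sigmoid calibration P(high | f) = 1 / (1 + exp(A f + B)),
# fitted on decision values with prior-smoothed targets; deterministic.
.platt_fit <- function(f, ispos) {
  np <- sum(ispos); nn <- sum(!ispos)
  tgt <- ifelse(ispos, (np + 1) / (np + 2), 1 / (nn + 2))
  nll <- function(ab) {
    z <- ab[1] * f + ab[2]
    # numerically stable: log(1+exp(z)) etc.
    lse <- ifelse(z > 0, z + log1p(exp(-z)), log1p(exp(z)))
    sum(tgt * lse + (1 - tgt) * (lse - z))
  }
  grad <- function(ab) {
    z <- ab[1] * f + ab[2]
    p <- 1 / (1 + exp(-z))          # = 1 - P(high)
    d <- p - (1 - tgt)
    c(sum(d * f), sum(d))
  }
  init <- c(0, log((nn + 1) / (np + 1)))
  fit <- stats::optim(init, nll, grad, method = "BFGS",
                      control = list(maxit = 200, reltol = 1e-10))
  list(A = fit$par[1], B = fit$par[2])
}

.platt_prob <- function(f, platt) {
  1 / (1 + exp(platt$A * f + platt$B))
}

#' Fit a linear screening SVM on the full data
#'
#' Standardizes the selected feature columns (z-score on the training
#' data; disable with `standardize = FALSE`), fits a linear soft-margin
#' SVM with the given cost, and fits a Platt sigmoid on the training
#' decision values so that [predictProbability()] returns calibrated
#' probabilities of the high-trait class.
#'
#' @param x numeric matrix (participants x features) with column names.
#' @param labels `high`/`low` per row.
#' @param features character, the feature subset to use (default: all
#'   columns).
#' @param cost soft-margin cost parameter (> 0).
#' @param standardize z-score the features before fitting (default TRUE).
#' @return A [ScreeningModel-class].
#' @export
fitScreeningModel <- function(x, labels, features = colnames(x),
                              cost = 0.001, standardize = TRUE) {
  y <- .as_group_factor(labels)
  if (nlevels(droplevels(y)) < 2)
    stop("calibration impossible: training data has a single class")
  x <- as.matrix(x)[, features, drop = FALSE]
  std <- if (standardize) .standardizer(x) else
    list(center = rep(0, ncol(x)), scale = rep(1, ncol(x)))
  z <- .apply_std(x, std)
  fit <- .fit_linear_svm(z, y, cost)
  f <- drop(z %*% fit$w) + fit$b
  platt <- .platt_fit(f, y == "high")
  methods::new("ScreeningModel",
    features = features, cost = cost,
    weights = stats::setNames(fit$w, features), bias = fit$b,
    center = std$center, scale = std$scale,
    plattA = platt$A, plattB = platt$B,
    levels = c("high", "low"))
}

#' Decision-function values of a ScreeningModel
#'
#' @param model a `ScreeningModel`.
#' @param x numeric matrix or data.frame containing the model's feature
#'   columns.
#' @return Numeric vector; positive values predict the high-trait class.
#' @export
decisionValues <- function(model, x) {
  x <- as.matrix(as.data.frame(x)[, model@features, drop = FALSE])
  z <- .apply_std(x, list(center = model@center, scale = model@scale))
  drop(z %*% model@weights) + model@bias
}

#' Calibrated probability of the high-trait class
#'
#' Platt sigmoid of the decision value, strictly increasing in it.
#'
#' @inheritParams decisionValues
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predictProbability <- function(model, x) {
  .platt_prob(decisionValues(model, x),
              list(A = model@plattA, B = model@plattB))
}

#' @describeIn ScreeningModel-class predict class labels
#' @param object a `ScreeningModel`
#' @param newdata matrix or data.frame of features
#' @export
setMethod("predict", "ScreeningModel", function(object, newdata) {
  ifelse(decisionValues(object, newdata) > 0, object@levels[1],
         object@levels[2])
})

# fast LOOCV: held-out label (and decision value + Platt probability if
# requested) for each row; deterministic given inputs. `max_errors`
# implements an exact branch-and-bound for the model search: once the
# error count provably exceeds the incumbent's, the remaining folds
# cannot change the outcome of the (correct, tp) comparison, so the
# scan stops and returns NULL. Selection results are identical to a
# full scan.
.loocv_core <- function(x, y, cost, standardize = TRUE,
                        probabilities = FALSE, max_errors = Inf) {
  n <- nrow(x)
  pred <- character(n)
  prob <- rep(NA_real_, n)
  degenerate <- FALSE
  errors <- 0L
  for (i in seq_len(n)) {
    xt <- x[-i, , drop = FALSE]
    yt <- droplevels(y[-i])
    if (nlevels(yt) < 2) {
      degenerate <- TRUE
      pred[i] <- as.character(yt[1])
      next
    }
    std <- if (standardize) .standardizer(xt) else
      list(center = rep(0, ncol(x)), scale = rep(1, ncol(x)))
    zt <- .apply_std(xt, std)
    fit <- .fit_linear_svm(zt, yt, cost)
    zi <- (x[i, ] - std$center) / std$scale
    fi <- sum(zi * fit$w) + fit$b
    pred[i] <- if (fi > 0) "high" else "low"
    if (pred[i] != as.character(y[i])) {
      errors <- errors + 1L
      if (errors > max_errors) return(NULL)
    }
    if (probabilities) {
      ft <- drop(zt %*% fit$w) + fit$b
      prob[i] <- .platt_prob(fi, .platt_fit(ft, yt == "high"))
    }
  }
  if (degenerate)
    warning("degenerate fold(s): training data single-class; predicted the training class")
  list(pred = pred, prob = prob)
}

.confusion_from_pred <- function(pred, y) {
  c(tp = sum(pred == "high" & y == "high"),
    fn = sum(pred == "low" & y == "high"),
    tn = sum(pred == "low" & y == "low"),
    fp = sum(pred == "high" & y == "low"))
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' Positive class is the high-trait group: accuracy =
#' (tp+tn)/(tp+tn+fp+fn), sensitivity = tp/(tp+fn), specificity =
#' tn/(tn+fp). A metric whose denominator class is empty is returned as
#' `NA` with a warning.
#'
#' @param counts named numeric/integer `tp, fn, tn, fp` (order free).
#' @return Named numeric `accuracy, sensitivity, specificity`.
#' @examples
#' confusionMetrics(c(tp = 18, fn = 2, tn = 113, fp = 0))
#' @export
confusionMetrics <- function(counts) {
  stopifnot(all(c("tp", "fn", "tn", "fp") %in% names(counts)))
  k <- counts
  if (sum(k) == 0) stop("empty confusion table")
  sens <- if (k[["tp"]] + k[["fn"]] == 0) {
    warning("sensitivity undefined: no positive-class participants")
    NA_real_
  } else k[["tp"]] / (k[["tp"]] + k[["fn"]])
  spec <- if (k[["tn"]] + k[["fp"]] == 0) {
    warning("specificity undefined: no negative-class participants")
    NA_real_
  } else k[["tn"]] / (k[["tn"]] + k[["fp"]])
  c(accuracy = (k[["tp"]] + k[["tn"]]) / sum(k),
    sensitivity = sens, specificity = spec)
}

.make_cvresult <- function(pred, prob, y, pids) {
  counts <- .confusion_from_pred(pred, y)
  met <- suppressWarnings(confusionMetrics(counts))
  methods::new("CVResult",
    counts = as.integer(counts) |> stats::setNames(names(counts)),
    accuracy = unname(met["accuracy"]),
    sensitivity = unname(met["sensitivity"]),
    specificity = unname(met["specificity"]),
    predictions = data.frame(
      participant_id = pids, label = as.character(y),
      predicted = pred, probability = prob,
      stringsAsFactors = FALSE))
}

#' Leave-one-out cross-validation of a fixed model specification
#'
#' For each participant, standardizes with the other n-1 rows, fits the
#' linear SVM with the given cost on those rows restricted to the
#' selected features, and predicts the held-out participant. Aggregates
#' the held-out predictions into confusion counts and metrics. A fold
#' whose training data is single-class (only possible when a class has
#' one member) predicts the training class and is flagged with a
#' warning.
#'
#' @param x numeric matrix or data.frame (participants x features).
#' @param labels `high`/`low` per row.
#' @param features feature subset (default all columns).
#' @param cost soft-margin cost.
#' @param standardize per-fold z-score standardization (default TRUE).
#' @param probabilities also compute per-fold Platt probabilities
#'   (default TRUE; disable for speed inside searches).
#' @return A [CVResult-class].
#' @export
loocvConfusion <- function(x, labels, features = NULL, cost = 0.001,
                           standardize = TRUE, probabilities = TRUE) {
  x <- as.matrix(as.data.frame(x))
  y <- .as_group_factor(labels)
  if (nrow(x) < 3) stop("need at least 3 participants")
  if (nlevels(droplevels(y)) < 2) stop("both classes must be present")
  if (!is.null(features)) x <- x[, features, drop = FALSE]
  res <- .loocv_core(x, y, cost, standardize, probabilities)
  pids <- if (!is.null(rownames(x))) rownames(x) else
    sprintf("P%03d", seq_len(nrow(x)))
  .make_cvresult(res$pred, res$prob, y, pids)
}

# lexicographic model comparison on integer counts: more correct, then
# more true positives (sensitivity), then fewer features, then lower cost
.better_model <- function(a, b) {
  if (is.null(a)) return(FALSE)
  if (is.null(b)) return(TRUE)
  if (a$correct != b$correct) return(a$correct > b$correct)
  if (a$tp != b$tp) return(a$tp > b$tp)
  if (a$k != b$k) return(a$k < b$k)
  a$cost < b$cost
}

.score_subset <- function(x, y, feats, cost, standardize,
                          max_errors = Inf) {
  res <- .loocv_core(x[, feats, drop = FALSE], y, cost, standardize,
                     probabilities = FALSE, max_errors = max_errors)
  if (is.null(res)) return(NULL)   # pruned: cannot beat the incumbent
  pred <- res$pred
  list(features = feats, cost = cost, k = length(feats),
       correct = sum(pred == as.character(y)),
       tp = sum(pred == "high" & y == "high"))
}

#' Joint feature-subset and cost selection for the screening SVM
#'
#' Searches feature subsets and the soft-margin cost grid for the model
#' maximizing leave-one-out accuracy, tie-broken by higher sensitivity,
#' then fewer features, then lower cost. The default search is greedy
#' sequential floating forward selection (add the best feature while it
#' improves the criterion, then drop any feature whose removal improves
#' it); `search = "exhaustive"` scores every non-empty subset and serves
#' as an oracle upper bound for small candidate sets.
#'
#' @param x numeric matrix or data.frame (participants x features).
#' @param labels `high`/`low` per row.
#' @param candidates candidate feature names (default: all columns).
#' @param cost_grid costs to search (default `10^(-3:1)`).
#' @param search `"greedy"` or `"exhaustive"`.
#' @param max_features cap on subset size for the greedy search
#'   (default 8).
#' @param standardize per-fold z-score standardization.
#' @return List with `features`, `cost`, `cv` (a [CVResult-class] for
#'   the selected model, with probabilities), and `search` used.
#' @export
selectModel <- function(x, labels, candidates = NULL,
                        cost_grid = 10^(-3:1),
                        search = c("greedy", "exhaustive"),
                        max_features = 8L, standardize = TRUE) {
  search <- match.arg(search)
  x <- as.matrix(as.data.frame(x))
  y <- .as_group_factor(labels)
  if (is.null(candidates)) candidates <- colnames(x)
  if (length(candidates) < 1) stop("need at least 1 candidate feature")
  cost_grid <- sort(cost_grid)

  n <- nrow(x)
  best <- NULL
  # prune a candidate once it provably scores fewer correct than the
  # incumbent (ties are never pruned: tie-breaks still apply)
  budget <- function(...) {
    inc <- max(c(-1, vapply(Filter(Negate(is.null), list(...)),
                            `[[`, numeric(1), "correct")))
    if (inc < 0) Inf else n - inc
  }
  if (search == "exhaustive") {
    if (length(candidates) > 20)
      stop("exhaustive search is limited to <= 20 candidates")
    for (size in seq_along(candidates)) {
      combs <- utils::combn(candidates, size, simplify = FALSE)
      for (feats in combs) for (cost in cost_grid) {
        sc <- .score_subset(x, y, feats, cost, standardize, budget(best))
        if (.better_model(sc, best)) best <- sc
      }
    }
  } else {
    S <- character(0)
    repeat {
      if (length(S) >= max_features) break
      step_best <- NULL
      for (f in setdiff(candidates, S)) for (cost in cost_grid) {
        sc <- .score_subset(x, y, c(S, f), cost, standardize,
                            budget(step_best, best))
        if (.better_model(sc, step_best)) step_best <- sc
      }
      if (is.null(step_best) || !.better_model(step_best, best)) break
      best <- step_best
      S <- step_best$features
      # floating backward passes: drop features whose removal improves
      while (length(S) > 1) {
        drop_best <- NULL
        for (g in S) for (cost in cost_grid) {
          sc <- .score_subset(x, y, setdiff(S, g), cost, standardize,
                              budget(drop_best, best))
          if (.better_model(sc, drop_best)) drop_best <- sc
        }
        if (!is.null(drop_best) && .better_model(drop_best, best)) {
          best <- drop_best
          S <- drop_best$features
        } else break
      }
    }
    if (is.null(best)) {   # no addition ever improved; take best single
      for (f in candidates) for (cost in cost_grid) {
        sc <- .score_subset(x, y, f, cost, standardize, budget(best))
        if (.better_model(sc, best)) best <- sc
      }
    }
  }
  cv <- loocvConfusion(x, y, features = best$features, cost = best$cost,
                       standardize = standardize, probabilities = TRUE)
  list(features = best$features, cost = best$cost, cv = cv,
       search = search, standardize = standardize)
}

#' Nested leave-one-out accuracy of the full selection pipeline
#'
#' Repeats the whole model search inside an outer leave-one-out loop:
#' for each participant, [selectModel()] runs on the remaining n-1, the
#' selected model is fitted on those n-1, and the held-out participant
#' is predicted. The resulting accuracy is free of selection optimism,
#' unlike the (selection-optimized) accuracy reported by
#' [selectModel()]; the difference between the two is the optimism gap.
#'
#' @inheritParams selectModel
#' @return List with `accuracy`, `counts`, `majority_rate` and the
#'   per-fold selected subset sizes.
#' @export
nestedLoocvAccuracy <- function(x, labels, candidates = NULL,
                                cost_grid = 10^(-3:1),
                                search = "greedy", max_features = 8L,
                                standardize = TRUE) {
  x <- as.matrix(as.data.frame(x))
  y <- .as_group_factor(labels)
  n <- nrow(x)
  pred <- character(n)
  sizes <- integer(n)
  for (i in seq_len(n)) {
    sel <- selectModel(x[-i, , drop = FALSE], y[-i],
                       candidates = candidates, cost_grid = cost_grid,
                       search = search, max_features = max_features,
                       standardize = standardize)
    model <- fitScreeningModel(x[-i, , drop = FALSE], y[-i],
                               features = sel$features, cost = sel$cost,
                               standardize = standardize)
    pred[i] <- predict(model, x[i, , drop = FALSE])
    sizes[i] <- length(sel$features)
  }
  counts <- .confusion_from_pred(pred, y)
  list(accuracy = (counts[["tp"]] + counts[["tn"]]) / n,
       counts = counts,
       majority_rate = max(table(y)) / n,
       subset_sizes = sizes)
}
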