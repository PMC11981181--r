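# Exact Shapley-value attributions for fitted linear screening models.

#' Exact Shapley attributions of a linear model
#'
#' For a linear decision function f(x) = w . x + b with an
#' interventional (background-mean) expectation, the Shapley value of
#' feature j for row i has the closed form
#' `phi_ij = w_j (x_ij - mean_j(background))`, and local accuracy
#' `base + sum_j phi_ij = f(x_i)` holds exactly with
#' `base = w . mean(background) + b`.
#'
#' @param weights named numeric, linear weights.
#' @param background numeric matrix of background rows (same columns as
#'   `weights`); non-empty.
#' @param x numeric matrix of rows to explain.
#' @param bias intercept of the decision function (default 0).
#' @return A [ShapMatrix-class].
#' @export
linearShap <- function(weights, background, x, bias = 0) {
  background <- as.matrix(background)
  x <- as.matrix(x)
  if (nrow(background) == 0) stop("background must be non-empty")
  if (ncol(background) != length(weights) || ncol(x) != length(weights))
    stop("feature-dimension mismatch between weights, background and x")
  mu <- colMeans(background)
  phi <- sweep(x, 2, mu, "-")
  phi <- sweep(phi, 2, as.numeric(weights), "*")
  colnames(phi) <- names(weights)
  methods::new("ShapMatrix", values = phi,
               baseValue = sum(as.numeric(weights) * mu) + bias)
}

#' Shapley attributions of a fitted ScreeningModel
#'
#' Standardizes the feature matrix with the model's training
#' center/scale and applies [linearShap()] on the decision function
#' (not the calibrated probability, so attributions are exact). The
#' background defaults to the cohort being explained.
#'
#' @param model a [ScreeningModel-class].
#' @param x matrix or data.frame containing the model's features.
#' @param background background rows (default `x`).
#' @return A [ShapMatrix-class].
#' @export
shapExplain <- function(model, x, background = x) {
  pick <- function(d) as.matrix(as.data.frame(d)[, model@features,
                                                 drop = FALSE])
  std <- list(center = model@center, scale = model@scale)
  linearShap(model@weights, .apply_std(pick(background), std),
             .apply_std(pick(x), std), bias = model@bias)
}

#' Rank features by mean absolute Shapley contribution
#'
#' @param shap a [ShapMatrix-class].
#' @return data.frame with `feature` and `mean_abs_contribution`,
#'   descending; ties broken alphabetically.
#' @export
featureImpactRanking <- function(shap) {
  v <- shapValues(shap)
  if (!ncol(v)) stop("empty attribution matrix")
  imp <- colMeans(abs(v))
  ord <- order(-imp, colnames(v))
  data.frame(feature = colnames(v)[ord],
             mean_abs_contribution = unname(imp[ord]),
             stringsAsFactors = FALSE)
}
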