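# PLS1 regression by NIPALS, with VIP attribute importance and leave-one-out
# validation. Written out explicitly (rather than wrapping a library) because
# the per-component weights, scores and explained-y sums of squares are what
# the VIP attribute-importance analysis consumes.

#' Fit a univariate partial least squares (PLS1) model by NIPALS
#'
#' Regresses a single response (here: storage day) on a matrix of sensory
#' attribute scores. The standard PLS1/NIPALS recursion is used: for each
#' component `a`,
#' `w_a = X'y / ||X'y||`, `t_a = X w_a`, `p_a = X' t_a / (t_a' t_a)`,
#' `q_a = y' t_a / (t_a' t_a)`, then `X` and `y` are deflated by the rank-one
#' terms `t_a p_a'` and `t_a q_a`. `X` is mean-centred and, by default,
#' autoscaled to unit variance (usual chemometrics practice for sensory
#' attributes with mixed ranges); `y` is centred.
#'
#' If the deflated `X'y` vanishes before `ncomp` components are extracted
#' (e.g. a noiseless rank-one relationship), the model stops early with a
#' warning and keeps the components found.
#'
#' @param X numeric matrix (n observations x p attributes), or data.frame.
#' @param y numeric response vector of length n.
#' @param ncomp number of latent components, `1 <= ncomp <= min(n-1, p)`.
#' @param scale logical; autoscale columns of `X` to unit variance.
#' @return An object of class `pls1_fit` with components `weights` (p x A,
#'   unit-norm columns), `scores` (n x A), `x_loadings` (p x A), `y_loadings`
#'   (length A), `x_mean`, `x_scale`, `y_mean`, `explained_y_ss` (per
#'   component), `fitted`, `ncomp`, and the column names.
#' @export
fit_pls1 <- function(X, y, ncomp, scale = TRUE) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (n < 2 || p < 1) stop("need n >= 2 and p >= 1")
  if (ncomp < 1 || ncomp > min(n - 1, p))
    stop("ncomp must lie in 1..min(n-1, p) = 1..", min(n - 1, p))

  x_mean <- colMeans(X)
  x_scale <- if (scale) apply(X, 2, stats::sd) else rep(1, p)
  if (any(x_scale == 0)) {
    # constant columns carry no information; leave them centred, unscaled
    x_scale[x_scale == 0] <- 1
  }
  Xc <- sweep(sweep(X, 2, x_mean), 2, x_scale, "/")
  y_mean <- mean(y)
  yc <- y - y_mean

  W <- matrix(0, p, ncomp); Tt <- matrix(0, n, ncomp)
  P <- matrix(0, p, ncomp); q <- numeric(ncomp)
  ssy <- numeric(ncomp)
  A <- 0
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(Xc, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      warning("X exhausted after ", A, " component(s); requested ", ncomp)
      break
    }
    w <- w / nw
    t_a <- drop(Xc %*% w)
    tt <- sum(t_a^2)
    if (tt < 1e-12) {
      warning("degenerate score vector after ", A, " component(s)")
      break
    }
    p_a <- drop(crossprod(Xc, t_a)) / tt
    q_a <- sum(yc * t_a) / tt
    Xc <- Xc - tcrossprod(t_a, p_a)
    yc <- yc - t_a * q_a
    A <- a
    W[, a] <- w; Tt[, a] <- t_a; P[, a] <- p_a; q[a] <- q_a
    ssy[a] <- q_a^2 * tt
  }
  if (A == 0) stop("no PLS component could be extracted (X'y is zero)")
  keep <- seq_len(A)
  fitted <- y_mean + drop(Tt[, keep, drop = FALSE] %*% q[keep])
  structure(list(weights = W[, keep, drop = FALSE],
                 scores = Tt[, keep, drop = FALSE],
                 x_loadings = P[, keep, drop = FALSE],
                 y_loadings = q[keep],
                 x_mean = x_mean, x_scale = x_scale, y_mean = y_mean,
                 explained_y_ss = ssy[keep],
                 fitted = fitted,
                 ncomp = A,
                 scaled = scale,
                 var_names = colnames(X)),
            class = "pls1_fit")
}

#' @export
print.pls1_fit <- function(x, ...) {
  cat("PLS1 (NIPALS) fit:", x$ncomp, "component(s),",
      length(x$x_mean), "predictors\n")
  cat("  explained y-SS per component:",
      paste(signif(x$explained_y_ss, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Predict from a PLS1 model
#'
#' New scores are computed sequentially from the stored weights with the same
#' deflation as at fit time; the prediction is
#' `y_mean + sum_a t_new,a * q_a`. An `ncomp` smaller than the fitted number
#' of components truncates the expansion (used by cross-validation).
#'
#' @param object a [fit_pls1()] model.
#' @param newdata matrix or data.frame with the same columns as the training
#'   `X`.
#' @param ncomp number of components to use (default: all fitted).
#' @param ... unused.
#' @return numeric vector of predicted responses.
#' @export
predict.pls1_fit <- function(object, newdata, ncomp = object$ncomp, ...) {
  Xn <- as.matrix(newdata)
  storage.mode(Xn) <- "double"
  if (ncol(Xn) != length(object$x_mean))
    stop("newdata has ", ncol(Xn), " columns; model expects ",
         length(object$x_mean))
  if (ncomp < 1 || ncomp > object$ncomp)
    stop("ncomp out of fitted range 1..", object$ncomp)
  Xc <- sweep(sweep(Xn, 2, object$x_mean), 2, object$x_scale, "/")
  yhat <- rep(object$y_mean, nrow(Xn))
  for (a in seq_len(ncomp)) {
    t_a <- drop(Xc %*% object$weights[, a])
    yhat <- yhat + t_a * object$y_loadings[a]
    Xc <- Xc - tcrossprod(t_a, object$x_loadings[, a])
  }
  yhat
}

#' Variable importance in projection (VIP)
#'
#' For predictor `j`,
#' `VIP_j = sqrt( p * sum_a SSY_a w_ja^2 / sum_a SSY_a )`
#' where `SSY_a = q_a^2 (t_a' t_a)` is the response sum of squares explained
#' by component `a` and the weight columns have unit norm. The scores satisfy
#' `sum_j VIP_j^2 = p`, so attributes with VIP above 1 contribute more than
#' an average attribute; 1.0 is the customary selection threshold.
#'
#' @param model a [fit_pls1()] model.
#' @param threshold selection threshold (default 1.0).
#' @return An object of class `vip_scores`: list with `vip` (named numeric),
#'   `threshold`, and `selected` (names with VIP above the threshold).
#' @export
vip_scores <- function(model, threshold = 1.0) {
  p <- nrow(model$weights)
  ssy <- model$explained_y_ss
  num <- drop(model$weights^2 %*% ssy)
  vip <- sqrt(p * num / sum(ssy))
  names(vip) <- if (!is.null(model$var_names)) model$var_names
                else paste0("x", seq_len(p))
  structure(list(vip = vip, threshold = threshold,
                 selected = names(vip)[vip > threshold]),
            class = "vip_scores")
}

#' @export
print.vip_scores <- function(x, ...) {
  cat("VIP scores (threshold", x$threshold, ")\n")
  v <- sort(x$vip, decreasing = TRUE)
  for (nm in names(v))
    cat(sprintf("  %-20s %6.3f%s\n", nm, v[nm],
                if (v[nm] > x$threshold) "  *" else ""))
  invisible(x)
}

#' Leave-one-out cross-validation for PLS1 component choice
#'
#' Computes the root-mean-square error of cross-validation for each number of
#' components up to `ncomp_max`; `chosen_ncomp` is the minimiser.
#'
#' @param X predictor matrix.
#' @param y response vector.
#' @param ncomp_max largest component count to try (capped at what each
#'   training fold can support).
#' @param scale autoscale flag passed to [fit_pls1()].
#' @return list with `rmsecv` (numeric vector indexed by component count) and
#'   `chosen_ncomp`.
#' @export
loo_cv_pls <- function(X, y, ncomp_max, scale = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3) stop("leave-one-out needs n >= 3")
  amax <- min(ncomp_max, n - 2, ncol(X))
  if (amax < 1) stop("ncomp_max out of range")
  press <- matrix(NA_real_, n, amax)
  for (i in seq_len(n)) {
    fit <- fit_pls1(X[-i, , drop = FALSE], y[-i], ncomp = amax, scale = scale)
    for (a in seq_len(fit$ncomp)) {
      pred <- predict(fit, X[i, , drop = FALSE], ncomp = a)
      press[i, a] <- (pred - y[i])^2
    }
    if (fit$ncomp < amax)  # early-stopped fold: higher counts behave like max
      press[i, seq(fit$ncomp + 1, amax)] <- press[i, fit$ncomp]
  }
  rmsecv <- sqrt(colMeans(press))
  list(rmsecv = rmsecv, chosen_ncomp = which.min(rmsecv))
}
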