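#' Pareto scaling
#'
#' Centers each column and divides by the square root of its sample
#' standard deviation (n-1 denominator) — the usual metabolomics compromise
#' between unit-variance scaling and no scaling: the variance of a scaled
#' column equals the original SD. Constant columns are dropped with a
#' warning.
#'
#' @param X samples x variables matrix.
#' @return an object of class `scaled_matrix` with `values`, `center`,
#'   `scale_sd`, `dropped` and `scaling = "pareto"`.
#' @export
pareto_scale <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 samples")
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  mu <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  dropped <- colnames(X)[sds == 0]
  if (length(dropped) == ncol(X)) stop("all columns are constant")
  if (length(dropped) > 0) {
    warning("dropping constant column(s): ",
            paste(dropped, collapse = ", "))
    keep <- sds > 0
    X <- X[, keep, drop = FALSE]; mu <- mu[keep]; sds <- sds[keep]
  }
  vals <- sweep(sweep(X, 2, mu), 2, sqrt(sds), `/`)
  structure(list(values = vals, center = mu, scale_sd = sds,
                 dropped = dropped, scaling = "pareto"),
            class = "scaled_matrix")
}

as_scaled_values <- function(Xs) {
  if (inherits(Xs, "scaled_matrix")) Xs$values else as.matrix(Xs)
}

# Core single-component NIPALS step on a centered X and centered y:
# w ~ X'y (unit norm), t = Xw, p = X't/t't, q = y't/t't.
pls1_core <- function(Xc, yc) {
  w <- crossprod(Xc, yc)[, 1]
  nw <- sqrt(sum(w^2))
  if (nw == 0) stop("X has no covariance with y (rank-0 problem)")
  w <- w / nw
  t <- as.numeric(Xc %*% w)
  tt <- sum(t^2)
  if (tt == 0) stop("degenerate score vector")
  list(w = w, t = t, p = crossprod(Xc, t)[, 1] / tt,
       q = sum(yc * t) / tt)
}

#' Fit a single-component PLS model (NIPALS)
#'
#' One-latent-variable PLS1: the weight vector is the normalized covariance
#' `X'y`, the score `t1 = Xw` summarizes the predictor space, and
#' `R2X`/`R2Y` are the fractions of (scaled) X and y variance captured.
#' Only one component is supported: the models this pipeline mirrors all
#' carried a single latent variable.
#'
#' @param Xs a [pareto_scale()] result (or an already-centered matrix).
#' @param y response vector (liver weight or technological yield); centered
#'   internally.
#' @param n_components must be 1.
#' @return an object of class `pls_model` with weights, loadings, scores,
#'   `r2x`, `r2y`, fitted values and VIP scores.
#' @export
fit_pls <- function(Xs, y, n_components = 1) {
  if (n_components != 1)
    stop("only single-component PLS models are supported")
  X <- as_scaled_values(Xs)
  if (anyNA(X) || anyNA(y)) stop("missing values are not supported")
  stopifnot(nrow(X) == length(y))
  y_mean <- mean(y)
  yc <- y - y_mean
  core <- pls1_core(X, yc)
  fitted <- y_mean + core$t * core$q
  ss_x <- sum(X^2)
  r2x <- sum(core$t^2) * sum(core$p^2) / ss_x
  ss_y <- sum(yc^2)
  r2y <- 1 - sum((y - fitted)^2) / ss_y
  model <- structure(list(
    n_components = 1L,
    weights = core$w, loadings = core$p, y_loading = core$q,
    scores = core$t, y_mean = y_mean,
    r2x = r2x, r2y = r2y,
    fitted = fitted, residuals = y - fitted,
    n = nrow(X), p_vars = ncol(X),
    variable_names = colnames(X)), class = "pls_model")
  model$vip <- vip_scores(model)
  model
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf(
    "PLS model (1 component): n = %d, p = %d, R2X = %.3f, R2Y = %.3f\n",
    x$n, x$p_vars, x$r2x, x$r2y))
  if (!is.null(x$q2)) cat(sprintf("  Q2 = %.3f (7-fold)\n", x$q2))
  invisible(x)
}

#' Variable importance in projection
#'
#' For a single-component model the standard multi-component VIP formula
#' collapses to `VIP_k = sqrt(p_vars * w_k^2)` (the lone component carries
#' all explained y-variance and `||w|| = 1`), so the mean squared VIP is 1
#' and variables with VIP > 1 are more important than average.
#'
#' @param model a [fit_pls()] model.
#' @return named non-negative numeric vector of VIP scores.
#' @export
vip_scores <- function(model) {
  w <- model$weights
  nw <- sum(w^2)
  if (nw == 0) stop("zero-norm weight vector")
  v <- sqrt(model$p_vars * w^2 / nw)
  names(v) <- model$variable_names
  v
}

#' Cross-validated predictive ability (Q2) and RMSECv
#'
#' Shuffles the samples (seeded), splits them into `k` contiguous folds and
#' leaves each fold out in turn; a single-component PLS model is refit on
#' the remaining samples (re-centered within the training set) and the
#' held-out responses predicted. `Q2 = 1 - PRESS / sum((y - mean(y))^2)`
#' and `RMSECv = sqrt(PRESS / n)`.
#'
#' @param Xs a [pareto_scale()] result (or centered matrix).
#' @param y response vector.
#' @param k number of folds.
#' @param seed integer seed for the fold shuffle.
#' @return list with `q2`, `rmsecv` and the fold assignment.
#' @export
q2_cross_validate <- function(Xs, y, k = 7, seed = 1L) {
  X <- as_scaled_values(Xs)
  n <- nrow(X)
  stopifnot(n >= k)
  if (floor(n / k) < 2) stop("a fold would hold fewer than 2 samples")
  folds <- with_seed(seed, {
    idx <- sample.int(n)
    split(idx, cut(seq_len(n), k, labels = FALSE))
  })
  press <- 0
  for (fold in folds) {
    tr <- setdiff(seq_len(n), fold)
    Xtr <- X[tr, , drop = FALSE]
    mu <- colMeans(Xtr)
    Xtr <- sweep(Xtr, 2, mu)
    ybar <- mean(y[tr])
    core <- pls1_core(Xtr, y[tr] - ybar)
    Xte <- sweep(X[fold, , drop = FALSE], 2, mu)
    pred <- ybar + as.numeric(Xte %*% core$w) * core$q
    press <- press + sum((y[fold] - pred)^2)
  }
  assignment <- integer(n)
  for (i in seq_along(folds)) assignment[folds[[i]]] <- i
  list(q2 = 1 - press / sum((y - mean(y))^2),
       rmsecv = sqrt(press / n),
       folds = assignment)
}

#' Root mean square error of estimation
#'
#' Fit error of the model on its own training data with the chemometric
#' convention `RMSEE = sqrt(RSS / (n - 1 - a))`, `a = 1` component.
#'
#' @param model a [fit_pls()] model.
#' @param Xs,y the data the model was fit on (kept in the signature for
#'   symmetry with [q2_cross_validate()]; residuals are stored in the
#'   model).
#' @return the RMSEE, in response units.
#' @export
rmsee <- function(model, Xs = NULL, y = NULL) {
  n <- model$n
  if (n <= 2) stop("need more than 2 samples")
  sqrt(sum(model$residuals^2) / (n - 1 - model$n_components))
}

#' Permutation validation of a PLS model
#'
#' Refits the model `n_permutations` times with the response order randomly
#' permuted while X is kept intact, recording each permuted model's R2Y and
#' 7-fold Q2 against the absolute correlation between the permuted and
#' original response. Least-squares lines of Q2 (and R2Y) on |correlation|,
#' including the original model at correlation 1, give the intercepts. The
#' model is *valid* when every permuted Q2 lies below the original Q2 and
#' the Q2 regression line intersects the vertical axis at or below zero.
#'
#' @param Xs a [pareto_scale()] result (or centered matrix).
#' @param y response vector.
#' @param n_permutations number of permutations (>= 1).
#' @param seed integer seed (drives both the permutations and the CV fold
#'   shuffles).
#' @param k folds for the embedded cross-validation.
#' @return an object of class `permutation_report`.
#' @export
permutation_validate <- function(Xs, y, n_permutations = 500, seed = 1L,
                                 k = 7) {
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  X <- as_scaled_values(Xs)
  orig_fit <- fit_pls(X, y)
  orig_cv <- q2_cross_validate(X, y, k = k, seed = seed)
  perms <- with_seed(seed, {
    lapply(seq_len(n_permutations), function(b) sample(y))
  })
  rec <- vapply(seq_len(n_permutations), function(b) {
    yp <- perms[[b]]
    fit <- fit_pls(X, yp)
    cv <- q2_cross_validate(X, yp, k = k, seed = seed + b)
    c(abs_cor = abs(stats::cor(yp, y)), r2y = fit$r2y, q2 = cv$q2)
  }, numeric(3))
  permuted <- as.data.frame(t(rec))
  xall <- c(permuted$abs_cor, 1)
  q2_line <- stats::lm.fit(cbind(1, xall), c(permuted$q2, orig_cv$q2))
  r2_line <- stats::lm.fit(cbind(1, xall), c(permuted$r2y, orig_fit$r2y))
  q2_intercept <- unname(q2_line$coefficients[1])
  structure(list(
    n_permutations = n_permutations,
    permuted = permuted,
    original = c(abs_cor = 1, r2y = orig_fit$r2y, q2 = orig_cv$q2),
    q2_intercept = q2_intercept,
    r2_intercept = unname(r2_line$coefficients[1]),
    valid = all(permuted$q2 < orig_cv$q2) && q2_intercept <= 0),
    class = "permutation_report")
}

#' @export
print.permutation_report <- function(x, ...) {
  cat(sprintf(
    "Permutation validation (%d permutations): original Q2 = %.3f\n",
    x$n_permutations, x$original["q2"]))
  cat(sprintf("  max permuted Q2 = %.3f, Q2 intercept = %.3f -> %s\n",
              max(x$permuted$q2), x$q2_intercept,
              if (x$valid) "VALID" else "NOT valid"))
  invisible(x)
}
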