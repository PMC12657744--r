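#' Fit configuration for node-wise penalized logistic regression
#'
#' @param lambda_mode `"cv_min"` (per-outcome 10-fold cross-validation at
#'   the deviance minimum, the default), `"cv_1se"` (largest penalty within
#'   one standard error of the CV minimum; markedly sparser networks at the
#'   cost of shrinking weaker true edges to zero), or `"fixed"`.
#' @param lambda_value penalty used when `lambda_mode = "fixed"` (>= 0).
#' @param n_folds number of CV folds (>= 2).
#' @param penalize_autoregressive penalize the self-path like any other
#'   coefficient (default TRUE).
#' @param standardize_predictors scale predictors to unit SD before fitting
#'   and back-transform coefficients (default FALSE: binary 0/1 items share
#'   a scale already and standardizing dummies distorts the odds-ratio
#'   interpretation).
#' @param direction_convention `"recode_reverse_first"` (recode
#'   reverse-keyed items toward the construct before fitting, the default)
#'   or `"raw"` (fit items as stored, so positively worded items yield
#'   negative associations with symptom items).
#' @param seed RNG seed for fold assignment.
#' @param tol solver convergence tolerance.
#' @param maxit maximum proximal-Newton iterations.
#' @return A list of class `clpn_fit_config`.
#' @export
fit_config <- function(lambda_mode = c("cv_min", "cv_1se", "fixed"),
                       lambda_value = NULL, n_folds = 10L,
                       penalize_autoregressive = TRUE,
                       standardize_predictors = FALSE,
                       direction_convention = c("recode_reverse_first",
                                                "raw"),
                       seed = NULL, tol = 1e-7, maxit = 100L) {
  lambda_mode <- match.arg(lambda_mode)
  direction_convention <- match.arg(direction_convention)
  if (lambda_mode == "fixed") {
    if (is.null(lambda_value) || lambda_value < 0)
      stop("fixed lambda_mode needs lambda_value >= 0")
  }
  if (n_folds < 2L) stop("n_folds must be >= 2")
  structure(list(lambda_mode = lambda_mode, lambda_value = lambda_value,
                 n_folds = as.integer(n_folds),
                 penalize_autoregressive = penalize_autoregressive,
                 standardize_predictors = standardize_predictors,
                 direction_convention = direction_convention,
                 seed = seed, tol = tol, maxit = as.integer(maxit)),
            class = "clpn_fit_config")
}

# Smallest penalty that zeroes every penalized coefficient when no
# unpenalized covariates (beyond the intercept) are present:
# max_j |<x_j, y - ybar>| / n over penalized columns.
lambda_max_value <- function(X, y, pen = rep(1, ncol(X))) {
  r <- y - mean(y)
  g <- abs(crossprod(X, r)) / length(y)
  max(g[pen > 0])
}

#' L1-penalized logistic regression
#'
#' Minimizes the mean negative Bernoulli log-likelihood plus
#' `lambda * sum(penalty_j * |beta_j|)` (intercept unpenalized) by
#' proximal-Newton coordinate descent. Deterministic for fixed inputs.
#'
#' @param X complete numeric predictor matrix (columns on a common scale;
#'   binary 0/1 in the intended use).
#' @param y complete binary outcome with both classes present.
#' @param lambda penalty >= 0.
#' @param config a [fit_config()]; `tol`, `maxit`,
#'   `standardize_predictors` are honored here.
#' @param penalty optional per-coefficient penalty multipliers (0 exempts a
#'   coefficient).
#' @return List with `intercept`, `coefficients` (named), `lambda`,
#'   `iterations`, `converged`.
#' @export
penalized_logistic <- function(X, y, lambda, config = fit_config(),
                               penalty = rep(1, ncol(X))) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (anyNA(X) || anyNA(y)) stop("X and y must be complete")
  if (length(unique(y)) < 2L) stop("outcome is constant")
  if (lambda < 0) stop("lambda must be >= 0")
  if (lambda == 0) {
    # exact collinearity has no unique unpenalized optimum: fail honestly
    if (qr(cbind(1, X))$rank < ncol(X) + 1L)
      stop("predictors are exactly collinear at lambda = 0")
  }
  scales <- rep(1, ncol(X))
  if (isTRUE(config$standardize_predictors)) {
    scales <- apply(X, 2L, stats::sd)
    scales[scales == 0] <- 1
    X <- sweep(X, 2L, scales, "/")
  }
  # full-shrinkage closed form: intercept-only model is exactly logit(ybar)
  if (lambda > 0 && all(penalty > 0) &&
      lambda >= lambda_max_value(X, y, penalty)) {
    co <- stats::setNames(rep(0, ncol(X)), colnames(X))
    return(list(intercept = qlogis(mean(y)), coefficients = co,
                lambda = lambda, iterations = 0L, converged = TRUE))
  }
  fit <- cd_logistic_cpp(X, y, lambda, as.numeric(penalty),
                         config$tol, config$maxit,
                         qlogis(mean(y)), rep(0, ncol(X)))
  if (!fit$converged)
    stop("solver did not converge after ", fit$iterations, " iterations")
  co <- stats::setNames(fit$beta / scales, colnames(X))
  list(intercept = fit$intercept, coefficients = co, lambda = lambda,
       iterations = fit$iterations, converged = TRUE)
}

# Stratified fold assignment preserving both outcome classes in every
# training set; errors when a class is too small to stratify.
make_folds <- function(y, n_folds, seed) {
  if (min(table(y)) < 2L)
    stop("cannot stratify folds: a class has fewer than 2 observations")
  with_seed(seed, {
    foldid <- integer(length(y))
    for (cls in unique(y)) {
      idx <- which(y == cls)
      foldid[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
    foldid
  })
}

#' Select the LASSO penalty by K-fold cross-validation
#'
#' Builds a 100-point log-spaced path from `lambda_max` (the smallest
#' penalty at which every penalized coefficient is zero) down to
#' `lambda_max * 1e-3`, computes mean out-of-fold binomial deviance per
#' fold, and returns the path value minimizing the fold-averaged deviance.
#' Ties are broken toward the larger (sparser) penalty. Folds are
#' stratified by outcome class and seeded via `config$seed`.
#'
#' @inheritParams penalized_logistic
#' @param config a [fit_config()].
#' @return Selected penalty (numeric scalar) with attributes `path`
#'   (lambda sequence) and `cvm` (fold-mean deviance per path point).
#' @export
select_lambda <- function(X, y, config = fit_config(),
                          penalty = rep(1, ncol(X))) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (length(unique(y)) < 2L) stop("outcome is constant")
  if (nrow(X) < config$n_folds) stop("need n >= n_folds")
  lmax <- lambda_max_value(X, y, penalty)
  path <- exp(seq(log(lmax), log(lmax * 1e-3), length.out = 100L))
  foldid <- make_folds(y, config$n_folds, config$seed)
  dev <- cv_deviance_cpp(X, y, as.integer(foldid), config$n_folds,
                         path, as.numeric(penalty), config$tol,
                         config$maxit)
  cvm <- rowMeans(dev)
  i_min <- which.min(cvm)  # path is decreasing: first minimum = largest lambda
  best <- if (identical(config$lambda_mode, "cv_1se")) {
    cvsd <- apply(dev, 1L, sd) / sqrt(config$n_folds)
    which(cvm <= cvm[i_min] + cvsd[i_min])[1L]
  } else i_min
  structure(path[best], path = path, cvm = cvm)
}

new_clpn_network <- function(items, B, intercepts, lambda_used, n_fit,
                             wave_pair) {
  structure(list(items = items, B = B, intercepts = intercepts,
                 lambda_used = lambda_used, n_fit = n_fit,
                 wave_pair = wave_pair),
            class = "clpn_network")
}

#' Estimate a cross-lagged panel network for one wave pair
#'
#' For every outcome item `j` at `wave_t1`, regresses it on all items at
#' `wave_t` (including item `j` itself, the autoregressive path) by
#' L1-penalized logistic regression, with a per-outcome penalty chosen by
#' cross-validation (or fixed). The result collects the coefficient matrix
#' `B` (rows = predictor, columns = outcome; diagonal = autoregressive),
#' per-outcome intercepts and selected penalties. Coefficients are log
#' odds; see [to_odds_ratios()] for the odds-ratio view in which 1 means
#' "no edge".
#'
#' @param panel a complete [panel_dataset()] (run [chained_impute()] or
#'   [complete_cases()] first).
#' @param wave_t,wave_t1 labels of the predictor and outcome waves.
#' @param config a [fit_config()].
#' @return A `clpn_network`.
#' @export
fit_clpn <- function(panel, wave_t, wave_t1, config = fit_config()) {
  if (config$direction_convention == "recode_reverse_first" &&
      any(panel$codebook$reverse_keyed))
    panel <- recode_reverse(panel)
  Xt <- wave_matrix(panel, wave_t)
  Xt1 <- wave_matrix(panel, wave_t1)
  if (anyNA(Xt) || anyNA(Xt1))
    stop("panel has missing values in waves ", wave_t, "/", wave_t1,
         "; run chained_impute() or complete_cases() first")
  items <- panel$items
  p <- length(items)
  B <- matrix(0, p, p, dimnames = list(items, items))
  intercepts <- stats::setNames(numeric(p), items)
  lambda_used <- stats::setNames(numeric(p), items)
  for (j in seq_len(p)) {
    y <- Xt1[, j]
    if (length(unique(y)) < 2L)
      stop("outcome item '", items[j], "' is constant at wave ", wave_t1)
    pen <- rep(1, p)
    if (!config$penalize_autoregressive) pen[j] <- 0
    lam <- if (config$lambda_mode == "fixed") config$lambda_value else
      tryCatch(as.numeric(select_lambda(Xt, y, config, penalty = pen)),
               error = function(e)
                 stop("lambda selection failed for outcome item '",
                      items[j], "': ", conditionMessage(e)))
    fit <- tryCatch(
      penalized_logistic(Xt, y, lam, config, penalty = pen),
      error = function(e)
        stop("fit failed for outcome item '", items[j], "': ",
             conditionMessage(e)))
    B[, j] <- fit$coefficients
    intercepts[j] <- fit$intercept
    lambda_used[j] <- lam
  }
  new_clpn_network(items, B, intercepts, lambda_used,
                   n_fit = nrow(Xt), wave_pair = c(wave_t, wave_t1))
}

#' Odds-ratio view of a network
#'
#' Elementwise `exp` of the log-odds coefficient matrix; an exact zero maps
#' to an exact 1 (no edge), weights above 1 are positive connections,
#' below 1 negative ones.
#'
#' @param net a `clpn_network`.
#' @return Items x items odds-ratio matrix.
#' @export
to_odds_ratios <- function(net) {
  exp(net$B)
}

#' @export
print.clpn_network <- function(x, ...) {
  nz_cross <- sum(x$B != 0) - sum(diag(x$B) != 0)
  cat(sprintf("clpn_network %s -> %s: %d items, n = %s\n",
              x$wave_pair[1], x$wave_pair[2], length(x$items),
              format(x$n_fit)))
  cat(sprintf("  nonzero: %d cross-lagged, %d autoregressive\n",
              nz_cross, sum(diag(x$B) != 0)))
  invisible(x)
}
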