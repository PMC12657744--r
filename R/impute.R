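#' Configuration for chained-equation single imputation
#'
#' @param n_cycles number of chained-equation cycles (>= 1, default 10).
#' @param aux_vars names of auxiliary covariate columns used as predictors
#'   in every conditional model (default: all aux columns of the panel).
#' @param seed RNG seed.
#' @return A list of class `clpn_impute_config`.
#' @export
impute_config <- function(n_cycles = 10L, aux_vars = NULL, seed = NULL) {
  if (n_cycles < 1L) stop("n_cycles must be >= 1")
  structure(list(n_cycles = as.integer(n_cycles), aux_vars = aux_vars,
                 seed = seed, single_dataset = TRUE),
            class = "clpn_impute_config")
}

#' Chained-equation single imputation for binary panel items
#'
#' Produces one completed dataset. Missing cells are initialized by draws
#' from each item-wave column's observed marginal; then for `n_cycles`
#' cycles each incomplete column is regressed (unpenalized logistic) on all
#' other item-wave columns plus the auxiliary covariates using the current
#' completed data, and its missing cells are re-drawn as Bernoulli(fitted
#' probability). Observed cells are never altered. If a conditional model
#' fails to converge (e.g. separation), that column falls back to a
#' marginal draw with a warning.
#'
#' @param panel a [panel_dataset()] with missing entries.
#' @param config an [impute_config()].
#' @return A complete [panel_dataset()].
#' @export
chained_impute <- function(panel, config = impute_config()) {
  resp <- panel$responses
  n <- dim(resp)[1L]; p <- dim(resp)[2L]; w <- dim(resp)[3L]
  flat <- matrix(resp, nrow = n)   # n x (p*w), wave-major blocks of items
  colnames(flat) <- paste(rep(panel$items, times = w),
                          rep(panel$waves, each = p), sep = "_")
  miss <- is.na(flat)
  if (!any(miss)) return(panel)
  all_missing <- colSums(!miss) == 0
  if (any(all_missing))
    stop("column(s) entirely missing: ",
         paste(colnames(flat)[all_missing], collapse = ", "))
  aux_vars <- config$aux_vars %||% names(panel$aux)
  aux_mat <- NULL
  if (length(aux_vars)) {
    if (is.null(panel$aux) || !all(aux_vars %in% names(panel$aux)))
      stop("aux_vars not present on the panel")
    aux_mat <- stats::model.matrix(
      ~ ., data = panel$aux[, aux_vars, drop = FALSE])[, -1L, drop = FALSE]
  }
  with_seed(config$seed, {
    # initialize from observed marginals
    for (k in which(colSums(miss) > 0)) {
      pk <- mean(flat[!miss[, k], k])
      flat[miss[, k], k] <- rbinom(sum(miss[, k]), 1L, pk)
    }
    incomplete <- which(colSums(miss) > 0)
    for (cycle in seq_len(config$n_cycles)) {
      for (k in incomplete) {
        Xk <- cbind(flat[, -k, drop = FALSE], aux_mat)
        yk <- flat[, k]
        obs <- !miss[, k]
        # separation (e.g. a near-deterministic predictor) leaves finite,
        # perfectly predictive coefficients: usable; only broken fits
        # (errors, non-finite coefficients) fall back to the marginal
        co <- tryCatch({
          g <- suppressWarnings(glm.fit(cbind(1, Xk[obs, , drop = FALSE]),
                                        yk[obs], family = binomial(),
                                        control = list(maxit = 50L)))
          cg <- coef(g)
          cg[is.na(cg)] <- 0   # aliased (collinear) columns drop out
          if (!all(is.finite(cg))) NULL else cg
        }, error = function(e) NULL)
        if (is.null(co)) {
          warning("conditional model for ", colnames(flat)[k],
                  " failed; marginal draw used", call. = FALSE)
          pk <- mean(yk[obs])
          flat[miss[, k], k] <- rbinom(sum(miss[, k]), 1L, pk)
        } else {
          eta <- drop(cbind(1, Xk[miss[, k], , drop = FALSE]) %*% co)
          flat[miss[, k], k] <- rbinom(sum(miss[, k]), 1L, plogis(eta))
        }
      }
    }
    panel$responses[] <- array(flat, dim = c(n, p, w))
    panel
  })
}

#' Restrict a panel to complete cases for given waves
#'
#' Keeps the persons with no missing item response in any of the named
#' waves (the complete-case sensitivity counterpart to imputation).
#'
#' @param panel a [panel_dataset()].
#' @param waves wave labels (default: all waves).
#' @return The filtered [panel_dataset()].
#' @export
complete_cases <- function(panel, waves = panel$waves) {
  bad <- setdiff(waves, panel$waves)
  if (length(bad)) stop("unknown wave(s): ", paste(bad, collapse = ", "))
  sub <- panel$responses[, , waves, drop = FALSE]
  keep <- apply(!is.na(sub), 1L, all)
  if (!any(keep)) stop("no complete cases for waves ",
                       paste(waves, collapse = ", "))
  subset_persons(panel, which(keep))
}
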