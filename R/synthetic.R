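#' Specification of a synthetic binary panel
#'
#' Defines the generative model used for validation: wave 1 is drawn
#' independently per item as Bernoulli(`wave1_prevalence`); each later wave
#' follows the logistic transition law
#' `P(x_j^(t) = 1 | x^(t-1)) = plogis(c_j + sum_i B[i, j] x_i^(t-1))`,
#' i.e. the generative counterpart of the cross-lagged panel network that
#' the estimator targets: `B`'s diagonal holds autoregressive weights, the
#' off-diagonal cross-lagged weights, all on the log-odds scale.
#'
#' @param codebook an [item_codebook()].
#' @param n_waves number of waves (>= 2).
#' @param wave1_prevalence per-item endorsement probability at wave 1, in
#'   (0, 1), in the item coding as stored (reverse-keyed items keep their
#'   raw positive wording).
#' @param true_network items x items matrix of log-odds transition weights
#'   (rows = predictor at wave t, columns = outcome at wave t+1), or a list
#'   of such matrices, one per wave pair, to let the transition law shift
#'   over time.
#' @param intercepts per-item transition intercepts `c_j`; defaults to
#'   [calibrate_intercepts()] so later waves keep roughly the wave-1
#'   prevalences.
#' @param aux_model named list of Bernoulli probabilities for binary 0/1
#'   auxiliary covariates (e.g. `list(female = 0.55, white = 0.9)`).
#' @param missing_model list with `intercept`, `coef` (named, one per aux
#'   covariate) and `sum_coef` (weight on the wave-1 sum score) defining
#'   the logit of whole-interview missingness at waves >= 2; `NULL`
#'   disables missingness.
#' @param seed RNG seed making the panel bit-reproducible.
#' @return An object of class `clpn_spec`.
#' @export
synthetic_spec <- function(codebook, n_waves, wave1_prevalence,
                           true_network, intercepts = NULL,
                           aux_model = NULL, missing_model = NULL,
                           seed = 1L) {
  p <- nrow(codebook)
  if (n_waves < 2L) stop("n_waves must be >= 2")
  if (length(wave1_prevalence) != p)
    stop("wave1_prevalence must have one entry per item")
  if (any(wave1_prevalence <= 0 | wave1_prevalence >= 1))
    stop("prevalences must lie strictly in (0, 1)")
  nets <- if (is.list(true_network)) true_network else
    rep(list(true_network), n_waves - 1L)
  if (length(nets) != n_waves - 1L)
    stop("need one transition matrix per wave pair")
  for (B in nets) {
    if (!all(dim(B) == c(p, p)) || !all(is.finite(B)))
      stop("each transition matrix must be finite items x items")
  }
  nets <- lapply(nets, function(B) {
    dimnames(B) <- list(codebook$item_id, codebook$item_id); B
  })
  if (is.null(intercepts)) {
    intercepts <- lapply(nets, calibrate_intercepts,
                         target_prev = wave1_prevalence,
                         predecessor_prev = wave1_prevalence)
  } else if (!is.list(intercepts)) {
    intercepts <- rep(list(intercepts), n_waves - 1L)
  }
  structure(list(codebook = codebook, n_items = p, n_waves = n_waves,
                 wave1_prevalence = stats::setNames(wave1_prevalence,
                                                    codebook$item_id),
                 true_network = nets, intercepts = intercepts,
                 aux_model = aux_model, missing_model = missing_model,
                 seed = seed),
            class = "clpn_spec")
}

#' Default 8-item validation fixture
#'
#' An 8-item, 4-wave spec shaped after the dichotomous CES-D-8: wave-1
#' prevalences (0.12, 0.20, 0.36, 0.92, 0.12, 0.91, 0.20, 0.20) with the
#' two positively worded items near 0.9, autoregressive weights of 1.2, and
#' a dozen cross-lagged edges (|b| between 0.4 and 0.9) concentrated on the
#' somatic-drive and affect items, so the strongest true paths mirror the
#' effort/could-not-get-going and happy/enjoy reciprocal pairs and the
#' lonely-to-depressed path. Auxiliary covariates are binary sex and
#' ethnicity indicators; the missingness model makes dropout at waves >= 2
#' more likely for non-white persons and for higher wave-1 sum scores.
#'
#' @param n_waves number of waves (default 4).
#' @param seed RNG seed stored in the spec.
#' @param missingness include the MAR missingness model (default TRUE).
#' @return A `clpn_spec`.
#' @export
cesd8_synthetic_spec <- function(n_waves = 4L, seed = 1L,
                                 missingness = TRUE) {
  cb <- cesd8_codebook()
  prev <- c(depressed = 0.12, effort = 0.20, sleep = 0.36, happy = 0.92,
            lonely = 0.12, enjoy = 0.91, sad = 0.20, getgoing = 0.20)
  B <- matrix(0, 8, 8, dimnames = list(cb$item_id, cb$item_id))
  diag(B) <- 1.2
  edges <- rbind(
    c("effort", "getgoing", 0.90),
    c("happy", "enjoy", 0.75),
    c("lonely", "depressed", 0.70),
    c("effort", "depressed", 0.65),
    c("getgoing", "effort", 0.65),
    c("enjoy", "happy", 0.60),
    c("depressed", "sad", 0.60),
    c("depressed", "lonely", 0.45),
    c("getgoing", "depressed", 0.45),
    c("lonely", "sad", 0.45),
    c("sleep", "effort", 0.45),
    c("sad", "depressed", 0.40))
  B[cbind(edges[, 1], edges[, 2])] <- as.numeric(edges[, 3])
  mm <- if (missingness)
    list(intercept = -1.5, coef = c(female = -0.1, white = -0.5),
         sum_coef = 0.15) else NULL
  synthetic_spec(cb, n_waves = n_waves, wave1_prevalence = prev,
                 true_network = B,
                 aux_model = list(female = 0.55, white = 0.9),
                 missing_model = mm, seed = seed)
}

#' Simulate a complete panel from a synthetic spec
#'
#' Draws wave 1 independently per item, then propagates each later wave
#' through the logistic transition law. The returned panel is complete; use
#' [apply_missingness()] to overlay the spec's missingness model. The same
#' spec (including seed) always yields a bit-identical panel.
#'
#' @param spec a [synthetic_spec()].
#' @param n number of persons.
#' @return A complete [panel_dataset()] with aux covariates when the spec
#'   has an `aux_model`.
#' @export
simulate_panel <- function(spec, n) {
  with_seed(spec$seed, {
    p <- spec$n_items; w <- spec$n_waves
    resp <- array(NA_real_, dim = c(n, p, w))
    resp[, , 1L] <- rbinom(n * p, 1L,
                           rep(spec$wave1_prevalence, each = n))
    for (t in 2L:w) {
      B <- spec$true_network[[t - 1L]]
      cvec <- spec$intercepts[[t - 1L]]
      eta <- resp[, , t - 1L] %*% B +
        matrix(cvec, n, p, byrow = TRUE)
      resp[, , t] <- rbinom(n * p, 1L, plogis(as.vector(eta)))
    }
    aux <- NULL
    if (!is.null(spec$aux_model)) {
      aux <- as.data.frame(lapply(spec$aux_model, function(pr)
        rbinom(n, 1L, pr)))
    }
    panel_dataset(resp, spec$codebook, waves = default_wave_labels(w),
                  aux = aux)
  })
}

default_wave_labels <- function(w) {
  # mirrors the 4-wave study layout: two pre-stressor, two stressor waves
  if (w == 4L) c("w8", "w9", "c1", "c2") else paste0("w", seq_len(w))
}

#' Calibrate transition intercepts to target prevalences
#'
#' Finds, for each item `j`, the intercept `c_j` solving
#' `E[plogis(c_j + sum_i B[i, j] X_i)] = target_prev[j]` under independent
#' Bernoulli(`predecessor_prev`) predictors. The expectation is evaluated by
#' exact enumeration over the joint states of the predictors with non-zero
#' weight when there are at most 12 of them, otherwise by seeded Monte
#' Carlo; the root is found by [uniroot()] to a residual below 1e-4.
#'
#' @param B items x items log-odds transition matrix.
#' @param target_prev desired next-wave prevalences, in (0, 1).
#' @param predecessor_prev prevalences of the predictor wave, in (0, 1).
#' @param mc_n Monte Carlo sample size used above 12 active predictors.
#' @return Named vector of intercepts.
#' @export
calibrate_intercepts <- function(B, target_prev, predecessor_prev,
                                 mc_n = 2e5) {
  p <- ncol(B)
  stopifnot(length(target_prev) == p, length(predecessor_prev) == p)
  if (any(c(target_prev, predecessor_prev) <= 0) ||
      any(c(target_prev, predecessor_prev) >= 1))
    stop("probabilities must lie strictly in (0, 1)")
  out <- numeric(p)
  for (j in seq_len(p)) {
    active <- which(B[, j] != 0)
    if (length(active) == 0L) {
      out[j] <- qlogis(target_prev[j])
      next
    }
    if (length(active) <= 12L) {
      states <- as.matrix(expand.grid(rep(list(0:1), length(active))))
      wts <- apply(states, 1L, function(s)
        prod(ifelse(s == 1, predecessor_prev[active],
                    1 - predecessor_prev[active])))
      etas <- drop(states %*% B[active, j])
      f <- function(c) sum(wts * plogis(c + etas)) - target_prev[j]
    } else {
      X <- with_seed(1L, matrix(
        rbinom(mc_n * length(active), 1L,
               rep(predecessor_prev[active], each = mc_n)),
        nrow = mc_n))
      etas <- drop(X %*% B[active, j])
      f <- function(c) mean(plogis(c + etas)) - target_prev[j]
    }
    lo <- -30; hi <- 30
    if (f(lo) > 0 || f(hi) < 0)
      stop("intercept root not bracketed for item ", j)
    out[j] <- uniroot(f, c(lo, hi), tol = 1e-10)$root
    if (abs(f(out[j])) > 1e-4)
      stop("intercept calibration residual too large for item ", j)
  }
  stats::setNames(out, colnames(B))
}

#' Overlay missing-at-random dropout on a complete panel
#'
#' For every person-wave at waves >= 2, the whole interview is set missing
#' with probability `plogis(intercept + coef'aux + sum_coef * sumscore_w1)`.
#' Wave 1 stays complete, and missingness is drawn before any wave >= 2
#' value is looked at, so the mechanism depends only on observed wave-1 data
#' and auxiliary covariates (MAR by construction).
#'
#' @param panel a complete [panel_dataset()] with the aux covariates named
#'   in the model.
#' @param spec a [synthetic_spec()] whose `missing_model` is non-NULL.
#' @param seed RNG seed (default: the spec's seed + 1).
#' @return The panel with missing person-waves.
#' @export
apply_missingness <- function(panel, spec, seed = spec$seed + 1L) {
  mm <- spec$missing_model
  if (is.null(mm)) return(panel)
  if (anyNA(panel$responses)) stop("panel must be complete")
  with_seed(seed, {
    n <- length(panel$persons)
    eta <- rep(mm$intercept, n)
    if (length(mm$coef)) {
      if (is.null(panel$aux) || !all(names(mm$coef) %in% names(panel$aux)))
        stop("aux covariates named in missing_model are absent")
      for (v in names(mm$coef))
        eta <- eta + mm$coef[[v]] * panel$aux[[v]]
    }
    eta <- eta + (mm$sum_coef %||% 0) * sum_scores(panel, panel$waves[1L])
    pr <- plogis(eta)
    for (t in 2L:length(panel$waves)) {
      drop_it <- runif(n) < pr
      panel$responses[drop_it, , t] <- NA_real_
    }
    panel
  })
}

#' Read / write a synthetic spec as YAML
#'
#' @param path YAML file path.
#' @export
write_synthetic_spec <- function(spec, path) {
  obj <- list(
    items = lapply(seq_len(nrow(spec$codebook)), function(i) list(
      item_id = spec$codebook$item_id[i],
      label = spec$codebook$label[i],
      reverse_keyed = spec$codebook$reverse_keyed[i])),
    n_waves = spec$n_waves,
    wave1_prevalence = as.list(spec$wave1_prevalence),
    true_network = lapply(spec$true_network, function(B)
      apply(B, 1L, as.list, simplify = FALSE)),
    intercepts = lapply(spec$intercepts, as.list),
    aux_model = spec$aux_model,
    missing_model = spec$missing_model,
    seed = spec$seed)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_synthetic_spec
#' @param spec a `clpn_spec` (for writing).
#' @export
read_synthetic_spec <- function(path) {
  obj <- yaml::read_yaml(path)
  cb <- item_codebook(vapply(obj$items, `[[`, "", "item_id"),
                      vapply(obj$items, `[[`, "", "label"),
                      vapply(obj$items, `[[`, TRUE, "reverse_keyed"))
  p <- nrow(cb)
  nets <- lapply(obj$true_network, function(rows)
    matrix(unlist(rows), nrow = p, byrow = TRUE,
           dimnames = list(cb$item_id, cb$item_id)))
  mm <- obj$missing_model
  if (!is.null(mm)) mm$coef <- unlist(mm$coef)
  synthetic_spec(cb, n_waves = obj$n_waves,
                 wave1_prevalence = unlist(obj$wave1_prevalence),
                 true_network = nets,
                 intercepts = lapply(obj$intercepts, unlist),
                 aux_model = obj$aux_model, missing_model = mm,
                 seed = obj$seed)
}
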