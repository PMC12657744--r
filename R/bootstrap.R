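#' Bootstrap configuration
#'
#' @param n_boot bootstrap iterations (default 1000).
#' @param ci_level confidence level for percentile intervals (default 0.95).
#' @param drop_proportions case-drop grid (default 0.10 to 0.75 by 0.05).
#' @param cs_correlation_threshold correlation the subsample centrality must
#'   maintain with the full-sample centrality (default 0.70).
#' @param cs_quantile probability with which the threshold must be
#'   maintained (default 0.95).
#' @param freeze_lambda reuse the full-sample per-outcome penalties in every
#'   resample instead of re-running cross-validation (default FALSE:
#'   re-selection is the honest-variability default; freezing trades a
#'   little variability for a large speedup).
#' @param seed RNG seed for resampling.
#' @return A list of class `clpn_boot_config`.
#' @export
bootstrap_config <- function(n_boot = 1000L, ci_level = 0.95,
                             drop_proportions = seq(0.10, 0.75, by = 0.05),
                             cs_correlation_threshold = 0.70,
                             cs_quantile = 0.95, freeze_lambda = FALSE,
                             seed = NULL) {
  if (ci_level <= 0 || ci_level >= 1) stop("ci_level must be in (0, 1)")
  if (any(drop_proportions <= 0 | drop_proportions >= 1) ||
      is.unsorted(drop_proportions, strictly = TRUE))
    stop("drop_proportions must be strictly increasing within (0, 1)")
  structure(list(n_boot = as.integer(n_boot), ci_level = ci_level,
                 drop_proportions = drop_proportions,
                 cs_correlation_threshold = cs_correlation_threshold,
                 cs_quantile = cs_quantile, freeze_lambda = freeze_lambda,
                 seed = seed),
            class = "clpn_boot_config")
}

# Predictor/outcome wave matrices with the direction convention applied,
# shared by the full fit and all resample refits.
boot_matrices <- function(panel, wave_t, wave_t1, fit_cfg) {
  if (fit_cfg$direction_convention == "recode_reverse_first" &&
      any(panel$codebook$reverse_keyed))
    panel <- recode_reverse(panel)
  Xt <- wave_matrix(panel, wave_t)
  Xt1 <- wave_matrix(panel, wave_t1)
  if (anyNA(Xt) || anyNA(Xt1))
    stop("panel has missing values in waves ", wave_t, "/", wave_t1,
         "; run chained_impute() or complete_cases() first")
  list(Xt = Xt, Xt1 = Xt1, items = panel$items)
}

# Node-wise refit on row subset idx with fixed per-outcome penalties.
refit_B <- function(Xt, Xt1, idx, lams, fit_cfg, penalize_ar) {
  p <- ncol(Xt)
  B <- matrix(0, p, p)
  Xs <- Xt[idx, , drop = FALSE]
  for (j in seq_len(p)) {
    pen <- rep(1, p)
    if (!penalize_ar) pen[j] <- 0
    fit <- penalized_logistic(Xs, Xt1[idx, j], lams[j], fit_cfg,
                              penalty = pen)
    B[, j] <- fit$coefficients
  }
  B
}

# Per-outcome penalties for a resample: frozen at the full-sample values
# or re-selected by CV on the resample.
resample_lambdas <- function(Xt, Xt1, idx, full, fit_cfg, boot_cfg) {
  if (boot_cfg$freeze_lambda || fit_cfg$lambda_mode == "fixed")
    return(full$lambda_used)
  p <- ncol(Xt)
  vapply(seq_len(p), function(j) {
    pen <- rep(1, p)
    if (!fit_cfg$penalize_autoregressive) pen[j] <- 0
    as.numeric(select_lambda(Xt[idx, , drop = FALSE], Xt1[idx, j],
                             fit_cfg, penalty = pen))
  }, 0)
}

# TRUE when every outcome column of the row subset retains both classes.
resample_ok <- function(Xt1, idx) {
  cm <- colMeans(Xt1[idx, , drop = FALSE])
  all(cm > 0 & cm < 1)
}

edge_ids <- function(items) {
  as.vector(outer(items, items, function(a, b) paste0(a, "->", b)))
}

#' Nonparametric bootstrap of edge weights
#'
#' Resamples persons with replacement `n_boot` times, refits the network on
#' every resample (re-selecting the penalty unless
#' `boot_config$freeze_lambda`), and returns the draws plus percentile
#' confidence intervals per edge. Resamples in which an outcome column is
#' single-class are redrawn (up to 10 consecutive attempts).
#'
#' @param panel complete [panel_dataset()].
#' @param wave_t,wave_t1 wave-pair labels.
#' @param fit_cfg a [fit_config()].
#' @param boot_cfg a [bootstrap_config()].
#' @return A list of class `clpn_boot` with the full-sample `network`,
#'   `edge_draws` (`n_boot` x items^2, columns named `src->tgt` in
#'   column-major order of `B`), `ci_lower`/`ci_upper` matrices, counts of
#'   redraws, and the configs.
#' @export
bootstrap_edges <- function(panel, wave_t, wave_t1,
                            fit_cfg = fit_config(),
                            boot_cfg = bootstrap_config()) {
  full <- fit_clpn(panel, wave_t, wave_t1, fit_cfg)
  mats <- boot_matrices(panel, wave_t, wave_t1, fit_cfg)
  n <- length(panel$persons)
  p <- length(full$items)
  draws <- matrix(NA_real_, boot_cfg$n_boot, p * p)
  colnames(draws) <- edge_ids(full$items)
  n_redraws <- 0L
  with_seed(boot_cfg$seed, {
    for (b in seq_len(boot_cfg$n_boot)) {
      attempts <- 0L
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (resample_ok(mats$Xt1, idx)) break
        attempts <- attempts + 1L
        n_redraws <- n_redraws + 1L
        if (attempts >= 10L)
          stop("resample kept producing a constant outcome column ",
               "after 10 redraws")
      }
      lams <- resample_lambdas(mats$Xt, mats$Xt1, idx, full, fit_cfg,
                               boot_cfg)
      draws[b, ] <- as.vector(
        refit_B(mats$Xt, mats$Xt1, idx, lams, fit_cfg,
                fit_cfg$penalize_autoregressive))
    }
  })
  if (n_redraws > 0L)
    message(n_redraws, " degenerate resample(s) redrawn")
  alpha <- (1 - boot_cfg$ci_level) / 2
  qs <- apply(draws, 2L, quantile, probs = c(alpha, 1 - alpha),
              names = FALSE)
  ci_lower <- matrix(qs[1L, ], p, p,
                     dimnames = dimnames(full$B))
  ci_upper <- matrix(qs[2L, ], p, p,
                     dimnames = dimnames(full$B))
  structure(list(network = full, edge_draws = draws,
                 ci_lower = ci_lower, ci_upper = ci_upper,
                 n_redraws = n_redraws, fit_config = fit_cfg,
                 boot_config = boot_cfg,
                 wave_pair = c(wave_t, wave_t1), items = full$items),
            class = "clpn_boot")
}

# Expected-influence draws (items columns) from stored edge draws.
ei_draws <- function(result, index = c("out", "in"),
                     include_autoregressive = FALSE) {
  index <- match.arg(index)
  p <- length(result$items)
  out <- matrix(0, nrow(result$edge_draws), p,
                dimnames = list(NULL, result$items))
  for (b in seq_len(nrow(result$edge_draws))) {
    B <- matrix(result$edge_draws[b, ], p, p)
    if (!include_autoregressive) diag(B) <- 0
    out[b, ] <- if (index == "out") rowSums(B) else colSums(B)
  }
  out
}

#' Case-drop bootstrap stability of centrality
#'
#' For each drop proportion, draws `n_boot` subsamples without replacement
#' retaining `(1 - p) * N` persons, refits the network, and correlates the
#' subsample expected influence with the full-sample expected influence.
#' The CS-coefficient is the largest drop proportion whose lower
#' `1 - cs_quantile` correlation quantile still reaches
#' `cs_correlation_threshold` (0 when no proportion qualifies).
#' Proportions whose retained sample is below 10 persons per item are
#' skipped with a warning. Degenerate subsample fits (zero centrality
#' spread) contribute a correlation of 0.
#'
#' @inheritParams bootstrap_edges
#' @return A list of class `clpn_casedrop` with `stability_curve` (one row
#'   per usable proportion: mean and lower-quantile correlation per index),
#'   `cs_out`, `cs_in`, the full-sample `network` and the configs.
#' @export
casedrop_stability <- function(panel, wave_t, wave_t1,
                               fit_cfg = fit_config(),
                               boot_cfg = bootstrap_config()) {
  full <- fit_clpn(panel, wave_t, wave_t1, fit_cfg)
  full_ei <- expected_influence(full)
  mats <- boot_matrices(panel, wave_t, wave_t1, fit_cfg)
  n <- length(panel$persons)
  p <- length(full$items)
  rows <- list()
  with_seed(boot_cfg$seed, {
    for (prop in boot_cfg$drop_proportions) {
      m <- round((1 - prop) * n)
      if (m < 10L * p) {
        warning("drop proportion ", prop, " retains only ", m,
                " persons; skipped", call. = FALSE)
        next
      }
      r_out <- r_in <- rep(NA_real_, boot_cfg$n_boot)
      for (b in seq_len(boot_cfg$n_boot)) {
        idx <- sample.int(n, m)
        if (!resample_ok(mats$Xt1, idx)) next
        lams <- resample_lambdas(mats$Xt, mats$Xt1, idx, full, fit_cfg,
                                 boot_cfg)
        B <- refit_B(mats$Xt, mats$Xt1, idx, lams, fit_cfg,
                     fit_cfg$penalize_autoregressive)
        diag(B) <- 0
        r_out[b] <- safe_cor(rowSums(B), full_ei$out_ei_raw)
        r_in[b] <- safe_cor(colSums(B), full_ei$in_ei_raw)
      }
      q <- 1 - boot_cfg$cs_quantile
      rows[[length(rows) + 1L]] <- data.frame(
        prop = prop,
        n_retained = m,
        n_used = sum(!is.na(r_out)),
        mean_r_out = mean(r_out, na.rm = TRUE),
        q_r_out = quantile(r_out, q, na.rm = TRUE, names = FALSE),
        mean_r_in = mean(r_in, na.rm = TRUE),
        q_r_in = quantile(r_in, q, na.rm = TRUE, names = FALSE))
    }
  })
  curve <- do.call(rbind, rows)
  cs_of <- function(qcol) {
    ok <- curve$prop[curve[[qcol]] >= boot_cfg$cs_correlation_threshold]
    if (length(ok)) max(ok) else 0
  }
  structure(list(stability_curve = curve,
                 cs_out = if (is.null(curve)) 0 else cs_of("q_r_out"),
                 cs_in = if (is.null(curve)) 0 else cs_of("q_r_in"),
                 network = full, fit_config = fit_cfg,
                 boot_config = boot_cfg),
            class = "clpn_casedrop")
}

safe_cor <- function(a, b) {
  if (sd(a) == 0 || sd(b) == 0) return(0)
  cor(a, b)
}

parse_edge <- function(edge, items) {
  if (length(edge) == 1L && grepl("->", edge, fixed = TRUE))
    edge <- strsplit(edge, "->", fixed = TRUE)[[1L]]
  if (length(edge) != 2L || !all(edge %in% items))
    stop("unknown edge: ", paste(edge, collapse = "->"))
  edge
}

#' Bootstrap difference test between two edges
#'
#' Tests whether two edge weights differ by forming the bootstrap
#' distribution of their difference; the difference is significant when the
#' percentile interval at `ci_level` excludes 0. No multiple-testing
#' correction is applied (the convention in the symptom-network
#' literature) — interpret families of such tests accordingly.
#'
#' @param result a `clpn_boot` from [bootstrap_edges()].
#' @param edge_a,edge_b edges as `"source->target"` strings or
#'   length-2 character vectors.
#' @param ci_level test level (default: the bootstrap config's).
#' @return List with `significant` (logical), `ci`, `estimate` (full-sample
#'   difference).
#' @export
edge_difference_test <- function(result, edge_a, edge_b,
                                 ci_level = result$boot_config$ci_level) {
  ea <- parse_edge(edge_a, result$items)
  eb <- parse_edge(edge_b, result$items)
  ida <- paste0(ea[1], "->", ea[2]); idb <- paste0(eb[1], "->", eb[2])
  d <- result$edge_draws[, ida] - result$edge_draws[, idb]
  alpha <- (1 - ci_level) / 2
  ci <- quantile(d, c(alpha, 1 - alpha), names = FALSE)
  est <- result$network$B[ea[1], ea[2]] - result$network$B[eb[1], eb[2]]
  list(significant = ci[1] > 0 || ci[2] < 0, ci = ci, estimate = est)
}

#' Bootstrap difference test between two items' centrality
#'
#' Analogous to [edge_difference_test()] on the bootstrap distribution of
#' the expected-influence difference of two items.
#'
#' @inheritParams edge_difference_test
#' @param item_a,item_b item ids.
#' @param index `"out"` or `"in"`.
#' @param include_autoregressive include self-paths in the sums.
#' @return List with `significant`, `ci`, `estimate`.
#' @export
centrality_difference_test <- function(result, item_a, item_b,
                                       index = c("out", "in"),
                                       ci_level =
                                         result$boot_config$ci_level,
                                       include_autoregressive = FALSE) {
  index <- match.arg(index)
  if (!all(c(item_a, item_b) %in% result$items))
    stop("unknown item id")
  E <- ei_draws(result, index, include_autoregressive)
  d <- E[, item_a] - E[, item_b]
  alpha <- (1 - ci_level) / 2
  ci <- quantile(d, c(alpha, 1 - alpha), names = FALSE)
  full_ei <- expected_influence(result$network, include_autoregressive)
  col <- paste0(index, "_ei_raw")
  est <- full_ei[[col]][full_ei$item == item_a] -
    full_ei[[col]][full_ei$item == item_b]
  list(significant = ci[1] > 0 || ci[2] < 0, ci = ci, estimate = est)
}
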