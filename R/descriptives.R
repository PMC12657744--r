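#' Item endorsement per item-wave
#'
#' Counts and proportions of persons endorsing each item at each wave,
#' computed over the non-missing responses, together with the closed-form
#' Bernoulli moments of each proportion (NA when the proportion is 0 or 1).
#'
#' @param panel a [panel_dataset()].
#' @return Data frame with one row per item-wave: `item`, `wave`,
#'   `n_observed`, `n_endorsed`, `prop_endorsed`, `skewness`,
#'   `excess_kurtosis`.
#' @export
endorsement <- function(panel) {
  rows <- expand.grid(item = panel$items, wave = panel$waves,
                      stringsAsFactors = FALSE)
  stat <- t(mapply(function(it, wv) {
    v <- panel$responses[, it, wv]
    v <- v[!is.na(v)]
    c(n_obs = length(v), n_end = sum(v),
      p = if (length(v)) mean(v) else 0)
  }, rows$item, rows$wave))
  mom <- t(apply(stat, 1L, function(s) {
    if (s["p"] > 0 && s["p"] < 1) unlist(bernoulli_moments(s["p"]))
    else c(skewness = NA_real_, excess_kurtosis = NA_real_)
  }))
  data.frame(item = rows$item, wave = rows$wave,
             n_observed = as.integer(stat[, "n_obs"]),
             n_endorsed = as.integer(stat[, "n_end"]),
             prop_endorsed = stat[, "p"],
             skewness = mom[, 1], excess_kurtosis = mom[, 2],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Closed-form moments of a Bernoulli item
#'
#' Population skewness and excess kurtosis of a 0/1 item with endorsement
#' probability `p`: skewness `(1 - 2p) / sqrt(p(1-p))` and excess kurtosis
#' `(1 - 6p(1-p)) / (p(1-p))`. At `p = 0.5` these are 0 and -2.
#'
#' @param p endorsement proportion, strictly in (0, 1).
#' @return List with `skewness` and `excess_kurtosis`.
#' @export
bernoulli_moments <- function(p) {
  if (any(p <= 0 | p >= 1))
    stop("moments are undefined at p = 0 or p = 1")
  q <- p * (1 - p)
  list(skewness = (1 - 2 * p) / sqrt(q),
       excess_kurtosis = (1 - 6 * q) / q)
}

#' KR-20 internal consistency for dichotomous items
#'
#' Kuder-Richardson formula 20,
#' `k/(k-1) * (1 - sum(p_i (1 - p_i)) / Var(sum))`, with population
#' (divide-by-n) variances throughout; on 0/1 data this equals Cronbach's
#' alpha computed with the same variance convention.
#'
#' @param items numeric matrix, persons x items, values 0/1 with no
#'   missing.
#' @return Alpha (numeric scalar).
#' @export
kr20_alpha <- function(items) {
  items <- as.matrix(items)
  if (ncol(items) < 2L) stop("need at least 2 items")
  if (anyNA(items)) stop("missing values: impute or drop incomplete rows")
  n <- nrow(items)
  p <- colMeans(items)
  total <- rowSums(items)
  var_total <- mean((total - mean(total))^2)
  if (var_total == 0) stop("zero total-score variance")
  k <- ncol(items)
  (k / (k - 1)) * (1 - sum(p * (1 - p)) / var_total)
}

#' Paired t-test on per-person sum scores
#'
#' Classical paired-samples t-test of the wave-to-wave change in sum
#' scores, two-sided.
#'
#' @param sum_t,sum_t1 per-person scores at the two waves (same persons,
#'   same order).
#' @return List with `t`, `p`, `df`, `mean_diff` (wave t+1 minus wave t).
#' @export
paired_ttest <- function(sum_t, sum_t1) {
  if (length(sum_t) != length(sum_t1))
    stop("score vectors must pair the same persons")
  d <- sum_t1 - sum_t
  if (sd(d) == 0) stop("zero-variance differences")
  ht <- t.test(sum_t1, sum_t, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), mean_diff = mean(d))
}
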