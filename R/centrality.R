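#' Expected-influence centrality of a cross-lagged network
#'
#' Out-expected influence of an item is the sum of its outgoing cross-lagged
#' edge weights (the degree to which a symptom predicts the other symptoms
#' at the next wave); in-expected influence is the sum of its incoming
#' weights. Sums are taken on the log-odds scale, so an absent edge
#' (odds ratio 1) contributes 0. Each index is also z-standardized across
#' the network's items; when an index has zero spread its z-scores are
#' reported as 0 and flagged.
#'
#' @param net a `clpn_network`.
#' @param include_autoregressive include the self-path in the sums
#'   (default FALSE: self-prediction is not inter-symptom influence).
#' @return A data frame of class `clpn_centrality` with columns `item`,
#'   `out_ei_raw`, `in_ei_raw`, `out_ei_z`, `in_ei_z`, and attribute
#'   `degenerate_sd` (named logical for the two indices).
#' @export
expected_influence <- function(net, include_autoregressive = FALSE) {
  B <- net$B
  if (!include_autoregressive) diag(B) <- 0
  out_raw <- rowSums(B)
  in_raw <- colSums(B)
  zstd <- function(v) {
    s <- sd(v)
    if (is.na(s) || s == 0) list(z = rep(0, length(v)), degenerate = TRUE)
    else list(z = (v - mean(v)) / s, degenerate = FALSE)
  }
  zo <- zstd(out_raw); zi <- zstd(in_raw)
  tab <- data.frame(item = net$items, out_ei_raw = unname(out_raw),
                    in_ei_raw = unname(in_raw), out_ei_z = unname(zo$z),
                    in_ei_z = unname(zi$z), row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(tab, "degenerate_sd") <- c(out = zo$degenerate, `in` = zi$degenerate)
  class(tab) <- c("clpn_centrality", "data.frame")
  tab
}

#' Correlate centrality between two networks
#'
#' Pearson correlation of the raw expected-influence vectors of two
#' networks over the same item set (aligned by item name).
#'
#' @param tab1,tab2 `clpn_centrality` tables.
#' @param index `"out"` or `"in"`.
#' @return Pearson r.
#' @export
centrality_correlation <- function(tab1, tab2, index = c("out", "in")) {
  index <- match.arg(index)
  if (!setequal(tab1$item, tab2$item))
    stop("centrality tables cover different item sets")
  col <- paste0(index, "_ei_raw")
  v1 <- tab1[[col]]
  v2 <- tab2[[col]][match(tab1$item, tab2$item)]
  if (sd(v1) == 0 || sd(v2) == 0)
    stop("zero variance in a centrality vector")
  cor(v1, v2)
}
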