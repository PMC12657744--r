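#' Count non-zero edges of a network
#'
#' @param net a `clpn_network`.
#' @param include_autoregressive count the diagonal self-paths too
#'   (default FALSE: cross-lagged edges only).
#' @return Integer count.
#' @export
count_nonzero <- function(net, include_autoregressive = FALSE) {
  B <- net$B
  if (!include_autoregressive) diag(B) <- 0
  sum(B != 0)
}

#' Correlation of two networks' edge lists
#'
#' Pearson correlation over the vectorized cross-lagged entries
#' (autoregressive paths excluded by default), with structural zeros
#' included by default so sparsity patterns count toward (dis)agreement.
#'
#' @param net1,net2 `clpn_network`s over the same item set.
#' @param scale `"log_odds"` (default) or `"odds_ratio"`.
#' @param include_zeros keep entries that are zero in both networks
#'   (default TRUE); when FALSE, only entries non-zero in at least one
#'   network enter.
#' @param include_autoregressive include the diagonal (default FALSE).
#' @return Pearson r.
#' @export
edge_correlation <- function(net1, net2,
                             scale = c("log_odds", "odds_ratio"),
                             include_zeros = TRUE,
                             include_autoregressive = FALSE) {
  scale <- match.arg(scale)
  if (!identical(net1$items, net2$items))
    stop("networks cover different item sets")
  m1 <- net1$B; m2 <- net2$B
  if (scale == "odds_ratio") { m1 <- exp(m1); m2 <- exp(m2) }
  keep <- matrix(TRUE, nrow(m1), ncol(m1))
  if (!include_autoregressive) diag(keep) <- FALSE
  if (!include_zeros) keep <- keep & (net1$B != 0 | net2$B != 0)
  v1 <- m1[keep]; v2 <- m2[keep]
  if (sd(v1) == 0 || sd(v2) == 0)
    stop("zero variance in an edge vector")
  cor(v1, v2)
}

#' Strongest cross-lagged edges of a network
#'
#' Cross-lagged edges ranked by the magnitude of their log-odds weight
#' (so strong negative edges rank too); ties broken by (source, target)
#' lexicographic order. Zero entries never appear.
#'
#' @param net a `clpn_network`.
#' @param k number of edges to return (default 5).
#' @return Data frame `source`, `target`, `log_odds`, `odds_ratio`, at most
#'   `k` rows.
#' @export
top_edges <- function(net, k = 5L) {
  B <- net$B
  diag(B) <- 0
  nz <- which(B != 0, arr.ind = TRUE)
  df <- data.frame(source = net$items[nz[, 1]],
                   target = net$items[nz[, 2]],
                   log_odds = B[nz], odds_ratio = exp(B[nz]),
                   stringsAsFactors = FALSE)
  ord <- order(-abs(df$log_odds), df$source, df$target)
  utils::head(df[ord, , drop = FALSE], k)
}

#' Compare a set of fitted networks
#'
#' Collects per-network non-zero edge counts and top-k edges, and pairwise
#' edge-list and centrality correlations.
#'
#' @param nets named list of `clpn_network`s over the same items.
#' @param k how many top edges per network (default 5).
#' @param include_autoregressive scope of the non-zero edge count.
#' @return A list of class `clpn_comparison` with `nonzero_counts`,
#'   `edge_correlation` (matrix), `centrality_correlations` (list of
#'   matrices per index), `top_edges` (list of data frames).
#' @export
compare_networks <- function(nets, k = 5L, include_autoregressive = FALSE) {
  if (is.null(names(nets)))
    names(nets) <- paste0("net", seq_along(nets))
  nn <- length(nets)
  counts <- vapply(nets, count_nonzero, 0L,
                   include_autoregressive = include_autoregressive)
  ec <- matrix(1, nn, nn, dimnames = list(names(nets), names(nets)))
  cc_out <- cc_in <- ec
  tabs <- lapply(nets, expected_influence)
  for (i in seq_len(nn)) for (j in seq_len(nn)) {
    if (i == j) next
    ec[i, j] <- edge_correlation(nets[[i]], nets[[j]])
    cc_out[i, j] <- centrality_correlation(tabs[[i]], tabs[[j]], "out")
    cc_in[i, j] <- centrality_correlation(tabs[[i]], tabs[[j]], "in")
  }
  structure(list(nonzero_counts = counts, edge_correlation = ec,
                 centrality_correlations = list(out = cc_out, `in` = cc_in),
                 top_edges = lapply(nets, top_edges, k = k)),
            class = "clpn_comparison")
}
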