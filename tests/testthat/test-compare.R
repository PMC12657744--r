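make_net2 <- function(B, items = paste0("v", seq_len(ncol(B)))) {
  dimnames(B) <- list(items, items)
  clpnet:::new_clpn_network(items, B, rep(0, ncol(B)),
                            rep(0.1, ncol(B)), 10L, c("w1", "w2"))
}

test_that("non-zero edge counting respects the autoregressive flag", {
  expect_equal(count_nonzero(make_net2(matrix(0, 8, 8))), 0L)
  B <- diag(8) * 1.2
  B[1, 2] <- 0.5
  net <- make_net2(B)
  expect_equal(count_nonzero(net), 1L)
  expect_equal(count_nonzero(net, include_autoregressive = TRUE), 9L)
})

test_that("edge counts agree with a scan of the exported edge list", {
  pan <- small_fixture_panel(n = 700, seed = 40)
  net <- fit_clpn(pan, "w1", "w2", raw_cfg(seed = 40))
  path <- withr_local_file("scan.csv")
  export_network(net, path, "edge_list_csv")
  df <- read.csv(path)
  expect_equal(count_nonzero(net), sum(!df$is_autoregressive))
  expect_equal(count_nonzero(net, TRUE), nrow(df))
})

test_that("edge correlation is exact, symmetric and scale-invariant", {
  B1 <- matrix(c(0, 0.5, -0.2, 0, 0, 0.4, 0.1, 0, 0), 3, 3, byrow = TRUE)
  diag(B1) <- 1
  B2 <- matrix(c(0, 0.3, 0.1, -0.2, 0, 0.2, 0, 0.5, 0), 3, 3,
               byrow = TRUE)
  diag(B2) <- 0.8
  n1 <- make_net2(B1); n2 <- make_net2(B2)
  expect_equal(edge_correlation(n1, n1), 1)
  n_half <- make_net2(B1 * 0.5)
  expect_equal(edge_correlation(n1, n_half), 1, tolerance = 1e-12)
  # direct formula oracle over the 6 cross-lagged entries
  off <- row(B1) != col(B1)
  expect_equal(edge_correlation(n1, n2), cor(B1[off], B2[off]),
               tolerance = 1e-12)
  expect_equal(edge_correlation(n1, n2), edge_correlation(n2, n1))
  expect_error(edge_correlation(n1, make_net2(diag(3))), "variance")
})

test_that("edge correlation is invariant to simultaneous relabeling", {
  pan <- small_fixture_panel(n = 500, seed = 41)
  cfg <- raw_cfg(lambda_mode = "fixed", lambda_value = 0.02)
  netA <- fit_clpn(pan, "w1", "w2", cfg)
  pan2 <- small_fixture_panel(n = 500, seed = 42)
  netB <- fit_clpn(pan2, "w1", "w2", cfg)
  r <- edge_correlation(netA, netB)
  perm <- c(5, 2, 7, 1, 8, 3, 6, 4)
  permute <- function(net) {
    net$B <- net$B[perm, perm]
    net$items <- net$items[perm]
    dimnames(net$B) <- list(net$items, net$items)
    net
  }
  expect_equal(edge_correlation(permute(netA), permute(netB)), r,
               tolerance = 1e-12)
})

test_that("top edges rank by magnitude with lexicographic tie-breaks", {
  B <- matrix(0, 3, 3)
  B[1, 2] <- 0.9; B[2, 1] <- -0.8; B[3, 1] <- 0.3
  net <- make_net2(B)
  top2 <- top_edges(net, 2)
  expect_equal(top2$log_odds, c(0.9, -0.8))
  one <- make_net2(matrix(c(0, 0.4, 0, 0, 0, 0, 0, 0, 0), 3, 3,
                          byrow = TRUE))
  expect_equal(nrow(top_edges(one, 5)), 1L)
  # ties broken by source then target
  Bt <- matrix(0, 3, 3)
  Bt[2, 1] <- 0.5; Bt[1, 3] <- 0.5
  tt <- top_edges(make_net2(Bt), 2)
  expect_equal(tt$source, c("v1", "v2"))
  # k large enough returns every nonzero cross-lagged edge
  pan <- small_fixture_panel(n = 400, seed = 43)
  fitted <- fit_clpn(pan, "w1", "w2",
                     raw_cfg(lambda_mode = "fixed", lambda_value = 0.02))
  all_edges <- top_edges(fitted, 8 * 7)
  expect_equal(nrow(all_edges), count_nonzero(fitted))
  # ranking equals a brute-force sort of the exported edge list
  path <- withr_local_file("sort.csv")
  export_network(fitted, path, "edge_list_csv")
  df <- read.csv(path)
  df <- df[!df$is_autoregressive, ]
  df <- df[order(-abs(df$log_odds), df$source, df$target), ]
  expect_equal(all_edges$log_odds, df$log_odds, tolerance = 1e-12)
})

test_that("compare_networks assembles counts, correlations and rankings", {
  pans <- lapply(44:46, function(s) small_fixture_panel(n = 600, seed = s))
  nets <- lapply(pans, fit_clpn, wave_t = "w1", wave_t1 = "w2",
                 config = raw_cfg(lambda_mode = "fixed",
                                  lambda_value = 0.02))
  cmp <- compare_networks(nets)
  expect_length(cmp$nonzero_counts, 3L)
  expect_true(all(cmp$nonzero_counts <= 56))
  expect_true(all(abs(cmp$edge_correlation) <= 1))
  expect_equal(diag(cmp$edge_correlation), rep(1, 3),
               ignore_attr = TRUE)
  expect_equal(cmp$edge_correlation["net1", "net2"],
               edge_correlation(nets[[1]], nets[[2]]))
  expect_true(all(vapply(cmp$top_edges, nrow, 0L) <= 5))
})
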