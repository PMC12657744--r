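fast_boot_cfg <- function(n_boot = 60, seed = 5, ...) {
  bootstrap_config(n_boot = n_boot, freeze_lambda = TRUE, seed = seed, ...)
}

test_that("bootstrap draws are reproducible under a fixed seed", {
  pan <- small_fixture_panel(n = 600, seed = 30)
  b1 <- bootstrap_edges(pan, "w1", "w2", raw_cfg(), fast_boot_cfg())
  b2 <- bootstrap_edges(pan, "w1", "w2", raw_cfg(), fast_boot_cfg())
  expect_identical(b1$edge_draws, b2$edge_draws)
  b3 <- bootstrap_edges(pan, "w1", "w2", raw_cfg(),
                        fast_boot_cfg(seed = 6))
  expect_false(identical(b1$edge_draws, b3$edge_draws))
})

test_that("the full-sample point estimate ignores the bootstrap config", {
  pan <- small_fixture_panel(n = 600, seed = 31)
  b1 <- bootstrap_edges(pan, "w1", "w2", raw_cfg(), fast_boot_cfg(20))
  b2 <- bootstrap_edges(pan, "w1", "w2", raw_cfg(),
                        fast_boot_cfg(40, seed = 9))
  expect_identical(b1$network$B, b2$network$B)
})

test_that("wider intervals contain narrower ones edge by edge", {
  pan <- small_fixture_panel(n = 600, seed = 32)
  b95 <- bootstrap_edges(pan, "w1", "w2", raw_cfg(),
                         fast_boot_cfg(ci_level = 0.95))
  b99 <- bootstrap_edges(pan, "w1", "w2", raw_cfg(),
                         fast_boot_cfg(ci_level = 0.99))
  expect_true(all(b99$ci_lower <= b95$ci_lower + 1e-12))
  expect_true(all(b99$ci_upper >= b95$ci_upper - 1e-12))
  expect_true(all(b95$ci_lower <= b95$ci_upper))
})

test_that("a strong true edge is detected: its CI excludes zero", {
  spec <- cesd8_synthetic_spec(seed = 11, missingness = FALSE)
  pan <- simulate_panel(spec, 2000)
  b <- bootstrap_edges(pan, "w8", "w9", raw_cfg(seed = 11),
                       fast_boot_cfg(n_boot = 200, seed = 11))
  expect_gt(b$ci_lower["effort", "getgoing"], 0)
})

test_that("an edge is never significantly different from itself", {
  pan <- small_fixture_panel(n = 600, seed = 33)
  b <- bootstrap_edges(pan, "w1", "w2", raw_cfg(), fast_boot_cfg())
  d <- edge_difference_test(b, "effort->getgoing", "effort->getgoing")
  expect_false(d$significant)
  expect_equal(d$ci, c(0, 0))
  expect_error(edge_difference_test(b, "effort->nosuch", "a->b"),
               "unknown edge")
})

test_that("clearly separated edges test as different", {
  spec <- cesd8_synthetic_spec(seed = 12, missingness = FALSE)
  pan <- simulate_panel(spec, 2000)
  b <- bootstrap_edges(pan, "w8", "w9", raw_cfg(seed = 12),
                       fast_boot_cfg(n_boot = 200, seed = 12))
  d <- edge_difference_test(b, "effort->getgoing", "sleep->happy")
  expect_true(d$significant)
})

test_that("a hub node out-influences an isolated node significantly", {
  cb <- item_codebook(paste0("v", 1:6))
  B <- matrix(0, 6, 6)
  diag(B) <- 0.8
  B[1, 2] <- B[1, 3] <- B[1, 4] <- 1.0   # v1 is the hub; v6 isolated
  spec <- synthetic_spec(cb, 2, rep(0.35, 6), B, seed = 13)
  pan <- simulate_panel(spec, 2500)
  b <- bootstrap_edges(pan, "w1", "w2", raw_cfg(seed = 13),
                       fast_boot_cfg(n_boot = 150, seed = 13))
  d <- centrality_difference_test(b, "v1", "v6", "out")
  expect_true(d$significant)
  self <- centrality_difference_test(b, "v3", "v3", "out")
  expect_false(self$significant)
})

test_that("constant-outcome resamples are redrawn and then refused", {
  # every outcome item endorsed by a single distinct person: a resample
  # missing any of them is single-class, so the redraw budget exhausts
  set.seed(1)
  resp <- array(0, dim = c(12, 8, 2))
  resp[, , 1] <- rbinom(12 * 8, 1, 0.5)
  for (j in 1:8) resp[j, j, 2] <- 1
  pan <- panel_dataset(resp, item_codebook(letters[1:8]))
  expect_error(
    suppressMessages(bootstrap_edges(
      pan, "w1", "w2",
      raw_cfg(lambda_mode = "fixed", lambda_value = 0.05),
      bootstrap_config(n_boot = 50, seed = 3, freeze_lambda = TRUE))),
    "redraws")
})

test_that("case-drop stability produces sane curves on a small panel", {
  pan <- small_fixture_panel(n = 1200, seed = 34)
  suppressWarnings(
    cs <- casedrop_stability(pan, "w1", "w2", raw_cfg(seed = 34),
                             fast_boot_cfg(n_boot = 30, seed = 34,
                                           drop_proportions = c(0.1, 0.3,
                                                                0.95))))
  curve <- cs$stability_curve
  expect_equal(nrow(curve), 2L)   # 0.95 skipped: too few retained persons
  expect_true(all(curve$mean_r_out >= -1 & curve$mean_r_out <= 1))
  expect_true(all(curve$q_r_out <= curve$mean_r_out + 1e-12 |
                    curve$n_used < 30))
  expect_true(cs$cs_out %in% c(0, curve$prop))
})
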