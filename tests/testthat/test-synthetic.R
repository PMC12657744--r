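test_that("identical specs produce bit-identical panels", {
  spec <- cesd8_synthetic_spec(seed = 11)
  p1 <- simulate_panel(spec, 200)
  p2 <- simulate_panel(spec, 200)
  expect_identical(p1$responses, p2$responses)
  expect_identical(p1$aux, p2$aux)
  p3 <- simulate_panel(cesd8_synthetic_spec(seed = 12), 200)
  expect_false(identical(p1$responses, p3$responses))
})

test_that("saturated negative intercepts force all later waves to zero", {
  cb <- cesd8_codebook()
  spec <- synthetic_spec(cb, 3, rep(0.5, 8), matrix(0, 8, 8),
                         intercepts = rep(-20, 8), seed = 1)
  pan <- simulate_panel(spec, 200)
  expect_true(all(pan$responses[, , 2:3] == 0))
})

test_that("zero network with zero intercepts gives prevalence one half", {
  cb <- cesd8_codebook()
  spec <- synthetic_spec(cb, 2, rep(0.5, 8), matrix(0, 8, 8),
                         intercepts = rep(0, 8), seed = 2)
  pan <- simulate_panel(spec, 10000)
  prev2 <- colMeans(pan$responses[, , 2])
  expect_true(all(abs(prev2 - 0.5) < 0.02))
})

test_that("conditional transition frequencies match the logistic law", {
  # single edge b_12 = 1, c_2 = -1: P(x2'=1 | x1=1) = plogis(0) = 0.5,
  # P(x2'=1 | x1=0) = plogis(-1) = 0.2689
  cb <- item_codebook(c("x1", "x2"))
  B <- matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE)
  spec <- synthetic_spec(cb, 2, c(0.5, 0.3), B,
                         intercepts = c(-0.5, -1), seed = 3)
  pan <- simulate_panel(spec, 20000)
  x1 <- pan$responses[, 1, 1]
  x2n <- pan$responses[, 2, 2]
  expect_equal(mean(x2n[x1 == 1]), 0.5, tolerance = 0.02)
  expect_equal(mean(x2n[x1 == 0]), plogis(-1), tolerance = 0.02)
})

test_that("intercept calibration reduces to logit under a zero network", {
  cb <- cesd8_codebook()
  B <- matrix(0, 8, 8)
  cal <- calibrate_intercepts(B, rep(0.1213, 8), rep(0.3, 8))
  expect_equal(unname(cal), rep(qlogis(0.1213), 8), tolerance = 1e-3)
  cal5 <- calibrate_intercepts(B, rep(0.5, 8), rep(0.5, 8))
  expect_equal(unname(cal5), rep(0, 8), tolerance = 1e-10)
})

test_that("3-item calibration matches a brute-force grid search", {
  cb <- item_codebook(c("x1", "x2", "x3"))
  B <- matrix(0, 3, 3)
  B[1, 2] <- 0.8
  B[3, 2] <- -0.3
  prev <- c(0.4, 0.25, 0.6)
  cal <- calibrate_intercepts(B, target_prev = prev,
                              predecessor_prev = prev)
  # independent oracle: exact expectation over the 2^3 predecessor states,
  # minimized on a fine grid
  states <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  wts <- apply(states, 1, function(s) prod(ifelse(s == 1, prev, 1 - prev)))
  grid <- seq(-6, 6, by = 1e-4)
  target_fn <- function(c0) {
    etas <- c0 + drop(states %*% B[, 2])
    sum(wts * plogis(etas))
  }
  vals <- vapply(grid, target_fn, 0)
  c2_grid <- grid[which.min(abs(vals - prev[2]))]
  expect_equal(unname(cal[2]), c2_grid, tolerance = 1e-4)
})

test_that("calibrated fixture keeps later-wave prevalences near targets", {
  spec <- cesd8_synthetic_spec(seed = 5, missingness = FALSE)
  pan <- simulate_panel(spec, 8000)
  for (w in 2:4) {
    prev <- colMeans(pan$responses[, , w])
    expect_true(all(abs(prev - spec$wave1_prevalence) < 0.05))
  }
})

test_that("missingness model behaves at its limits and is MAR-directional", {
  spec <- cesd8_synthetic_spec(seed = 6)
  pan <- simulate_panel(spec, 10000)
  # all coefficients at -20: nothing goes missing
  spec_none <- spec
  spec_none$missing_model <- list(intercept = -20, coef = NULL,
                                  sum_coef = 0)
  expect_false(anyNA(apply_missingness(pan, spec_none)$responses))
  # intercept 0, no covariate effects: about half the person-waves drop
  spec_half <- spec
  spec_half$missing_model <- list(intercept = 0, coef = NULL, sum_coef = 0)
  miss <- apply_missingness(pan, spec_half)
  rate <- mean(is.na(miss$responses[, 1, 2]))
  expect_equal(rate, 0.5, tolerance = 0.02)
  expect_false(anyNA(miss$responses[, , 1]))
  # positive weight on the wave-1 sum score: higher scorers drop out more
  spec_mar <- spec
  spec_mar$missing_model <- list(intercept = -1.5, coef = NULL,
                                 sum_coef = 0.4)
  miss2 <- apply_missingness(pan, spec_mar)
  s1 <- sum_scores(pan, "w8")
  dropped <- is.na(miss2$responses[, 1, 2])
  expect_gt(mean(dropped[s1 >= 3]), mean(dropped[s1 <= 1]))
})

test_that("synthetic spec YAML round trip preserves the generative model", {
  spec <- cesd8_synthetic_spec(seed = 9)
  path <- withr_local_file("spec.yaml")
  write_synthetic_spec(spec, path)
  back <- read_synthetic_spec(path)
  expect_equal(back$true_network, spec$true_network, tolerance = 1e-12)
  expect_equal(back$wave1_prevalence, spec$wave1_prevalence)
  expect_equal(back$missing_model$sum_coef, spec$missing_model$sum_coef)
  expect_identical(simulate_panel(back, 100)$responses,
                   simulate_panel(spec, 100)$responses)
})
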