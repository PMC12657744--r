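test_that("large penalties shrink everything; intercept is logit(mean)", {
  d <- sim_logit_data(300, c(0.8, -0.5, 0.3), seed = 1)
  f <- penalized_logistic(d$X, d$y, 10)
  expect_true(all(f$coefficients == 0))
  expect_identical(f$intercept, qlogis(mean(d$y)))
})

test_that("unpenalized fits agree with the Newton-IRLS oracle (glm)", {
  for (s in 1:5) {
    betas <- runif(3 + (s %% 3), -1, 1)
    d <- sim_logit_data(200, betas, seed = 100 + s)
    f <- penalized_logistic(d$X, d$y, 0)
    g <- glm(d$y ~ d$X, family = binomial())
    expect_lt(max(abs(c(f$intercept, f$coefficients) - coef(g))), 1e-4)
  }
})

test_that("penalized fits agree with glmnet at matched penalties", {
  skip_if_not_installed("glmnet")
  d <- sim_logit_data(600, c(1, -0.6, 0, 0.4, 0), seed = 3)
  for (lam in c(0.05, 0.01, 0.002)) {
    f <- penalized_logistic(d$X, d$y, lam)
    g <- glmnet::glmnet(d$X, d$y, family = "binomial", lambda = lam,
                        standardize = FALSE, thresh = 1e-12)
    expect_lt(max(abs(c(f$intercept, f$coefficients) -
                        as.numeric(coef(g)))), 1e-5)
  }
})

test_that("exactly collinear predictors are refused at lambda zero", {
  d <- sim_logit_data(200, c(1, 0.5), seed = 4)
  X <- cbind(d$X, dup = d$X[, 1])
  expect_error(penalized_logistic(X, d$y, 0), "collinear")
  # but the LASSO resolves them at lambda > 0
  f <- penalized_logistic(X, d$y, 0.02)
  expect_true(all(is.finite(f$coefficients)))
})

test_that("constant outcomes are refused", {
  d <- sim_logit_data(50, c(1), seed = 5)
  expect_error(penalized_logistic(d$X, rep(1, 50), 0.1), "constant")
})

test_that("total shrinkage is monotone along the penalty path", {
  pan <- small_fixture_panel(n = 700, seed = 10)
  X <- wave_matrix(pan, "w1")
  y <- wave_matrix(pan, "w2")[, "depressed"]
  lams <- exp(seq(log(0.1), log(1e-4), length.out = 12))
  l1 <- vapply(lams, function(l)
    sum(abs(penalized_logistic(X, y, l)$coefficients)), 0)
  expect_true(all(diff(l1) >= -1e-8))   # decreasing lambda grows the fit
})

test_that("at lambda_max the selected path head keeps all coefficients 0", {
  d <- sim_logit_data(400, c(0.8, 0, -0.4), seed = 6)
  lmax <- clpnet:::lambda_max_value(d$X, d$y)
  f <- penalized_logistic(d$X, d$y, lmax)
  expect_true(all(f$coefficients == 0))
  sl <- select_lambda(d$X, d$y, fit_config(seed = 1))
  expect_equal(max(attr(sl, "path")), lmax, tolerance = 1e-12)
})

test_that("lambda selection keeps noise sparse and retains strong signal", {
  # pure-noise outcome: most coefficients shrunk away
  set.seed(21)
  X <- matrix(rbinom(2000 * 8, 1, 0.35), 2000, 8,
              dimnames = list(NULL, paste0("x", 1:8)))
  y <- rbinom(2000, 1, 0.3)
  lam <- select_lambda(X, y, fit_config(seed = 2))
  f <- penalized_logistic(X, y, as.numeric(lam))
  expect_gte(sum(f$coefficients == 0), 6L)
  # strong single predictor survives selection
  d <- sim_logit_data(2000, c(2, 0, 0, 0), intercept = -1, seed = 7)
  lam2 <- select_lambda(d$X, d$y, fit_config(seed = 2))
  f2 <- penalized_logistic(d$X, d$y, as.numeric(lam2))
  expect_gt(f2$coefficients[1], 0)
})

test_that("the 1-SE rule never selects a smaller penalty than cv_min", {
  d <- sim_logit_data(1500, c(0.9, 0, -0.5, 0, 0, 0.3), seed = 8)
  lmin <- select_lambda(d$X, d$y, fit_config(seed = 3))
  l1se <- select_lambda(d$X, d$y, fit_config("cv_1se", seed = 3))
  expect_gte(as.numeric(l1se), as.numeric(lmin))
})

test_that("relabeling items permutes the network accordingly", {
  pan <- small_fixture_panel(n = 500, seed = 12)
  cfg <- raw_cfg(lambda_mode = "fixed", lambda_value = 0.01)
  net <- fit_clpn(pan, "w1", "w2", cfg)
  perm <- c(3, 1, 2, 5, 4, 8, 6, 7)
  cb2 <- item_codebook(pan$codebook$item_id[perm],
                       pan$codebook$label[perm],
                       pan$codebook$reverse_keyed[perm])
  pan2 <- panel_dataset(pan$responses[, perm, , drop = FALSE], cb2,
                        persons = pan$persons, waves = pan$waves)
  net2 <- fit_clpn(pan2, "w1", "w2", cfg)
  expect_equal(net2$B, net$B[perm, perm], tolerance = 1e-10)
  expect_equal(net2$intercepts, net$intercepts[perm], tolerance = 1e-10)
})

test_that("odds-ratio view maps zero weights to exactly one", {
  items <- c("a", "b", "c")
  B <- matrix(0, 3, 3, dimnames = list(items, items))
  B[1, 2] <- log(2); B[2, 3] <- -0.1054
  net <- clpnet:::new_clpn_network(items, B, rep(0, 3), rep(0.1, 3),
                                   10L, c("w1", "w2"))
  OR <- to_odds_ratios(net)
  expect_identical(OR[1, 1], 1)
  expect_identical(OR[3, 2], 1)
  expect_equal(OR[1, 2], 2, tolerance = 1e-12)
  expect_equal(OR[2, 3], 0.90, tolerance = 1e-3)
})

test_that("fitting refuses incomplete waves and constant outcome items", {
  pan <- small_fixture_panel(n = 120, seed = 13)
  pan$responses[3, 1, 2] <- NA
  expect_error(fit_clpn(pan, "w1", "w2", raw_cfg()), "missing")
  pan2 <- small_fixture_panel(n = 120, seed = 14)
  pan2$responses[, "sad", 2] <- 1
  expect_error(fit_clpn(pan2, "w1", "w2", raw_cfg()), "sad")
})

test_that("reverse-recoding before the fit transforms the estimand", {
  # with the default convention, reverse-keyed raw items enter recoded;
  # a raw-mode fit on the manually recoded panel must coincide
  pan <- small_fixture_panel(n = 900, seed = 15)
  cfg_fixed <- fit_config(lambda_mode = "fixed", lambda_value = 0.01,
                          direction_convention = "recode_reverse_first")
  net_default <- fit_clpn(pan, "w1", "w2", cfg_fixed)
  net_manual <- fit_clpn(recode_reverse(pan), "w1", "w2",
                         raw_cfg(lambda_mode = "fixed",
                                 lambda_value = 0.01))
  expect_equal(net_default$B, net_manual$B, tolerance = 1e-12)
})
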