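# Shared fixtures built in code.

tiny_codebook <- function() {
  item_codebook(c("a", "b"), c("item a", "item b"),
                reverse_keyed = c(FALSE, TRUE))
}

# 2-person, 2-item, 2-wave panel from explicit values (persons x items x waves)
tiny_panel <- function(values = rep(0, 8)) {
  panel_dataset(array(values, dim = c(2, 2, 2)), tiny_codebook())
}

# small simulated complete panel used across tests
small_fixture_panel <- function(n = 800, seed = 1, n_waves = 2) {
  simulate_panel(cesd8_synthetic_spec(n_waves = n_waves, seed = seed,
                                      missingness = FALSE), n)
}

# simple logistic regression dataset with known structure
sim_logit_data <- function(n, betas, intercept = -0.5, seed = 1,
                           prev = 0.4) {
  set.seed(seed)
  p <- length(betas)
  X <- matrix(rbinom(n * p, 1, prev), n, p,
              dimnames = list(NULL, paste0("x", seq_len(p))))
  y <- rbinom(n, 1, plogis(intercept + drop(X %*% betas)))
  list(X = X, y = y)
}

raw_cfg <- function(seed = 1, ...) {
  fit_config(seed = seed, direction_convention = "raw", ...)
}

# temp file scheduled for cleanup when the calling test finishes
withr_local_file <- function(name, env = parent.frame()) {
  path <- file.path(withr::local_tempdir(.local_envir = env), name)
  path
}
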