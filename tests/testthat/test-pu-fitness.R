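# Build a pu_features object from explicit per-observation key lists.
fm_from_lists <- function(input, sorted, min_count = 1L) {
  feature_matrix(input, sorted, min_mutation_count = min_count)
}

test_that("PU objective has the closed form at zero coefficients", {
  # 100 observations per pool, one feature carried by half of each pool
  input <- c(rep(list("A1V"), 50), rep(list(character(0)), 50))
  sorted <- c(rep(list("A1V"), 50), rep(list(character(0)), 50))
  fm <- fm_from_lists(input, sorted)
  # beta = 0, beta0 = 0: sigma = 0.5, q = 100*0.5/(100*0.5 + 100*0.5) = 0.5
  out <- pu_negative_log_likelihood(0, 0, fm, prior_pi = 0.5)
  expect_equal(out$objective, 200 * log(2), tolerance = 1e-12)
})

test_that("PU gradient matches central finite differences", {
  set.seed(33)
  for (rep in 1:5) {
    keys <- random_keys(6, seed = rep)
    obs <- function(n) lapply(seq_len(n),
                              function(i) sample(keys, sample.int(3, 1)))
    fm <- fm_from_lists(obs(60), obs(40))
    par <- c(rnorm(1), rnorm(length(fm$keys), 0, 1.5))
    pi0 <- runif(1, 0.1, 0.9)
    l2 <- 1e-3
    ana <- pu_negative_log_likelihood(par[1], par[-1], fm, pi0, l2)$gradient
    h <- 1e-6
    num <- vapply(seq_along(par), function(j) {
      up <- par; up[j] <- up[j] + h
      dn <- par; dn[j] <- dn[j] - h
      (pu_negative_log_likelihood(up[1], up[-1], fm, pi0, l2)$objective -
         pu_negative_log_likelihood(dn[1], dn[-1], fm, pi0, l2)$objective) / (2 * h)
    }, numeric(1L))
    expect_lt(max(abs(ana - num) / pmax(abs(num), 1)), 1e-5)
  }
})

test_that("objective is minimized near zero slopes when pools are shuffled", {
  set.seed(34)
  keys <- random_keys(5)
  all_obs <- lapply(1:20000, function(i) sample(keys, sample.int(2, 1)))
  z <- sample(rep(0:1, 10000))
  fm <- fm_from_lists(all_obs[z == 0], all_obs[z == 1])
  fit <- fit_pu_logistic(fm, prior_pi = 0.3, l2_penalty = 0)
  expect_true(all(abs(fit$beta) < 0.15))
  # fitted objective no worse than the zero-slope null
  null_obj <- pu_negative_log_likelihood(attr(fit, "beta0"),
                                         rep(0, length(fm$keys)),
                                         fm, 0.3)$objective
  expect_lte(attr(fit, "objective"), null_obj + 1e-8)
})

test_that("single-feature fit matches a dense grid search of the objective", {
  # fixed counts: feature in 200/1000 input reads and 700/1000 sorted reads
  input <- c(rep(list("C7G"), 200), rep(list(character(0)), 800))
  sorted <- c(rep(list("C7G"), 700), rep(list(character(0)), 300))
  fm <- fm_from_lists(input, sorted)
  fit <- fit_pu_logistic(fm, prior_pi = 0.25, l2_penalty = 0, tol = 1e-12)
  obj <- function(b0, b1)
    pu_negative_log_likelihood(b0, b1, fm, 0.25)$objective
  # two-stage grid refinement
  g0 <- seq(-6, 6, length.out = 121)
  g1 <- seq(-10, 10, length.out = 201)
  vals <- outer(g0, g1, Vectorize(obj))
  w <- which(vals == min(vals), arr.ind = TRUE)[1L, ]
  c0 <- g0[w[1L]]; c1 <- g1[w[2L]]
  g0 <- seq(c0 - 0.2, c0 + 0.2, by = 5e-4)
  g1 <- seq(c1 - 0.2, c1 + 0.2, by = 5e-4)
  vals <- outer(g0, g1, Vectorize(obj))
  w <- which(vals == min(vals), arr.ind = TRUE)[1L, ]
  expect_lt(abs(attr(fit, "beta0") - g0[w[1L]]), 1e-3)
  expect_lt(abs(fit$beta - g1[w[2L]]), 1e-3)
})

test_that("coefficients recover planted effects from a simulated screen", {
  keys <- random_keys(100, seed = 42)
  set.seed(42)
  beta_true <- setNames(rnorm(100, -1, 2), keys)
  lib <- keyed_library(keys, 2000, seed = 43)
  lib <- assign_ground_truth(lib, beta_true, 0.25, seed = 44)
  scr <- simulate_droplet_sort(lib, screen_config(seed = 45), 1e5)
  obs_in <- pool_observations(lib, scr$input_pool, 3e4, seed = 46)
  obs_so <- pool_observations(lib, scr$sorted_pool, 3e4, seed = 47)
  fm <- feature_matrix(obs_in, obs_so, 10)
  fit <- suppressWarnings(fit_pu_logistic(fm, 0.25, compute_se = FALSE))
  rho <- cor(fit$beta, beta_true[fit$key], method = "spearman")
  expect_gt(rho, 0.85)
})

test_that("recovery improves with sequencing depth", {
  keys <- random_keys(40, seed = 50)
  set.seed(50)
  beta_true <- setNames(rnorm(40, -1, 2), keys)
  lib <- keyed_library(keys, 800, seed = 51)
  lib <- assign_ground_truth(lib, beta_true, 0.25, seed = 52)
  rho_at <- function(depth, seed) {
    scr_cfg <- screen_config(seed = seed)
    scr <- simulate_droplet_sort(lib, scr_cfg, 4e4)
    fm <- feature_matrix(pool_observations(lib, scr$input_pool, depth, seed),
                         pool_observations(lib, scr$sorted_pool, depth, seed + 1L),
                         10)
    fit <- suppressWarnings(fit_pu_logistic(fm, 0.25, compute_se = FALSE))
    cor(fit$beta, beta_true[fit$key], method = "spearman")
  }
  seeds <- 1:10
  shallow <- mean(vapply(seeds, function(s) rho_at(1000L, 100L + s), numeric(1L)))
  deep <- mean(vapply(seeds, function(s) rho_at(10000L, 200L + s), numeric(1L)))
  expect_gte(deep, shallow)
})

test_that("stop gains land below the median of neutral substitutions", {
  keys <- c(random_keys(30, seed = 60), sprintf("K%d*", 101:110))
  beta_true <- setNames(rep(0, 40), keys)  # stops act through forced inactivity
  lib <- keyed_library(keys, 1500, seed = 61)
  lib <- assign_ground_truth(lib, beta_true, 0.25, seed = 62)
  scr <- simulate_droplet_sort(lib, screen_config(seed = 63), 6e4)
  fm <- feature_matrix(pool_observations(lib, scr$input_pool, 2e4, 64),
                       pool_observations(lib, scr$sorted_pool, 2e4, 65), 10)
  fit <- suppressWarnings(fit_pu_logistic(fm, 0.25, compute_se = FALSE))
  is_stop <- endsWith(fit$key, "*")
  expect_true(any(is_stop))
  neutral_median <- median(fit$beta[!is_stop])
  expect_true(all(fit$beta[is_stop] < neutral_median))
})

test_that("PU and naive log-enrichment agree in sign for common substitutions", {
  # low mutation load (<= 2 substitutions/variant) so the marginal
  # enrichment and the regression coefficient estimate the same effect;
  # at higher loads the PU fit deliberately conditions on co-occurring
  # mutations and the two quantities diverge for near-neutral sites
  keys <- random_keys(60, seed = 70)
  beta_true <- simulate_truth_coefficients(keys, seed = 71)
  lib <- keyed_library(keys, 800, max_subs = 2L, seed = 72)
  lib <- assign_ground_truth(lib, beta_true, 0.25, seed = 73)
  scr <- simulate_droplet_sort(lib, screen_config(seed = 74), 8e4)
  fm <- feature_matrix(pool_observations(lib, scr$input_pool, 3e4, 75),
                       pool_observations(lib, scr$sorted_pool, 3e4, 76), 10)
  fit <- suppressWarnings(fit_pu_logistic(fm, 0.25, compute_se = FALSE))
  tab <- data.frame(key = fm$keys, ref = substr(fm$keys, 1, 1),
                    position = seq_along(fm$keys),
                    alt = substr(fm$keys, nchar(fm$keys), nchar(fm$keys)),
                    count_input = as.integer(fm$n_input),
                    count_sorted = as.integer(fm$n_sorted))
  attr(tab, "n_input") <- fm$n_U
  attr(tab, "n_sorted") <- fm$n_P
  class(tab) <- c("count_table", "data.frame")
  naive <- naive_log_enrichment(tab)
  ok <- fit$n_input + fit$n_sorted >= 100
  expect_gt(sum(ok), 20)
  expect_gte(mean(sign(fit$beta[ok]) == sign(naive$beta[match(fit$key, naive$key)][ok])),
             0.8)
})

test_that("naive log-enrichment: hand value, null, and sign contracts", {
  tab <- data.frame(key = c("A1V", "C2G", "D3E"),
                    ref = c("A", "C", "D"), position = 1:3,
                    alt = c("V", "G", "E"),
                    count_input = c(10L, 50L, 30L),
                    count_sorted = c(190L, 50L, 0L))
  attr(tab, "n_input") <- 1000L
  attr(tab, "n_sorted") <- 1000L
  class(tab) <- c("count_table", "data.frame")
  out <- naive_log_enrichment(tab, pseudocount = 0.5)
  expect_equal(out$beta[1L], log(190.5 / 1000.5) - log(10.5 / 1000.5),
               tolerance = 1e-12)
  expect_equal(out$beta[1L], 2.898, tolerance = 1e-3)
  expect_equal(out$beta[2L], 0)       # equal frequencies
  expect_lt(out$beta[3L], 0)          # absent from sorted pool
  expect_error(naive_log_enrichment(tab, 0), "pseudocount")
})

test_that("separable features are capped with a warning", {
  input <- c(rep(list("A1V"), 50), rep(list(character(0)), 50))   # input-only
  sorted <- c(rep(list("C2G"), 20), rep(list(character(0)), 80))  # sorted-only
  fm <- feature_matrix(input, sorted, 1)
  expect_warning(fit <- fit_pu_logistic(fm, 0.25, compute_se = FALSE),
                 "separable")
  expect_true(all(abs(fit$beta) <= 10 + 1e-8))
  expect_lt(fit$beta[fit$key == "A1V"], 0)
  expect_gt(fit$beta[fit$key == "C2G"], 0)
})

test_that("fit is deterministic given inputs and seed", {
  keys <- random_keys(20, seed = 80)
  lib <- keyed_library(keys, 300, seed = 81)
  lib <- assign_ground_truth(lib, setNames(rnorm(20), keys), 0.25, seed = 82)
  scr <- simulate_droplet_sort(lib, screen_config(seed = 83), 2e4)
  fm <- feature_matrix(pool_observations(lib, scr$input_pool, 5000, 84),
                       pool_observations(lib, scr$sorted_pool, 5000, 85), 10)
  f1 <- suppressWarnings(fit_pu_logistic(fm, 0.25, seed = 9))
  f2 <- suppressWarnings(fit_pu_logistic(fm, 0.25, seed = 9))
  expect_identical(f1$beta, f2$beta)
  expect_identical(attr(f1, "objective"), attr(f2, "objective"))
})

test_that("replicate concordance: identical, outlier, and 2-replicate cases", {
  keys <- random_keys(30, seed = 90)
  set.seed(90)
  base <- data.frame(key = keys, ref = substr(keys, 1, 1),
                     position = seq_along(keys),
                     alt = substr(keys, nchar(keys), nchar(keys)),
                     beta = rnorm(30, -1, 2), se = NA_real_,
                     n_input = 50L, n_sorted = 50L)
  class(base) <- c("coef_table", "data.frame")
  jitter_tab <- function(tab, sd, seed) {
    set.seed(seed); tab$beta <- tab$beta + rnorm(nrow(tab), 0, sd); tab
  }
  identical3 <- list(a = base, b = base, c = base)
  conc <- replicate_concordance(identical3)
  expect_true(all(abs(conc$correlations - 1) < 1e-12))
  expect_length(conc$excluded, 0L)

  permuted <- base
  set.seed(91); permuted$beta <- sample(permuted$beta)
  conc2 <- replicate_concordance(list(r1 = jitter_tab(base, 0.2, 1),
                                      r2 = jitter_tab(base, 0.2, 2),
                                      r3 = permuted))
  expect_identical(conc2$excluded, "r3")

  conc3 <- replicate_concordance(list(good = base, bad = permuted))
  expect_length(conc3$excluded, 0L)   # no exclusion possible with 2
  expect_error(replicate_concordance(list(base)), "at least 2")
})

test_that("replicate combination is a count-weighted mean", {
  t1 <- data.frame(key = c("A1V", "C2G"), ref = c("A", "C"), position = 1:2,
                   alt = c("V", "G"), beta = c(1, 2), se = NA_real_,
                   n_input = c(10L, 10L), n_sorted = c(10L, 10L))
  t2 <- t1; t2$beta <- c(3, 2); t2$n_input <- c(30L, 10L); t2$n_sorted <- c(30L, 10L)
  class(t1) <- class(t2) <- c("coef_table", "data.frame")
  comb <- combine_replicates(list(a = t1, b = t2))
  # A1V: (1*20 + 3*60) / 80 = 2.5; C2G: equal weights -> 2
  expect_equal(comb$beta[comb$key == "A1V"], 2.5)
  expect_equal(comb$beta[comb$key == "C2G"], 2)
  expect_equal(comb$n_input[comb$key == "A1V"], 40)
})
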