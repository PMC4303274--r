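test_that("weighted SSE is zero on noiseless model data and 1/n-weighted", {
  mix <- cam_mixture(tr2c_ref(), 5e-6)
  clean <- generate_titration(mix, noise = noise_model(0, 0), seed = 1)
  par <- list(L = 8.616e3, K_R = 1.979e-8, K_T = 6.241e-5)
  expect_equal(weighted_sse(par, clean), 0, tolerance = 1e-20)
  # single dataset: unweighted SSE times 1/n
  noisy <- generate_titration(mix, noise = noise_model(0.05, 0), seed = 2)
  ym <- lobe_saturation(tr2c_ref(), noisy$ca_free_molar)
  expect_equal(weighted_sse(par, noisy),
               sum((ym - noisy$saturation)^2) / nrow(noisy))
  # datasets of sizes 10 and 20 with equal per-point residuals contribute
  # equally under 1/n_k weighting
  d10 <- generate_titration(mix, n_points = 10, noise = noise_model(0, 0),
                            seed = 3)
  d20 <- generate_titration(mix, n_points = 20, noise = noise_model(0, 0),
                            seed = 3)
  d10$saturation <- d10$saturation + 0.01
  d20$saturation <- d20$saturation + 0.01
  expect_equal(weighted_sse(par, list(d10, d20)),
               2 * weighted_sse(par, d10), tolerance = 1e-12)
  expect_error(weighted_sse(par, tibble::tibble(ca_free_molar = 1e-6,
                                                saturation = 0.5)),
               "mixture")
})

test_that("short constrained fits return feasible, self-consistent results", {
  suite <- make_benchmark_suite(2)
  fit <- fit_tr2c(suite$fit, generations = 40, seed = 2)
  expect_true(fit$feasible)
  expect_lte(fit$par$K_R, 20e-9 * (1 + 1e-12))
  expect_gte(fit$par$K_T, 10e-6 * (1 - 1e-12))
  expect_lte(fit$par$c, 0.002 * (1 + 1e-12))
  # score self-consistency: stored score equals a fresh evaluation
  expect_equal(fit$score, weighted_sse(fit$par, suite$fit),
               tolerance = 1e-12)
  td <- tidy(fit)
  expect_true(all(c("L", "K_R", "K_T", "K_T_nav", "c") %in% td$term))
  gl <- glance(fit)
  expect_equal(gl$pop_size, 20)
  expect_true(gl$feasible)
  # determinism: same seed, same result
  fit2 <- fit_tr2c(suite$fit, generations = 40, seed = 2)
  expect_equal(fit$par, fit2$par)
})

test_that("validation datasets score comparably to fitting datasets", {
  suite <- make_benchmark_suite(1)
  fit <- fit_tr2c(suite$fit, generations = 150, seed = 1)
  per_point <- function(sets) weighted_sse(fit$par, sets) / length(sets)
  expect_lt(per_point(suite$validation), 3 * per_point(suite$fit))
  res <- fit_residuals(fit, suite$fit)
  expect_equal(nrow(res), sum(vapply(suite$fit, nrow, 0)))
  expect_equal(res$model - res$observed, res$residual)
  expect_lt(max(abs(res$residual)), 0.1)
})

test_that("the full protocol recovers noiseless generating parameters exactly", {
  suite <- make_benchmark_suite(seed = 1, sigma_Y = 0)
  fit <- fit_tr2c(suite$fit, seed = 1)
  truth <- suite$truth
  expect_lt(abs(fit$par$L / truth$params$L - 1), 0.01)
  expect_lt(abs(fit$par$K_R / truth$params$K_R - 1), 0.01)
  expect_lt(abs(fit$par$K_T / truth$params$K_T - 1), 0.01)
  expect_lt(abs(fit$par$K_T_nav / truth$K_T_nav - 1), 0.01)
  expect_lt(fit$score, 1e-10)
})

test_that("bootstrap resampling attaches uncertainty estimates", {
  suite <- make_benchmark_suite(seed = 4)
  fit <- fit_tr2c(suite$fit, generations = 15, seed = 4, polish = FALSE)
  bfit <- bootstrap_fit(fit, suite$fit, n_boot = 2, generations = 10,
                        seed = 4)
  expect_length(bfit$boot_sd, 5)  # L, K_R, K_T, K_T_nav, c (in decades)
  expect_true(all(is.finite(bfit$boot_sd)))
  expect_true("std.error" %in% names(tidy(bfit)))
})

test_that("N-lobe two-step procedure recovers noiseless parameters", {
  truth <- nlobe_ref()
  ca <- default_ca_grid(25)
  mutant <- tibble::tibble(ca_free_molar = ca,
                           saturation = ca / (truth$K_T + ca), weight = 1)
  nlobe <- generate_titration(cam_mixture(truth, 5e-6),
                              noise = noise_model(0, 0), seed = 1)
  fit <- fit_nlobe(mutant, nlobe, K_R_fixed = truth$K_R)
  expect_lt(abs(fit$par$K_T_N / truth$K_T - 1), 0.01)
  expect_lt(abs(fit$par$L_N / truth$L - 1), 0.01)
  expect_equal(fit$par$c_N, truth$K_R / fit$par$K_T_N)
  expect_false(fit$cooperative_mutant)
  # non-cooperative half-saturation sits at K_T_N
  expect_equal(half_saturation(function(x) x / (fit$par$K_T_N + x)),
               fit$par$K_T_N, tolerance = 1e-8)
})

test_that("N-lobe fit recovers L within a factor two under noise", {
  truth <- nlobe_ref()
  ca <- default_ca_grid(25)
  mutant <- tibble::tibble(ca_free_molar = ca,
                           saturation = ca / (truth$K_T + ca), weight = 1)
  nlobe <- generate_titration(cam_mixture(truth, 5e-6),
                              noise = noise_model(0.02, 0), seed = 4)
  fit <- fit_nlobe(mutant, nlobe, K_R_fixed = truth$K_R)
  expect_lt(abs(log10(fit$par$L_N / truth$L)), log10(2))
})

test_that("a cooperative mutant dataset raises the warning flag", {
  truth <- nlobe_ref()
  coop <- generate_titration(cam_mixture(truth, 5e-6),
                             noise = noise_model(0, 0), seed = 1)
  nl <- coop
  expect_warning(fit <- fit_nlobe(coop, nl, K_R_fixed = truth$K_R),
                 "cooperative")
  expect_true(fit$cooperative_mutant)
})

test_that("score landscape brackets the truth and ignores row order", {
  suite <- make_benchmark_suite(3)
  d <- suite$fit$alone
  surf <- score_landscape(d, K_T_fixed = 1e-4,
                          L_grid = 10^seq(2, 6, by = 0.25),
                          c_grid = 10^seq(-5, log10(0.002), length.out = 13))
  # minimum over the grid is no worse than the grid point nearest the truth
  truth_L <- 8.616e3
  truth_c <- 1.979e-8 / 1e-4
  near <- surf[which.min(abs(log10(surf$L / truth_L)) +
                           abs(log10(surf$c / truth_c))), ]
  expect_lte(min(surf$score), near$score)
  # row order of the dataset does not change the surface
  d_shuffled <- d[sample(nrow(d)), ]
  attr(d_shuffled, "mixture") <- attr(d, "mixture")
  surf2 <- score_landscape(d_shuffled, K_T_fixed = 1e-4,
                           L_grid = 10^seq(2, 6, by = 0.25),
                           c_grid = 10^seq(-5, log10(0.002), length.out = 13))
  expect_equal(surf$score, surf2$score, tolerance = 1e-12)
})

test_that("doubling or halving L shifts half-saturation less than the data scatter", {
  p <- tr2c_ref()
  h0 <- half_saturation(lobe_saturation_fun(p))
  for (fac in c(0.5, 2)) {
    h <- half_saturation(lobe_saturation_fun(
      lobe_params(fac * p$L, p$K_R, p$K_T)))
    expect_lte(abs(log10(h / h0)), log10(2))
  }
})
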