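test_that("mixture construction validates inputs", {
  p <- tr2c_ref()
  expect_error(cam_mixture(p, -1), "non-negative")
  expect_error(cam_mixture(p, 5e-6, list(cam_fixture("wff_lobe")),
                           numeric()), "one total")
  expect_error(cam_mixture(p, 5e-6,
                           list(cam_fixture("wff_lobe"), cam_fixture("wff_lobe")),
                           c(1e-6, 1e-6)), "duplicate")
  expect_error(cam_mixture(intact_ref(), 5e-6, list(cam_fixture("wff_lobe")),
                           1e-6), "intact_target_spec")
})

test_that("a non-binding target stays entirely free", {
  p <- tr2c_ref()
  ghost <- target_spec("ghost", 1e6, 1e6)  # effectively no binding
  mix <- cam_mixture(p, 1e-4, list(ghost), 1e-6)
  sol <- solve_free_concentrations(mix, c(1e-7, 1e-5))
  expect_equal(sol$free_ghost_molar, c(1e-6, 1e-6), tolerance = 1e-9)
})

test_that("a tight binder in excess protein is almost fully bound", {
  p <- tr2c_ref()
  tight <- target_spec("tight", 1e-9, 1e-10, stoichiometry = "per_molecule")
  mix <- cam_mixture(p, 1e-4, list(tight), 1e-6)
  sol <- solve_free_concentrations(mix, 1e-6)
  expect_lt(sol$free_tight_molar, 0.01 * 1e-6)
})

test_that("free-target solution matches the grid-scan oracle", {
  p <- tr2c_ref()
  set.seed(42)
  for (rep in 1:5) {
    spec <- target_spec("t", K_Rt = 10^stats::runif(1, -8, -6),
                        K_Tt = 10^stats::runif(1, -8, -6),
                        stoichiometry = sample(c("per_subunit",
                                                 "per_molecule"), 1))
    mix <- cam_mixture(p, 10^stats::runif(1, -6, -5), list(spec),
                       10^stats::runif(1, -6, -5))
    ca <- 10^stats::runif(1, -7, -5)
    sol <- solve_free_concentrations(mix, ca)
    expect_equal(sol$free_t_molar, oracle_free_target(mix, ca),
                 tolerance = 1e-6)
  }
})

test_that("mass conservation holds to high precision at every point", {
  p <- tr2c_ref()
  mix <- cam_mixture(p, 5e-6,
                     list(cam_fixture("wff_lobe"), cam_fixture("nav_fitted")),
                     c(7e-6, 7e-6), binding = "exclusive")
  sol <- solve_free_concentrations(mix, default_ca_grid(20))
  res <- conservation_residuals(mix, sol)
  expect_true(all(res$max_rel_residual < 1e-10))
  # exclusivity: total bound target never exceeds protein total
  bound_tot <- sol$bound_WFF_molar + sol$bound_NaV1.2IQp_molar
  expect_true(all(bound_tot <= mix$protein_total + 1e-15))
})

test_that("intact calmodulin without targets is the mean of its lobes", {
  ip <- intact_ref()
  cv <- titration_curve(cam_mixture(ip, 5e-6))
  ymean <- (lobe_saturation(ip$N, cv$ca_free_molar) +
              lobe_saturation(ip$C, cv$ca_free_molar)) / 2
  expect_equal(cv$saturation, ymean, tolerance = 1e-10)
})

test_that("titration curves are monotone for single-protein systems", {
  p <- tr2c_ref()
  for (mix in list(cam_mixture(p, 5e-6),
                   cam_mixture(p, 5e-6, list(cam_fixture("wff_lobe")), 7e-6),
                   cam_mixture(intact_ref(), 5e-6,
                               list(cam_fixture("wf10_intact")), 7e-6))) {
    cv <- titration_curve(mix)
    expect_true(all(diff(cv$saturation) > -1e-12))
  }
})

test_that("doubling the NaV peptide produces no further affinity shift", {
  p <- tr2c_ref()
  nav <- cam_fixture("nav_fitted")
  h14 <- half_saturation(curve_fun(cam_mixture(p, 5e-6, list(nav), 1.4 * 5e-6)))
  h28 <- half_saturation(curve_fun(cam_mixture(p, 5e-6, list(nav), 2.8 * 5e-6)))
  expect_lt(abs(log10(h28 / h14)), 0.05)
  # but the peptide itself produces a marked right shift
  h0 <- half_saturation(lobe_saturation_fun(p))
  expect_gt(h14 / h0, 2)
})

test_that("target direction follows the state-affinity ratio e", {
  p <- tr2c_ref()
  h0 <- half_saturation(lobe_saturation_fun(p))
  # neurogranin (e > 1, stabilises T): right shift
  h_ng <- half_saturation(curve_fun(
    cam_mixture(p, 40e-6, list(cam_fixture("ng")), 40e-6)))
  expect_gt(h_ng, h0)
  # CaMKII peptide (e < 1, stabilises R): left shift
  h_ck <- half_saturation(curve_fun(
    cam_mixture(p, 40e-6, list(cam_fixture("camkii")), 100e-6)))
  expect_lt(h_ck, h0)
})

test_that("competing targets nearly cancel in the three-component mixture", {
  p <- tr2c_ref()
  mix <- cam_fixture("fig_competition")
  h_mix <- half_saturation(curve_fun(mix))
  h0 <- half_saturation(lobe_saturation_fun(p))
  h_ng <- half_saturation(curve_fun(
    cam_mixture(p, 40e-6, list(cam_fixture("ng")), 40e-6)))
  h_ck <- half_saturation(curve_fun(
    cam_mixture(p, 40e-6, list(cam_fixture("camkii")), 100e-6)))
  expect_gt(h_mix, min(h_ng, h_ck))
  expect_lt(h_mix, max(h_ng, h_ck))
  expect_lt(h_mix / h0, 2)
  expect_gt(h_mix / h0, 0.5)
})

test_that("removing one competitor reduces to the single-target curve", {
  p <- tr2c_ref()
  grid <- default_ca_grid(15)
  one <- cam_mixture(p, 40e-6, list(cam_fixture("ng")), 40e-6,
                     binding = "exclusive")
  cv1 <- competing_targets_curve(one, grid)
  cv2 <- titration_curve(one, grid)
  expect_equal(cv1$saturation, cv2$saturation, tolerance = 1e-14)
})

test_that("intact calmodulin with WF10 yields a biphasic curve", {
  mi <- cam_mixture(intact_ref(), 5e-6, list(cam_fixture("wf10_intact")),
                    1.4 * 5e-6)
  cv <- titration_curve(mi, default_ca_grid(200))
  slope <- diff(cv$saturation) / diff(log10(cv$ca_free_molar))
  n_peaks <- sum(diff(sign(diff(slope))) == -2)
  expect_gte(n_peaks, 2)
  # the two phases are genuinely separated: the slope dips markedly
  # between the maxima (the target-free lobes only produce a shallow dip)
  peaks <- which(diff(sign(diff(slope))) == -2) + 1
  trough <- min(slope[peaks[1]:peaks[length(peaks)]])
  expect_lt(trough, 0.8 * min(slope[peaks[1]], slope[peaks[length(peaks)]]))
})

test_that("conserved-total calcium mode closes the calcium mass balance", {
  p <- tr2c_ref()
  mix <- cam_mixture(p, 5e-6, calcium_mode = "conserved_total")
  ca_tot <- c(2e-6, 1e-5, 1e-4)
  cv <- titration_curve(mix, ca_tot)
  bound <- 2 * 5e-6 * cv$saturation
  expect_equal(cv$ca_free_molar + bound, ca_tot, tolerance = 1e-9)
  expect_true(all(cv$ca_free_molar < ca_tot))
})

test_that("curve serialisation includes free-target columns", {
  p <- tr2c_ref()
  mix <- cam_mixture(p, 5e-6, list(cam_fixture("wff_lobe")), 7e-6)
  cv <- titration_curve(mix, default_ca_grid(10))
  expect_true("free_WFF_molar" %in% names(cv))
  path <- withr::local_tempfile(fileext = ".csv")
  write_curve_csv(cv, path)
  back <- utils::read.csv(path, comment.char = "#")
  expect_equal(back$saturation, cv$saturation, tolerance = 1e-12)
})
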