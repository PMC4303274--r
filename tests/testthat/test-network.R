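test_that("species enumeration counts follow the combinatorics", {
  ip <- intact_ref()
  expect_equal(nrow(enumerate_species(ip)), 64)
  expect_equal(nrow(enumerate_species(ip, list(cam_fixture("wff_intact")))),
               128)
  expect_equal(nrow(enumerate_species(
    ip, list(cam_fixture("wff_intact"), cam_fixture("wf10_intact")))), 192)
  # lobe: 2 conformations x 4 occupancy patterns
  expect_equal(nrow(enumerate_species(tr2c_ref())), 8)
  expect_error(enumerate_species(
    ip, list(cam_fixture("wff_intact"), cam_fixture("wff_intact"))),
    "duplicate")
})

test_that("species ids encode conformation, occupancy and target", {
  sp <- enumerate_species(intact_ref(), list(cam_fixture("wff_intact")))
  expect_true("CaM_TT_A0B0C0D0" %in% sp$id)
  expect_true("CaM_RT_A1B0C1D0_tWFF" %in% sp$id)
  expect_false(anyDuplicated(sp$id) > 0)
})

test_that("lobe network has the expected reactions and flip constants", {
  p <- tr2c_ref()
  net <- build_network(p)
  expect_equal(nrow(net$species), 8)
  expect_equal(nrow(net$reactions), 12)
  expect_equal(sum(net$reactions$type == "ca_binding"), 8)
  expect_equal(sum(net$reactions$type == "flip"), 4)
  re <- net$reactions
  # apo flip: [T]/[R] = L; one calcium bound scales it by c
  apo_flip <- re[re$type == "flip" & re$reactant == "Lobe_T_A0B0", ]
  expect_equal(1 / apo_flip$Keq, p$L, tolerance = 1e-12)
  one_flip <- re[re$type == "flip" & re$reactant == "Lobe_T_A1B0", ]
  expect_equal(1 / one_flip$Keq, p$L * p$c, tolerance = 1e-12)
  two_flip <- re[re$type == "flip" & re$reactant == "Lobe_T_A1B1", ]
  expect_equal(1 / two_flip$Keq, p$L * p$c^2, tolerance = 1e-12)
  # calcium binding constants are conformation-specific
  bindR <- re[re$type == "ca_binding" & re$reactant == "Lobe_R_A0B0", ]
  expect_equal(unique(1 / bindR$Keq), p$K_R)
})

test_that("every constructed network satisfies detailed balance", {
  for (net in list(build_network(tr2c_ref()),
                   build_network(intact_ref()),
                   build_network(intact_ref(),
                                 list(cam_fixture("wff_intact"),
                                      cam_fixture("wf10_intact"))))) {
    res <- wegscheider_residuals(net)
    expect_lt(max(res$log_residual), 1e-9)
    # network closed: potentials assignable from the apo state
    expect_silent(hemicam:::network_potentials(net))
  }
})

test_that("network equilibrium reproduces the closed-form lobe curve", {
  p <- tr2c_ref()
  net <- build_network(p)
  eq0 <- network_equilibrium(net, 5e-6, numeric(), 0)
  # no calcium, large L: at least L/(1+L) of protein in T
  fT <- sum(eq0$concentration[eq0$conf == "T"]) / 5e-6
  expect_gte(fT, p$L / (1 + p$L) - 1e-12)
  eqh <- network_equilibrium(net, 5e-6, numeric(), 1.836267e-6)
  expect_equal(attr(eqh, "saturation"), 0.5, tolerance = 1e-4)
  curve <- network_saturation_curve(net, 5e-6, ca_grid = default_ca_grid(20))
  expect_equal(curve$saturation,
               lobe_saturation(p, curve$ca_free_molar), tolerance = 1e-10)
})

test_that("lobe network with a target matches the analytic mass balance", {
  p <- tr2c_ref()
  wff <- cam_fixture("wff_lobe")  # per-molecule binding
  net <- build_network(p, list(wff))
  mix <- cam_mixture(p, 5e-6, list(wff), 7e-6)
  for (ca in c(1e-7, 1e-6, 1e-5)) {
    eq <- network_equilibrium(net, 5e-6, 7e-6, ca)
    sol <- solve_free_concentrations(mix, ca)
    expect_equal(attr(eq, "free_targets")[["WFF"]],
                 sol$free_WFF_molar, tolerance = 1e-6)
    expect_equal(attr(eq, "saturation"), sol$saturation, tolerance = 1e-8)
  }
})

test_that("intact network equilibrium matches the hemiconcerted closed form", {
  ip <- intact_ref()
  # (a) no targets: (Y_N + Y_C)/2 at 60 grid points
  net <- build_network(ip)
  grid <- default_ca_grid(60)
  curve <- network_saturation_curve(net, 5e-6, ca_grid = grid)
  ymean <- (lobe_saturation(ip$N, grid) + lobe_saturation(ip$C, grid)) / 2
  expect_lt(max(abs(curve$saturation - ymean)), 1e-8)
  # (b) whole-molecule target: 4-conformation partition function
  wf10 <- cam_fixture("wf10_intact")
  netT <- build_network(ip, list(wf10))
  mix <- cam_mixture(ip, 5e-6, list(wf10), 7e-6)
  sub <- default_ca_grid(12)
  sol <- solve_free_concentrations(mix, sub)
  for (i in seq_along(sub)) {
    eq <- network_equilibrium(netT, 5e-6, 7e-6, sub[i])
    expect_equal(attr(eq, "saturation"), sol$saturation[i], tolerance = 1e-8)
    expect_equal(attr(eq, "free_targets")[["WF10"]],
                 sol$free_WF10_molar[i], tolerance = 1e-6)
  }
})

test_that("intact-target affinity assignment follows the four rules", {
  spec <- assign_intact_target_affinities(600e-6, 0.1e-9, 735e-9,
                                          name = "WFF")
  ref <- cam_fixture("wff_intact")
  expect_equal(spec$K_RR, ref$K_RR)
  expect_equal(spec$K_RT, ref$K_RT)
  expect_equal(spec$K_TR, ref$K_TR)
  expect_equal(spec$K_TT, ref$K_TT)
  wf10 <- assign_intact_target_affinities(200e-6, 735e-9, 735e-9,
                                          name = "WF10")
  expect_equal(unclass(wf10)[c("K_RR", "K_RT", "K_TR", "K_TT")],
               unclass(cam_fixture("wf10_intact"))[c("K_RR", "K_RT",
                                                     "K_TR", "K_TT")])
  same <- assign_intact_target_affinities(1e-6, 1e-6, 1e-6)
  expect_true(all(unlist(same[c("K_RR", "K_RT", "K_TR", "K_TT")]) == 1e-6))
})

test_that("intact flip constants carry the target conformation ratio", {
  ip <- intact_ref()
  wff <- cam_fixture("wff_intact")
  net <- build_network(ip, list(wff))
  re <- net$reactions
  # C-lobe flip of apo, WFF-bound molecule: TT -> TR changes the target
  # dissociation constant from K_TT to K_TR
  fl <- re[re$type == "flip" & re$reactant == "CaM_TT_A0B0C0D0_tWFF" &
             re$product == "CaM_TR_A0B0C0D0_tWFF", ]
  expect_equal(1 / fl$Keq, ip$C$L * wff$K_TR / wff$K_TT, tolerance = 1e-12)
})

test_that("stoichiometry matrix balances every reaction", {
  net <- build_network(tr2c_ref(), list(cam_fixture("wff_lobe")))
  S <- stoichiometry_matrix(net)
  # every reaction converts exactly one protein species into another
  prot <- rownames(S) %in% net$species$id
  expect_true(all(colSums(S[prot, ] != 0) == 2))
  expect_true(all(colSums(S[prot, ]) == 0))
})
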