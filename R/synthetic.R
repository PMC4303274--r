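#' Transcribed parameter fixtures
#'
#' Registry of the fitted model parameters and literature peptide
#' affinities used throughout the package: the TR2C (C-lobe) and N-lobe
#' MWC parameters, the skMLCK peptides WFF and WF10 and the NaV1.2 IQ
#' peptide for the isolated lobe, the four-conformation affinities of WFF
#' and WF10 for intact calmodulin, the neurogranin and CaMKII peptides,
#' and the three-component competition scenario. Inequality affinities
#' from the literature are encoded at their bound value and flagged.
#'
#' @param name One of `"tr2c"`, `"nlobe"`, `"intact"`, `"wff_lobe"`,
#'   `"wf10_lobe"`, `"nav"`, `"nav_fitted"`, `"ng"`, `"camkii"`,
#'   `"wff_intact"`, `"wf10_intact"`, `"fig_competition"`.
#' @return The parameter bundle for `name` (see Details).
#' @details
#' * `tr2c`: list with `params` ([lobe_params()]: L = 8.616e3,
#'   K_R = 1.979e-8 M, K_T = 6.241e-5 M) and `K_T_nav` = 6.095e-10 M, the
#'   fitted T-state affinity of the NaV1.2 IQ peptide.
#' * `nlobe`: list with `params` (L = 3.226e5, K_R = 1.979e-8 M,
#'   K_T = 9.192e-5 M).
#' * `intact`: [intact_params()] combining the two.
#' * `wff_lobe`, `wf10_lobe`, `nav`, `nav_fitted`, `ng`, `camkii`:
#'   [target_spec()] objects.
#' * `wff_intact`, `wf10_intact`: [intact_target_spec()] objects.
#' * `fig_competition`: the 40 uM TR2C + 40 uM neurogranin + 100 uM CaMKII
#'   competition mixture as a [cam_mixture()].
#' @export
cam_fixture <- function(name) {
  tr2c <- lobe_params(L = 8.616e3, K_R = 1.979e-8, K_T = 6.241e-5)
  nlobe <- lobe_params(L = 3.226e5, K_R = 1.979e-8, K_T = 9.192e-5)
  switch(
    name,
    tr2c = list(params = tr2c, K_T_nav = 6.095e-10),
    nlobe = list(params = nlobe),
    intact = intact_params(N = nlobe, C = tr2c),
    wff_lobe = target_spec("WFF", K_Rt = 76e-9, K_Tt = 1.6e-6,
                           stoichiometry = "per_molecule"),
    wf10_lobe = target_spec("WF10", K_Rt = 712e-9, K_Tt = 1.1e-6,
                            stoichiometry = "per_molecule"),
    nav = target_spec("NaV1.2IQp", K_Rt = 75e-9, K_Tt = 25e-9,
                      stoichiometry = "per_molecule", bounds = TRUE),
    nav_fitted = target_spec("NaV1.2IQp", K_Rt = 75e-9, K_Tt = 6.095e-10,
                             stoichiometry = "per_molecule"),
    ng = target_spec("Ng", K_Rt = 1.05e-6, K_Tt = 43e-9,
                     stoichiometry = "per_molecule"),
    camkii = target_spec("CaMKII", K_Rt = 0.95e-6, K_Tt = 88e-6,
                         stoichiometry = "per_molecule"),
    wff_intact = intact_target_spec("WFF", K_RR = 0.1e-9, K_RT = 600e-6,
                                    K_TR = 735e-9, K_TT = 600e-6),
    wf10_intact = intact_target_spec("WF10", K_RR = 735e-9, K_RT = 200e-6,
                                     K_TR = 735e-9, K_TT = 200e-6),
    fig_competition = cam_mixture(
      tr2c, 40e-6,
      targets = list(cam_fixture("ng"), cam_fixture("camkii")),
      target_totals = c(40e-6, 100e-6), binding = "exclusive"),
    stop("unknown fixture: ", name)
  )
}

#' Noise model for synthetic titrations
#'
#' Additive Gaussian noise on the saturation axis plus optional Gaussian
#' jitter on the log10 free-calcium axis. Defaults carry y-noise only,
#' since free calcium in buffered titrations is known to high precision;
#' x-jitter is available for robustness studies emulating the roughly
#' factor-two half-saturation scatter across published curves.
#'
#' @param sigma_Y Standard deviation of additive saturation noise.
#' @param sigma_logCa Standard deviation of jitter on log10(calcium).
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(sigma_Y = 0.03, sigma_logCa = 0) {
  if (sigma_Y < 0 || sigma_logCa < 0) stop("noise sigmas must be >= 0")
  structure(list(sigma_Y = sigma_Y, sigma_logCa = sigma_logCa),
            class = "noise_model")
}

#' Generate a synthetic titration dataset
#'
#' Draws a noisy titration dataset from a model mixture: the clean curve
#' is computed by [titration_curve()], saturation noise is added, and the
#' reported calcium values optionally receive log-scale jitter. Output is
#' deterministic given the seed; with both sigmas zero the points lie
#' exactly on the model curve.
#'
#' @param mixture A [cam_mixture()] describing the generating model and
#'   composition.
#' @param n_points Number of titration points (>= 4), log-spaced.
#' @param ca_range Calcium range (molar).
#' @param noise A [noise_model()].
#' @param seed Integer seed; recorded in the provenance.
#' @return A tibble of class `cam_titration` with columns
#'   `ca_free_molar`, `saturation`, `weight`, carrying `mixture` and
#'   `provenance` attributes. Saturation is clipped to `[-0.1, 1.1]` and
#'   rows are sorted by calcium.
#' @export
generate_titration <- function(mixture, n_points = 25,
                               ca_range = c(1e-8, 1e-3),
                               noise = noise_model(), seed = 1) {
  stopifnot(inherits(mixture, "cam_mixture"))
  if (n_points < 4) stop("n_points must be at least 4")
  if (!inherits(noise, "noise_model")) stop("noise must be a noise_model()")
  grid <- default_ca_grid(n_points, ca_range)
  clean <- titration_curve(mixture, grid)
  withr::with_seed(seed, {
    ca_rep <- grid * 10^stats::rnorm(n_points, 0, noise$sigma_logCa)
    y <- clean$saturation + stats::rnorm(n_points, 0, noise$sigma_Y)
  })
  y <- pmin(pmax(y, -0.1), 1.1)
  out <- tibble::tibble(ca_free_molar = ca_rep, saturation = y,
                        weight = 1)
  out <- out[order(out$ca_free_molar), ]
  attr(out, "mixture") <- mixture
  attr(out, "provenance") <- list(
    seed = seed, n_points = n_points, ca_range = ca_range,
    noise = unclass(noise),
    generator = "hemicam::generate_titration")
  class(out) <- c("cam_titration", class(out))
  out
}

#' Benchmark suite of synthetic titration datasets
#'
#' Builds the five-dataset benchmark mirroring the fitting/validation
#' split of the TR2C protocol: three fitting datasets (TR2C alone, TR2C +
#' WFF at 1:1.4, TR2C + NaV1.2 IQ peptide at 1:1.4) and two validation
#' datasets (TR2C + WF10 at 1:1.4, TR2C + NaV1.2 IQ peptide at 1:2.8),
#' all generated from the TR2C reference parameters. Validation datasets
#' are never used for fitting.
#'
#' @param seed Integer seed; each dataset uses a distinct sub-seed.
#' @param n_points Points per dataset.
#' @param sigma_Y Additive saturation noise s.d.
#' @param protein_total Total TR2C concentration (molar). The source
#'   titrations only report molar ratios, so the absolute concentration is
#'   an explicit configuration choice, 5 uM by default.
#' @return A list with elements `fit` (3 datasets) and `validation`
#'   (2 datasets), each a named list of `cam_titration` tibbles, plus
#'   `truth` (the generating parameter bundle).
#' @export
make_benchmark_suite <- function(seed = 1, n_points = 25, sigma_Y = 0.02,
                                 protein_total = 5e-6) {
  fx <- cam_fixture("tr2c")
  wff <- cam_fixture("wff_lobe")
  nav <- cam_fixture("nav_fitted")
  wf10 <- cam_fixture("wf10_lobe")
  nm <- noise_model(sigma_Y = sigma_Y, sigma_logCa = 0)
  mk <- function(targets, ratio, sub) {
    mix <- cam_mixture(fx$params, protein_total,
                       targets = targets,
                       target_totals = ratio * protein_total)
    generate_titration(mix, n_points = n_points, noise = nm,
                       seed = seed * 1000L + sub)
  }
  list(
    fit = list(
      alone = mk(list(), numeric(), 1L),
      wff_1_1.4 = mk(list(wff), 1.4, 2L),
      nav_1_1.4 = mk(list(nav), 1.4, 3L)),
    validation = list(
      wf10_1_1.4 = mk(list(wf10), 1.4, 4L),
      nav_1_2.8 = mk(list(nav), 2.8, 5L)),
    truth = fx)
}
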