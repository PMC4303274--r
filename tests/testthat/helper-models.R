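# Shared model objects and independent oracles used across tests.

tr2c_ref <- function() cam_fixture("tr2c")$params
nlobe_ref <- function() cam_fixture("nlobe")$params
intact_ref <- function() cam_fixture("intact")

# Brute-force partition-function oracle for a two-identical-site lobe with
# independent per-site/per-molecule targets: enumerates conformation x
# calcium occupancy x target occupancy and sums statistical weights.
# Independent of the closed-form implementation.
oracle_lobe_saturation <- function(params, ca, targets = list(),
                                   target_free = numeric()) {
  conf_w <- function(conf) {
    K <- if (conf == "R") params$K_R else params$K_T
    base <- if (conf == "R") 1 else params$L
    tw <- 1
    for (i in seq_along(targets)) {
      Kt <- if (conf == "R") targets[[i]]$K_Rt else targets[[i]]$K_Tt
      m <- if (targets[[i]]$stoichiometry == "per_subunit") 2 else 1
      tw <- tw * (1 + target_free[i] / Kt)^m
    }
    # two identical sites: binomial occupancy weights
    z <- 0; bound <- 0
    for (n in 0:2) {
      w <- base * choose(2, n) * (ca / K)^n * tw
      z <- z + w
      bound <- bound + n * w
    }
    c(z = z, bound = bound)
  }
  tot <- conf_w("R") + conf_w("T")
  unname(tot["bound"] / (2 * tot["z"]))
}

# Closed-form half-saturation of the two-site MWC lobe (analytic root of
# Y = 1/2), used as the oracle for numeric bisection.
oracle_half_saturation <- function(params, L_eff = params$L) {
  params$K_R * sqrt((1 + L_eff) / (1 + L_eff * params$c^2))
}

# Analytic Hill-plane slope oracle, derived independently from
# Y/(1-Y) = alpha * A / B with A = (1+a) + Lc(1+ca), B = (1+a) + L(1+ca).
oracle_hill_at <- function(params, ca, L_eff = params$L) {
  a <- ca / params$K_R
  cc <- params$c
  A <- (1 + a) + L_eff * cc * (1 + cc * a)
  B <- (1 + a) + L_eff * (1 + cc * a)
  1 + a * (1 + L_eff * cc^2) / A - a * (1 + L_eff * cc) / B
}

# Grid-scan oracle for the free-target conservation root of a single-target
# lobe mixture: scans free target on a fine log grid and refines the sign
# change by bisection on the conservation residual.
oracle_free_target <- function(mix, ca) {
  tot <- mix$target_totals[1]
  g <- function(a) {
    ev <- hemicam:::mixture_eval(mix, ca, matrix(a, 1, 1))
    a + mix$protein_total * ev$bound[1, 1] - tot
  }
  grid <- c(0, 10^seq(log10(tot) - 12, log10(tot), length.out = 2000))
  vals <- vapply(grid, g, 0)
  i <- which(diff(sign(vals)) > 0)[1]
  lo <- grid[i]; hi <- grid[i + 1]
  for (k in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}
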