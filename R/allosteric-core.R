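#' Allosteric parameters of one calmodulin lobe
#'
#' A calmodulin lobe (the unit covered by the tryptic fragments TR1C and
#' TR2C) is modelled as a concerted two-state MWC molecule with two
#' identical calcium-binding sites. The lobe exists in a low-affinity T
#' state and a high-affinity R state in thermodynamic equilibrium.
#'
#' @param L Allosteric (isomerisation) constant, the ratio `[T0]/[R0]` of
#'   unliganded T- to R-state concentrations. Dimensionless, `> 0`.
#' @param K_R Calcium dissociation constant of the R state (molar).
#' @param K_T Calcium dissociation constant of the T state (molar). Must
#'   satisfy `K_R <= K_T` (R is the high-affinity state).
#' @return An object of class `lobe_params` with fields `L`, `K_R`, `K_T`
#'   and the derived affinity ratio `c = K_R / K_T` (so `0 < c <= 1`).
#' @examples
#' tr2c <- lobe_params(L = 8.616e3, K_R = 1.979e-8, K_T = 6.241e-5)
#' tr2c$c
#' @export
lobe_params <- function(L, K_R, K_T) {
  stopifnot(is.numeric(L), is.numeric(K_R), is.numeric(K_T),
            length(L) == 1, length(K_R) == 1, length(K_T) == 1)
  if (!is.finite(K_R) || !is.finite(K_T) || K_R <= 0 || K_T <= 0)
    stop("K_R and K_T must be positive finite concentrations (molar)")
  if (L < 0 || !is.finite(L))
    stop("L must be a non-negative finite number")
  if (K_R > K_T)
    stop("K_R must not exceed K_T: the R state is the high-affinity state")
  structure(list(L = L, K_R = K_R, K_T = K_T, c = K_R / K_T),
            class = "lobe_params")
}

#' @export
print.lobe_params <- function(x, ...) {
  cat("<lobe_params>  two-state MWC lobe (2 identical Ca sites)\n")
  cat(sprintf("  L   = %.4g\n  K_R = %.4g M\n  K_T = %.4g M\n  c   = %.4g\n",
              x$L, x$K_R, x$K_T, x$c))
  invisible(x)
}

#' Allosteric target of an isolated lobe
#'
#' A target (typically a calmodulin-binding peptide) binds both lobe
#' conformations, but with different dissociation constants. The ratio
#' `e = K_Rt / K_Tt` determines the direction of modulation: `e < 1`
#' stabilises the R state (left-shifts the calcium saturation curve),
#' `e > 1` stabilises the T state (right shift), and `e = 1` has no
#' allosteric effect.
#'
#' @param name Target identifier.
#' @param K_Rt Dissociation constant for the R state (molar).
#' @param K_Tt Dissociation constant for the T state (molar).
#' @param stoichiometry `"per_subunit"` (each of the two subunits carries a
#'   target site, the classical effector convention that squares the
#'   modulation factor) or `"per_molecule"` (one target per lobe, the
#'   convention used for intact calmodulin, which binds a single target).
#' @param bounds Logical; `TRUE` marks affinities that are literature upper
#'   bounds encoded at their bound value rather than measured constants.
#' @return An object of class `target_spec` with the derived ratio `e`.
#' @examples
#' wff <- target_spec("WFF", K_Rt = 76e-9, K_Tt = 1.6e-6)
#' wff$e  # < 1: stabilises R
#' @export
target_spec <- function(name, K_Rt, K_Tt,
                        stoichiometry = c("per_subunit", "per_molecule"),
                        bounds = FALSE) {
  stoichiometry <- match.arg(stoichiometry)
  if (!is.character(name) || length(name) != 1 || !nzchar(name))
    stop("target name must be a non-empty string")
  if (!is.finite(K_Rt) || !is.finite(K_Tt) || K_Rt <= 0 || K_Tt <= 0)
    stop("target dissociation constants must be positive and finite")
  structure(list(name = name, K_Rt = K_Rt, K_Tt = K_Tt,
                 e = K_Rt / K_Tt, stoichiometry = stoichiometry,
                 bounds = isTRUE(bounds)),
            class = "target_spec")
}

#' @export
print.target_spec <- function(x, ...) {
  cat(sprintf("<target_spec> %s  K_Rt = %.4g M, K_Tt = %.4g M, e = %.4g (%s)%s\n",
              x$name, x$K_Rt, x$K_Tt, x$e, x$stoichiometry,
              if (x$bounds) "  [bound values]" else ""))
  invisible(x)
}

target_stoich_exponent <- function(spec) {
  if (spec$stoichiometry == "per_subunit") 2L else 1L
}

#' Effective allosteric constant under target binding
#'
#' Bound targets shift the T/R equilibrium, which is equivalent to
#' replacing the allosteric constant `L` by an effective value
#' `L' = L * prod_t ((1 + gamma_t * e_t) / (1 + gamma_t))^exponent`,
#' where `gamma_t = [A_t]_free / K_Rt` is the reduced free target
#' concentration and `e_t = K_Rt / K_Tt`. With no targets `L' = L`; in the
#' saturating limit `gamma -> Inf` the factor per target tends to
#' `e^exponent`.
#'
#' @param L Allosteric constant (`> 0`).
#' @param targets A data frame (or list coercible to one) with columns
#'   `gamma` (reduced free target concentration, `>= 0`) and `e`
#'   (state-affinity ratio, `> 0`); one row per target. May be empty.
#' @param exponent Number of target sites that sense the conformational
#'   change: `2` for the per-subunit effector convention of an isolated
#'   lobe, `1` for per-molecule binding (intact calmodulin).
#' @return The effective allosteric constant `L'` (dimensionless).
#' @examples
#' effective_allosteric_constant(8616, tibble::tibble(gamma = 1, e = 0.0475))
#' @export
effective_allosteric_constant <- function(L, targets = NULL, exponent = 2) {
  if (!is.finite(L) || L <= 0) stop("L must be positive and finite")
  if (!exponent %in% c(1, 2)) stop("exponent must be 1 or 2")
  if (is.null(targets) || (is.data.frame(targets) && nrow(targets) == 0))
    return(L)
  targets <- as.data.frame(targets)
  gamma <- targets$gamma
  e <- targets$e
  if (any(!is.finite(e)) || any(e <= 0)) stop("all target e must be positive")
  if (any(gamma < 0)) stop("all gamma must be non-negative")
  fac <- ifelse(is.infinite(gamma), e, (1 + gamma * e) / (1 + gamma))
  L * prod(fac)^exponent
}

## Conformation-specific modulation factors (f_R, f_T) produced by a set of
## free targets. "independent" multiplies per-target site factors (matching
## the product form of L'); "exclusive" uses a single shared site so the
## factors are additive across targets.
target_factors <- function(targets, free, mode = c("independent", "exclusive")) {
  mode <- match.arg(mode)
  if (length(targets) == 0) return(list(fR = 1, fT = 1))
  gam <- vapply(seq_along(targets), function(i) free[i] / targets[[i]]$K_Rt, 0)
  ge <- vapply(seq_along(targets), function(i) free[i] / targets[[i]]$K_Tt, 0)
  if (mode == "independent") {
    m <- vapply(targets, target_stoich_exponent, 0L)
    list(fR = prod((1 + gam)^m), fT = prod((1 + ge)^m))
  } else {
    list(fR = 1 + sum(gam), fT = 1 + sum(ge))
  }
}

#' Fractional calcium saturation of an isolated lobe
#'
#' Closed-form saturation of a two-site, two-state MWC lobe at a given free
#' calcium concentration, optionally modulated by allosteric targets at
#' known *free* concentrations:
#' `Y = (a(1+a) + L' a c (1+a c)) / ((1+a)^2 + L' (1+a c)^2)` with
#' `a = ca_free / K_R`. Conversion from total to free target
#' concentrations is the job of [titration_curve()] and
#' [solve_free_concentrations()].
#'
#' @param params A [lobe_params()] object.
#' @param ca_free Free calcium concentration(s), molar. Vectorised;
#'   `Inf` is treated as the analytic saturating limit.
#' @param targets Optional list of [target_spec()] objects.
#' @param target_free Free concentrations (molar), one per target.
#' @return Fractional saturation in `[0, 1]`, same length as `ca_free`.
#' @examples
#' tr2c <- lobe_params(8.616e3, 1.979e-8, 6.241e-5)
#' lobe_saturation(tr2c, c(1e-7, 1.836e-6, 1e-4))
#' @export
lobe_saturation <- function(params, ca_free, targets = list(),
                            target_free = numeric()) {
  stopifnot(inherits(params, "lobe_params"))
  check_ca(ca_free)
  Lp <- lobe_effective_L(params, targets, target_free)
  mwc_saturation(Lp, params$c, ca_free / params$K_R)
}

lobe_effective_L <- function(params, targets, target_free,
                             mode = "independent") {
  if (length(targets) == 0) return(params$L)
  if (inherits(targets, "target_spec")) targets <- list(targets)
  if (length(target_free) != length(targets))
    stop("need one free concentration per target")
  if (any(target_free < 0)) stop("target concentrations must be non-negative")
  f <- target_factors(targets, target_free, mode)
  params$L * f$fT / f$fR
}

## Eq for Y as a function of effective L, c and reduced calcium alpha.
mwc_saturation <- function(Lp, c, alpha) {
  y <- ifelse(is.infinite(alpha), 1,
              (alpha * (1 + alpha) + Lp * alpha * c * (1 + alpha * c)) /
                ((1 + alpha)^2 + Lp * (1 + alpha * c)^2))
  ## L = 0 (pure R) reduces to alpha/(1+alpha); formula already covers it
  y
}

check_ca <- function(ca_free) {
  if (any(is.na(ca_free)) || any(ca_free < 0))
    stop("ca_free must be non-negative (molar)")
  invisible(TRUE)
}

#' Non-cooperative bounding curves of the pure T and R populations
#'
#' Any observed MWC saturation curve is a population mixture and must lie
#' between the hyperbolic binding curves of a pure T-state population and a
#' pure R-state population. These limit curves underpin the parameter
#' bounds used during fitting (upper bound on `K_R`, lower bound on `K_T`).
#'
#' @inheritParams lobe_saturation
#' @return A tibble with columns `ca_free_molar`, `Y_T`, `Y_R`.
#' @export
pure_state_curves <- function(params, ca_free) {
  stopifnot(inherits(params, "lobe_params"))
  check_ca(ca_free)
  hyper <- function(K) ifelse(is.infinite(ca_free), 1,
                              (ca_free / K) / (1 + ca_free / K))
  tibble::tibble(ca_free_molar = ca_free,
                 Y_T = hyper(params$K_T),
                 Y_R = hyper(params$K_R))
}

#' Fraction of lobes in the R conformation
#'
#' Population-shift diagnostic: the fraction of lobe molecules in the
#' high-affinity R state, `(1+a)^2 / ((1+a)^2 + L'(1+ac)^2)`. At zero
#' calcium this is `1/(1+L')`; it increases monotonically with calcium when
#' `c < 1` and saturates at `1/(1 + L'c^2)`.
#'
#' @inheritParams lobe_saturation
#' @return Fraction in `[0, 1]`, same length as `ca_free`.
#' @export
state_fraction_R <- function(params, ca_free, targets = list(),
                             target_free = numeric()) {
  stopifnot(inherits(params, "lobe_params"))
  check_ca(ca_free)
  Lp <- lobe_effective_L(params, targets, target_free)
  alpha <- ca_free / params$K_R
  cc <- params$c
  ifelse(is.infinite(alpha), 1 / (1 + Lp * cc^2),
         (1 + alpha)^2 / ((1 + alpha)^2 + Lp * (1 + alpha * cc)^2))
}

#' Saturation function of a lobe as a closure
#'
#' Convenience wrapper returning `Y(ca_free)` with targets held at fixed
#' free concentrations. The returned function carries the parameters as
#' attributes so that [hill_coefficient()] can use the exact analytic
#' Hill-plane slope instead of finite differences.
#'
#' @inheritParams lobe_saturation
#' @return A function of one argument (free calcium, molar).
#' @export
lobe_saturation_fun <- function(params, targets = list(),
                                target_free = numeric()) {
  stopifnot(inherits(params, "lobe_params"))
  Lp <- lobe_effective_L(params, targets, target_free)
  f <- function(ca_free) mwc_saturation(Lp, params$c, ca_free / params$K_R)
  attr(f, "mwc") <- list(L_eff = Lp, c = params$c, K_R = params$K_R)
  f
}

#' Analytic half-saturation point of a lobe
#'
#' For a two-identical-site MWC lobe the half-saturation point has the
#' closed form `alpha_half = sqrt((1 + L') / (1 + L' c^2))`, i.e.
#' `ca_half = K_R * alpha_half`.
#'
#' @inheritParams lobe_saturation
#' @return Free calcium at `Y = 0.5` (molar).
#' @examples
#' half_saturation_lobe(lobe_params(8.616e3, 1.979e-8, 6.241e-5))
#' @export
half_saturation_lobe <- function(params, targets = list(),
                                 target_free = numeric()) {
  Lp <- lobe_effective_L(params, targets, target_free)
  params$K_R * sqrt((1 + Lp) / (1 + Lp * params$c^2))
}
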