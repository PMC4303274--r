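#' Parameters of intact calmodulin (two independent lobes)
#'
#' Intact calmodulin is modelled hemiconcertedly: each lobe is a concerted
#' two-state unit, and the two lobes switch independently, giving four
#' whole-molecule conformations. Conformation labels follow the
#' convention that the first letter is the N lobe and the second the
#' C-lobe (`"RT"` = N lobe R, C-lobe T).
#'
#' @param N [lobe_params()] of the N-terminal lobe (sites A, B).
#' @param C [lobe_params()] of the C-terminal lobe (sites C, D).
#' @return An object of class `intact_params`.
#' @export
intact_params <- function(N, C) {
  stopifnot(inherits(N, "lobe_params"), inherits(C, "lobe_params"))
  structure(list(N = N, C = C), class = "intact_params")
}

#' @export
print.intact_params <- function(x, ...) {
  cat("<intact_params> hemiconcerted intact calmodulin\n")
  cat(sprintf("  N lobe: L = %.4g, K_R = %.4g M, K_T = %.4g M\n",
              x$N$L, x$N$K_R, x$N$K_T))
  cat(sprintf("  C lobe: L = %.4g, K_R = %.4g M, K_T = %.4g M\n",
              x$C$L, x$C$K_R, x$C$K_T))
  invisible(x)
}

#' Target affinities for the four conformations of intact calmodulin
#'
#' A whole-molecule target binds intact calmodulin with a dissociation
#' constant that depends on the joint conformation of the two lobes.
#'
#' @param name Target identifier.
#' @param K_RR,K_RT,K_TR,K_TT Dissociation constants (molar) for the four
#'   conformations (first letter N lobe, second C-lobe). Literature
#'   inequality bounds are encoded at their bound value.
#' @return An object of class `intact_target_spec`.
#' @export
intact_target_spec <- function(name, K_RR, K_RT, K_TR, K_TT) {
  ks <- c(K_RR, K_RT, K_TR, K_TT)
  if (any(!is.finite(ks)) || any(ks <= 0))
    stop("all four conformation affinities must be positive and finite")
  structure(list(name = name, K_RR = K_RR, K_RT = K_RT,
                 K_TR = K_TR, K_TT = K_TT),
            class = "intact_target_spec")
}

#' @export
print.intact_target_spec <- function(x, ...) {
  cat(sprintf(
    "<intact_target_spec> %s  K(RR) = %.4g, K(RT) = %.4g, K(TR) = %.4g, K(TT) = %.4g M\n",
    x$name, x$K_RR, x$K_RT, x$K_TR, x$K_TT))
  invisible(x)
}

#' Reaction mixture with total reagent concentrations
#'
#' Describes the composition of a titration experiment: a protein model
#' (lobe or intact calmodulin) at a total concentration, plus targets at
#' total concentrations. Calcium is by default clamped at its free value
#' (buffered titrations); `conserved_total` mode treats total calcium as
#' the known quantity instead.
#'
#' @param protein A [lobe_params()] or [intact_params()] object.
#' @param protein_total Total protein concentration (molar).
#' @param targets List of [target_spec()] (for a lobe) or
#'   [intact_target_spec()] (for intact calmodulin) objects.
#' @param target_totals Total target concentrations (molar), one per target.
#' @param calcium_mode `"clamped_free"` or `"conserved_total"`.
#' @param binding For lobe mixtures with several targets: `"independent"`
#'   (each target has its own site(s), matching the product form of the
#'   effective allosteric constant) or `"exclusive"` (targets compete for
#'   a single site per molecule). Intact calmodulin always binds targets
#'   exclusively, one per molecule.
#' @return An object of class `cam_mixture`.
#' @export
cam_mixture <- function(protein, protein_total, targets = list(),
                        target_totals = numeric(),
                        calcium_mode = c("clamped_free", "conserved_total"),
                        binding = c("independent", "exclusive")) {
  calcium_mode <- match.arg(calcium_mode)
  binding <- match.arg(binding)
  if (inherits(targets, "target_spec") || inherits(targets, "intact_target_spec"))
    targets <- list(targets)
  if (!is.numeric(protein_total) || protein_total < 0)
    stop("protein_total must be a non-negative concentration (molar)")
  if (length(targets) != length(target_totals))
    stop("need one total concentration per target")
  if (any(target_totals < 0)) stop("target totals must be non-negative")
  nm <- vapply(targets, function(t) t$name, "")
  if (anyDuplicated(nm)) stop("duplicate target names in mixture")
  intact <- inherits(protein, "intact_params")
  ok <- if (intact) "intact_target_spec" else "target_spec"
  if (!all(vapply(targets, inherits, TRUE, what = ok)))
    stop("targets must be ", ok, " objects for this protein")
  if (intact) binding <- "exclusive"  # one target per molecule
  structure(list(protein = protein, protein_total = protein_total,
                 targets = targets, target_totals = target_totals,
                 calcium_mode = calcium_mode, binding = binding),
            class = "cam_mixture")
}

#' @export
print.cam_mixture <- function(x, ...) {
  kind <- if (inherits(x$protein, "intact_params")) "intact CaM" else "lobe"
  cat(sprintf("<cam_mixture> %s at %.4g M, %d target(s), calcium %s\n",
              kind, x$protein_total, length(x$targets), x$calcium_mode))
  invisible(x)
}

n_sites <- function(protein) if (inherits(protein, "intact_params")) 4L else 2L

## ---- model evaluation at known FREE concentrations --------------------

## Calcium-dependent quantities that do not depend on free target
## concentrations, hoisted out of the mass-balance iteration.
mixture_precompute <- function(mix, ca) {
  if (inherits(mix$protein, "intact_params")) {
    sw <- intact_state_weights(mix$protein, ca)
    list(kind = "intact", w = sw$w, q = sw$q, n = length(ca),
         targets = mix$targets)
  } else {
    p <- mix$protein
    alpha <- ca / p$K_R
    list(kind = "lobe", alpha = alpha, c = p$c, L = p$L,
         wR0 = (1 + alpha)^2, wT0 = p$L * (1 + p$c * alpha)^2,
         n = length(ca), targets = mix$targets, binding = mix$binding)
  }
}

## Per-protein expected bound targets (matrix [n_ca x nt]) and saturation
## given free target concentrations. `free` is [n_ca x nt].
mixture_eval_pre <- function(pre, free) {
  nt <- length(pre$targets)
  if (pre$kind == "lobe") {
    if (nt == 0) {
      return(list(Y = mwc_saturation(pre$L, pre$c, pre$alpha),
                  bound = matrix(0, pre$n, 0)))
    }
    gam <- ge <- matrix(0, pre$n, nt)
    for (i in seq_len(nt)) {
      gam[, i] <- free[, i] / pre$targets[[i]]$K_Rt
      ge[, i] <- free[, i] / pre$targets[[i]]$K_Tt
    }
    bound <- matrix(0, pre$n, nt)
    if (pre$binding == "independent") {
      m <- vapply(pre$targets, target_stoich_exponent, 0L)
      fR <- fT <- rep(1, pre$n)
      for (i in seq_len(nt)) {
        fR <- fR * (1 + gam[, i])^m[i]
        fT <- fT * (1 + ge[, i])^m[i]
      }
      wR <- pre$wR0 * fR; wT <- pre$wT0 * fT
      Z <- wR + wT
      for (i in seq_len(nt))
        bound[, i] <- (m[i] * gam[, i] / (1 + gam[, i]) * wR +
                         m[i] * ge[, i] / (1 + ge[, i]) * wT) / Z
    } else {
      fR <- 1 + rowSums(gam); fT <- 1 + rowSums(ge)
      Z <- pre$wR0 * fR + pre$wT0 * fT
      for (i in seq_len(nt))
        bound[, i] <- (pre$wR0 * gam[, i] + pre$wT0 * ge[, i]) / Z
    }
    Lp <- pre$L * fT / fR
    list(Y = mwc_saturation(Lp, pre$c, pre$alpha), bound = bound)
  } else {
    intact_eval_pre(pre, free)
  }
}

intact_conformations <- c("TT", "TR", "RT", "RR")

## Conformation weights (relative to apo-TT / L_N L_C) and per-state bound
## calcium for intact CaM. Returns list of matrices [n_ca x 4].
intact_state_weights <- function(p, ca) {
  wN <- cbind(T = p$N$L * (1 + ca / p$N$K_T)^2, R = (1 + ca / p$N$K_R)^2)
  wC <- cbind(T = p$C$L * (1 + ca / p$C$K_T)^2, R = (1 + ca / p$C$K_R)^2)
  qN <- cbind(T = 2 * (ca / p$N$K_T) / (1 + ca / p$N$K_T),
              R = 2 * (ca / p$N$K_R) / (1 + ca / p$N$K_R))
  qC <- cbind(T = 2 * (ca / p$C$K_T) / (1 + ca / p$C$K_T),
              R = 2 * (ca / p$C$K_R) / (1 + ca / p$C$K_R))
  confN <- substr(intact_conformations, 1, 1)
  confC <- substr(intact_conformations, 2, 2)
  w <- sapply(1:4, function(s) wN[, confN[s]] * wC[, confC[s]])
  q <- sapply(1:4, function(s) qN[, confN[s]] + qC[, confC[s]])
  list(w = matrix(w, nrow = length(ca)), q = matrix(q, nrow = length(ca)))
}

intact_eval_pre <- function(pre, free) {
  nt <- length(pre$targets)
  n <- pre$n
  if (nt == 0) {
    Z <- rowSums(pre$w)
    return(list(Y = rowSums(pre$w * pre$q) / (4 * Z),
                bound = matrix(0, n, 0)))
  }
  ## gamma[, s, t] = free_t / K_conf(s, t); exclusive single-site binding
  gsum <- matrix(0, n, 4)
  gt <- array(0, c(n, 4, nt))
  for (i in seq_len(nt)) {
    Ks <- unlist(pre$targets[[i]][paste0("K_", intact_conformations)])
    for (s in 1:4) gt[, s, i] <- free[, i] / Ks[s]
    gsum <- gsum + gt[, , i]
  }
  wocc <- pre$w * (1 + gsum)
  Z <- rowSums(wocc)
  bound <- sapply(seq_len(nt), function(i) rowSums(pre$w * gt[, , i]) / Z)
  list(Y = rowSums(wocc * pre$q) / (4 * Z),
       bound = matrix(bound, nrow = n))
}

mixture_eval <- function(mix, ca, free) {
  mixture_eval_pre(mixture_precompute(mix, ca), free)
}

## ---- mass balance: totals -> free -------------------------------------

## Vectorised over the calcium grid: free target concentrations satisfying
## total = free + protein_total * bound_per_protein(free). Gauss-Seidel
## sweeps over targets, bisection in each (binding is competitive and
## monotone, so each 1-D problem has a unique root).
solve_free_targets <- function(mix, ca, rel_tol = 1e-12, max_sweep = 60) {
  nt <- length(mix$targets)
  nca <- length(ca)
  free <- matrix(rep(mix$target_totals, each = nca), nrow = nca)
  if (nt == 0 || mix$protein_total == 0 || all(mix$target_totals == 0))
    return(free)
  P <- mix$protein_total
  tot <- mix$target_totals
  pre <- mixture_precompute(mix, ca)
  for (sweep in seq_len(max_sweep)) {
    for (i in seq_len(nt)) {
      if (tot[i] == 0) next
      lo <- rep(0, nca); hi <- rep(tot[i], nca)
      for (it in 1:62) {
        mid <- (lo + hi) / 2
        free[, i] <- mid
        b <- mixture_eval_pre(pre, free)$bound[, i]
        g <- mid + P * b - tot[i]
        up <- g > 0
        hi[up] <- mid[up]
        lo[!up] <- mid[!up]
      }
      free[, i] <- (lo + hi) / 2
    }
    ev <- mixture_eval_pre(pre, free)
    res <- vapply(seq_len(nt), function(i) {
      if (tot[i] == 0) return(0)
      max(abs(free[, i] + P * ev$bound[, i] - tot[i]) / tot[i])
    }, 0)
    if (max(res) < rel_tol) break
  }
  if (max(res) >= rel_tol)
    stop(sprintf(
      "free-target solver did not converge: max relative residual %.3g after %d sweeps",
      max(res), max_sweep))
  free
}

#' Solve free concentrations from totals at given free calcium
#'
#' Solves the mass-balance (conservation) equations of a mixture: each
#' target's total concentration equals its free concentration plus the
#' amount bound to the protein, computed from the model's binding
#' polynomial at the solved free values. Calcium is clamped at its free
#' value (the buffered-titration convention). Roots are found by monotone
#' vectorised bisection; relative conservation residuals are below 1e-10.
#'
#' @param mixture A [cam_mixture()].
#' @param ca_free Free calcium concentration(s), molar.
#' @return A tibble with one row per calcium point: `ca_free_molar`,
#'   `saturation`, and per-target columns `free_<name>_molar` and
#'   `bound_<name>_molar`.
#' @export
solve_free_concentrations <- function(mixture, ca_free) {
  stopifnot(inherits(mixture, "cam_mixture"))
  check_ca(ca_free)
  free <- solve_free_targets(mixture, ca_free)
  ev <- mixture_eval(mixture, ca_free, free)
  out <- tibble::tibble(ca_free_molar = ca_free, saturation = ev$Y)
  for (i in seq_along(mixture$targets)) {
    nm <- mixture$targets[[i]]$name
    out[[paste0("free_", nm, "_molar")]] <- free[, i]
    out[[paste0("bound_", nm, "_molar")]] <-
      mixture$protein_total * ev$bound[, i]
  }
  out
}

#' Titration curve of a mixture
#'
#' Fractional calcium saturation over a calcium grid, solving the target
#' mass balance at each point. For intact calmodulin with no targets the
#' curve equals the mean of the two independent lobe curves by
#' construction.
#'
#' @param mixture A [cam_mixture()].
#' @param ca_grid Calcium grid (molar), default [default_ca_grid()]. In
#'   `conserved_total` mode the grid is interpreted as total calcium.
#' @return A tibble of class `cam_curve` with `ca_free_molar`,
#'   `saturation`, and `free_<target>_molar` columns; the mixture is kept
#'   as an attribute.
#' @examples
#' tr2c <- lobe_params(8.616e3, 1.979e-8, 6.241e-5)
#' titration_curve(cam_mixture(tr2c, 5e-6))
#' @export
titration_curve <- function(mixture, ca_grid = default_ca_grid()) {
  stopifnot(inherits(mixture, "cam_mixture"))
  if (mixture$calcium_mode == "conserved_total") {
    ca_free <- vapply(ca_grid, function(ct) solve_free_calcium(mixture, ct), 0)
  } else {
    ca_free <- ca_grid
  }
  sol <- solve_free_concentrations(
    within_mode(mixture, "clamped_free"), ca_free)
  out <- sol[, c("ca_free_molar", "saturation",
                 grep("^free_", names(sol), value = TRUE)), drop = FALSE]
  if (mixture$calcium_mode == "conserved_total")
    out$ca_total_molar <- ca_grid
  attr(out, "mixture") <- mixture
  class(out) <- c("cam_curve", class(out))
  out
}

within_mode <- function(mix, mode) { mix$calcium_mode <- mode; mix }

#' Titration curve under competing targets
#'
#' Saturation curve of a mixture in which two or more targets compete for
#' a single binding site per protein molecule (mutually exclusive
#' binding). With a single target this reduces exactly to
#' [titration_curve()] with per-molecule stoichiometry.
#'
#' @inheritParams titration_curve
#' @return A `cam_curve` tibble.
#' @export
competing_targets_curve <- function(mixture, ca_grid = default_ca_grid()) {
  stopifnot(inherits(mixture, "cam_mixture"))
  mixture$binding <- "exclusive"
  titration_curve(mixture, ca_grid)
}

#' Saturation function of a mixture as a closure
#'
#' Returns `Y(ca_free)` with the target mass balance solved at each call.
#' For a target-free lobe mixture the closure carries the analytic MWC
#' attributes, so [hill_coefficient()] uses the exact derivative.
#'
#' @param mixture A [cam_mixture()].
#' @return Function of free calcium (molar).
#' @export
curve_fun <- function(mixture) {
  stopifnot(inherits(mixture, "cam_mixture"))
  if (length(mixture$targets) == 0 && !inherits(mixture$protein, "intact_params"))
    return(lobe_saturation_fun(mixture$protein))
  function(ca_free) {
    free <- solve_free_targets(mixture, ca_free)
    mixture_eval(mixture, ca_free, free)$Y
  }
}

## Free calcium from a conserved total: ca_total = ca_free + bound Ca.
solve_free_calcium <- function(mix, ca_total, rel_tol = 1e-12) {
  if (ca_total == 0) return(0)
  ns <- n_sites(mix$protein)
  g <- function(ca) {
    free <- solve_free_targets(mix, ca)
    y <- mixture_eval(mix, ca, free)$Y
    ca + ns * mix$protein_total * y - ca_total
  }
  lo <- 0; hi <- ca_total
  for (it in 1:80) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) hi <- mid else lo <- mid
    if ((hi - lo) < rel_tol * ca_total) break
  }
  (lo + hi) / 2
}

#' Mass-conservation residuals of a solved mixture
#'
#' Diagnostic: recomputes, for each target, `|free + bound - total|/total`
#' at every calcium point of a solution from
#' [solve_free_concentrations()].
#'
#' @param mixture The [cam_mixture()] that produced the solution.
#' @param solution Tibble returned by [solve_free_concentrations()].
#' @return A tibble with columns `target` and `max_rel_residual`.
#' @export
conservation_residuals <- function(mixture, solution) {
  purrr::map_dfr(seq_along(mixture$targets), function(i) {
    nm <- mixture$targets[[i]]$name
    tot <- mixture$target_totals[i]
    res <- if (tot == 0) 0 else
      max(abs(solution[[paste0("free_", nm, "_molar")]] +
                solution[[paste0("bound_", nm, "_molar")]] - tot) / tot)
    tibble::tibble(target = nm, max_rel_residual = res)
  })
}
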