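#' Weighted sum of squared residuals over titration datasets
#'
#' Score function of the fitting protocol:
#' `S = sum_k w_k sum_i (Y_model - Y_obs)^2`, with default weights
#' `w_k = 1/n_k` so that datasets with different point counts contribute
#' comparably. The model curve for each dataset is rebuilt from the
#' dataset's own composition (protein total, targets and ratios) with the
#' candidate lobe parameters substituted; target mass balance is solved
#' from totals at every point.
#'
#' @param par Named list or vector with elements `L`, `K_R`, `K_T` and
#'   optionally `K_T_nav` (T-state affinity of the NaV1.2 IQ peptide,
#'   substituted into any target named `"NaV1.2IQp"`).
#' @param datasets A `cam_titration` tibble or list of them; each must
#'   carry its composition as a `mixture` attribute.
#' @param weights Optional per-dataset weights (default `1/n_k`).
#' @return The score `S` (dimensionless).
#' @export
weighted_sse <- function(par, datasets, weights = NULL) {
  datasets <- as_dataset_list(datasets)
  par <- as.list(par)
  if (is.null(weights)) weights <- 1 / vapply(datasets, nrow, 0)
  if (length(weights) != length(datasets))
    stop("need one weight per dataset")
  s <- 0
  for (k in seq_along(datasets)) {
    d <- datasets[[k]]
    ym <- model_saturation_for(par, d)
    s <- s + weights[k] * sum((ym - d$saturation)^2)
  }
  s
}

as_dataset_list <- function(datasets) {
  if (is.data.frame(datasets)) datasets <- list(datasets)
  for (d in datasets) {
    if (is.null(attr(d, "mixture")))
      stop("every dataset must carry its composition as a 'mixture' attribute")
  }
  datasets
}

## Model saturation at the dataset's calcium points, with candidate lobe
## parameters (and optional NaV T-state affinity) substituted into the
## dataset's own composition.
model_saturation_for <- function(par, dataset) {
  mix <- attr(dataset, "mixture")
  if (inherits(mix$protein, "intact_params"))
    stop("fitting operates on lobe datasets")
  mix$protein <- lobe_params(par$L, par$K_R, par$K_T)
  if (!is.null(par$K_T_nav)) {
    for (i in seq_along(mix$targets)) {
      if (mix$targets[[i]]$name == "NaV1.2IQp") {
        t <- mix$targets[[i]]
        mix$targets[[i]] <- target_spec(t$name, K_Rt = t$K_Rt,
                                        K_Tt = par$K_T_nav,
                                        stoichiometry = t$stoichiometry)
      }
    }
  }
  ca <- dataset$ca_free_molar
  free <- solve_free_targets(mix, ca)
  mixture_eval(mix, ca, free)$Y
}

default_tr2c_bounds <- function() {
  list(L = c(1, 1e8), K_R = c(1e-10, 20e-9), K_T = c(1e-5, 1e-3),
       K_T_nav = c(1e-11, 25e-9))
}

default_tr2c_constraints <- function() {
  list(K_R_max = 20e-9, K_T_min = 10e-6, c_max = 0.002)
}

constraint_violation <- function(par, constraints) {
  v <- 0
  if (!is.null(constraints$K_R_max))
    v <- v + max(0, log10(par$K_R / constraints$K_R_max))
  if (!is.null(constraints$K_T_min))
    v <- v + max(0, log10(constraints$K_T_min / par$K_T))
  if (!is.null(constraints$c_max))
    v <- v + max(0, log10((par$K_R / par$K_T) / constraints$c_max))
  v
}

vec_to_par <- function(x, names) {
  p <- as.list(10^x)
  names(p) <- names
  p
}

## Feasibility-first comparison: feasible beats infeasible; among feasible,
## lower score wins, ties broken by lower L (deterministic reporting);
## among infeasible, lower violation wins.
better_than <- function(a, b) {
  if ((a$v == 0) != (b$v == 0)) return(a$v == 0)
  if (a$v > 0) return(a$v < b$v)
  if (a$s != b$s) return(a$s < b$s)
  a$x[1] < b$x[1]
}

#' Constrained simultaneous fit of the TR2C datasets
#'
#' The core fitting protocol: a seeded population-based global search
#' (genetic algorithm with feasibility-first tournament ranking, a
#' stand-in for stochastic-ranking constraint handling) over the four
#' free parameters `L`, `K_R`, `K_T` and `K_T_nav` in log space,
#' minimising the weighted sum of squared residuals over the three
#' fitting datasets (TR2C alone, +WFF 1:1.4, +NaV 1:1.4) simultaneously.
#' Peptide affinities other than `K_T_nav` are fixed at their values in
#' each dataset's composition (the WFF constants are known; the NaV
#' R-state affinity is fixed at its literature upper bound). Active
#' constraints: `K_R <= 20 nM`, `K_T >= 10 uM`, `c = K_R/K_T <= 0.002`,
#' derived from the pure-state bounding curves. The best feasible point
#' is polished by Nelder-Mead inside the feasible region.
#'
#' @param datasets List of (typically three) `cam_titration` datasets.
#' @param constraints List with `K_R_max`, `K_T_min`, `c_max`.
#' @param bounds Named list of `c(lower, upper)` box bounds (natural
#'   units) for `L`, `K_R`, `K_T`, `K_T_nav`; the search runs in log10
#'   space within them.
#' @param pop_size Population size (default 20).
#' @param generations Number of generations (default 1000).
#' @param seed Integer seed for the whole search.
#' @param polish Run the deterministic ridge-ladder Nelder-Mead polish
#'   after the population search (recommended; disable only for cheap
#'   replicate fits such as bootstrap resamples).
#' @param fit_nav Whether `K_T_nav` is a free parameter (disable for
#'   datasets without the NaV peptide).
#' @param weights Optional per-dataset weights, default `1/n_k`.
#' @return A `cam_fit` object: `par` (named list, natural units), `score`,
#'   `feasible`, `constraints`, `seed`, `pop_size`, `generations`,
#'   `n_eval`, `history` (best score trace).
#' @export
fit_tr2c <- function(datasets,
                     constraints = default_tr2c_constraints(),
                     bounds = default_tr2c_bounds(),
                     pop_size = 20, generations = 1000, seed = 1,
                     polish = TRUE, fit_nav = TRUE, weights = NULL) {
  datasets <- as_dataset_list(datasets)
  par_names <- c("L", "K_R", "K_T", if (fit_nav) "K_T_nav")
  bounds <- bounds[par_names]
  if (any(vapply(bounds, is.null, TRUE))) stop("missing bounds")
  lo <- log10(vapply(bounds, `[`, 0, 1))
  hi <- log10(vapply(bounds, `[`, 0, 2))
  if (any(lo >= hi)) stop("infeasible bounds")
  objective <- function(x) {
    p <- vec_to_par(x, par_names)
    list(x = x, s = weighted_sse(p, datasets, weights),
         v = constraint_violation(p, constraints))
  }
  n_eval <- 0L
  history <- numeric()
  best <- NULL
  withr::with_seed(seed, {
    pop <- lapply(seq_len(pop_size), function(i) {
      objective(lo + stats::runif(length(lo)) * (hi - lo))
    })
    n_eval <- n_eval + pop_size
    for (p in pop) if (is.null(best) || better_than(p, best)) best <- p
    width <- hi - lo
    for (gen in seq_len(generations)) {
      sigma <- 0.25 * (0.02 / 0.25)^((gen - 1) / max(1, generations - 1))
      tournament <- function() {
        i <- sample.int(pop_size, 2)
        if (better_than(pop[[i[1]]], pop[[i[2]]])) pop[[i[1]]] else pop[[i[2]]]
      }
      offspring <- lapply(seq_len(pop_size - 1), function(j) {
        p1 <- tournament(); p2 <- tournament()
        u <- stats::runif(length(lo), -0.25, 1.25)  # BLX blend
        x <- p1$x + u * (p2$x - p1$x)
        x <- x + stats::rnorm(length(lo), 0, sigma * width)
        objective(pmin(pmax(x, lo), hi))
      })
      n_eval <- n_eval + length(offspring)
      pop <- c(list(best), offspring)  # elitism
      for (p in pop) if (better_than(p, best)) best <- p
      if (gen %% 50 == 0) history <- c(history, best$s)
    }
    ## local polish, barrier keeps iterates feasible
    pen <- function(x) {
      o <- objective(pmin(pmax(x, lo), hi))
      if (o$v > 0) return(o$s + 1e3 * (1 + o$v))
      o$s
    }
    polish_after <- polish
    polish <- function(x0, maxit) {
      opt <- stats::optim(x0, pen, method = "Nelder-Mead",
                          control = list(reltol = 1e-12, maxit = maxit))
      n_eval <<- n_eval + opt$counts[1]
      objective(pmin(pmax(opt$par, lo), hi))
    }
    if (best$v == 0 && polish_after) {
      cand <- polish(best$x, 600)
      if (better_than(cand, best)) best <- cand
      ## the (L, K_R) plane has a long flat ridge (L -> lambda L,
      ## K_R -> K_R / sqrt(lambda) preserves the curves almost exactly);
      ## a single local descent can stall far along it, so restart the
      ## polish from a deterministic ladder of ridge-shifted points
      for (Ltry in seq(lo[1] + 0.25, hi[1] - 0.25, by = 1)) {
        x0 <- best$x
        dL <- Ltry - x0[1]
        x0[1] <- x0[1] + dL
        x0[2] <- x0[2] - dL / 2
        x0 <- pmin(pmax(x0, lo), hi)
        st <- objective(x0)
        if (st$v > 0) next
        cand <- polish(x0, 600)
        if (better_than(cand, best)) best <- cand
      }
      cand <- polish(best$x, 2000)
      if (better_than(cand, best)) best <- cand
    }
  })
  if (best$v > 0)
    stop("no feasible parameter set found: constraint violation ", best$v)
  par <- vec_to_par(best$x, par_names)
  par$c <- par$K_R / par$K_T
  score <- weighted_sse(par, datasets, weights)
  new_cam_fit(par = par, score = score, feasible = TRUE,
              constraints = constraints, seed = seed,
              pop_size = pop_size, generations = generations,
              n_eval = as.integer(n_eval), history = history,
              method = "GA + Nelder-Mead polish")
}

new_cam_fit <- function(...) structure(list(...), class = "cam_fit")

#' @export
print.cam_fit <- function(x, ...) {
  cat(sprintf("<cam_fit> %s  score = %.6g  (seed %s, %s evals)\n",
              x$method, x$score, x$seed, x$n_eval))
  for (nm in names(x$par))
    cat(sprintf("  %-8s = %.4g\n", nm, x$par[[nm]]))
  invisible(x)
}

#' @export
tidy.cam_fit <- function(x, ...) {
  out <- tibble::tibble(term = names(x$par),
                        estimate = unlist(x$par),
                        unit = ifelse(names(x$par) %in% c("L", "c"), "", "M"))
  if (!is.null(x$boot_sd))
    out$std.error <- x$boot_sd[out$term]
  out
}

#' @export
glance.cam_fit <- function(x, ...) {
  tibble::tibble(score = x$score, feasible = x$feasible,
                 pop_size = x$pop_size %||% NA_integer_,
                 generations = x$generations %||% NA_integer_,
                 n_eval = x$n_eval, seed = x$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Two-step parameterisation of the N-lobe
#'
#' Step 1 fits the T-state calcium affinity `K_T_N` on the titration of a
#' conformationally locked (disulfide-constrained, closed) mutant with a
#' non-cooperative model of two identical sites, `Y = x / (K + x)`; a
#' warning flag is raised if that dataset looks cooperative (Hill fit
#' n > 1.2). Step 2 fixes the R-state affinity at the value shared with
#' the C-lobe and fits the allosteric constant `L_N` on the N-lobe
#' titration, with `c_N = K_R / K_T_N` implied.
#'
#' @param mutant_dataset Titration of the locked (pure T) mutant.
#' @param nlobe_dataset Titration of the wild-type isolated N-lobe.
#' @param K_R_fixed R-state calcium affinity (molar), shared with the
#'   C-lobe fit.
#' @param L_bounds Search range for `L_N`.
#' @return A `cam_fit` with parameters `L_N`, `K_T_N`, `K_R` and `c_N`,
#'   and a `cooperative_mutant` warning flag.
#' @export
fit_nlobe <- function(mutant_dataset, nlobe_dataset, K_R_fixed,
                      L_bounds = c(1, 1e8)) {
  x <- mutant_dataset$ca_free_molar
  y <- mutant_dataset$saturation
  sse1 <- function(lk) sum((y - x / (10^lk + x))^2)
  o1 <- stats::optimize(sse1, lower = -9, upper = -1, tol = 1e-12)
  K_T_N <- 10^o1$minimum
  coop_flag <- FALSE
  hf <- tryCatch(fit_hill(mutant_dataset), error = function(e) NULL)
  if (!is.null(hf) && hf$n_H > 1.2) {
    coop_flag <- TRUE
    warning("mutant dataset appears cooperative (Hill n = ",
            round(hf$n_H, 2), "); locked-state fit may be biased")
  }
  params_at <- function(L) lobe_params(L, K_R_fixed, K_T_N)
  x2 <- nlobe_dataset$ca_free_molar
  y2 <- nlobe_dataset$saturation
  sse2 <- function(lL) sum((y2 - lobe_saturation(params_at(10^lL), x2))^2)
  o2 <- stats::optimize(sse2, lower = log10(L_bounds[1]),
                        upper = log10(L_bounds[2]), tol = 1e-12)
  L_N <- 10^o2$minimum
  score <- o1$objective / length(x) + o2$objective / length(x2)
  new_cam_fit(par = list(L_N = L_N, K_T_N = K_T_N, K_R = K_R_fixed,
                         c_N = K_R_fixed / K_T_N),
              score = score, feasible = TRUE,
              constraints = list(), seed = NA_integer_,
              n_eval = NA_integer_, history = numeric(),
              cooperative_mutant = coop_flag,
              method = "two-step N-lobe (locked mutant, then L)")
}

#' Score landscape over the (L, c) plane
#'
#' With the T-state affinity fixed, the lobe model reduces to the
#' classical MWC parameters `L` and `c` (with `K_R = c * K_T` implied).
#' This computes the weighted SSE score on a log-spaced grid — the
#' identifiability diagnostic: a target-free titration alone produces a
#' long flat valley of near-optimal `(L, c)` pairs, which the target
#' datasets collapse to a compact region.
#'
#' @param datasets A dataset or list of datasets (compositions attached).
#' @param K_T_fixed Fixed T-state affinity (molar).
#' @param L_grid,c_grid Log-spaced grids.
#' @param K_T_nav NaV T-state affinity substituted into NaV-containing
#'   compositions (default: the value stored in the composition itself).
#' @param weights Optional per-dataset weights.
#' @return A tibble of class `cam_landscape` with columns `L`, `c`,
#'   `score`.
#' @export
score_landscape <- function(datasets, K_T_fixed,
                            L_grid = 10^seq(0, 8, by = 0.1),
                            c_grid = 10^seq(-5, log10(0.002), length.out = 25),
                            K_T_nav = NULL, weights = NULL) {
  datasets <- as_dataset_list(datasets)
  grid <- expand.grid(L = L_grid, c = c_grid)
  grid$score <- vapply(seq_len(nrow(grid)), function(i) {
    par <- list(L = grid$L[i], K_R = grid$c[i] * K_T_fixed, K_T = K_T_fixed)
    if (!is.null(K_T_nav)) par$K_T_nav <- K_T_nav
    weighted_sse(par, datasets, weights)
  }, 0)
  out <- tibble::as_tibble(grid)
  attr(out, "K_T_fixed") <- K_T_fixed
  class(out) <- c("cam_landscape", class(out))
  out
}

#' Width of the near-optimal valley of a score landscape
#'
#' Profiles the landscape over `L` (minimising over `c`) and measures the
#' extent, in decades of `L`, of the region whose profile score is within
#' `frac` of the global minimum.
#'
#' @param landscape A [score_landscape()] result.
#' @param frac Relative score margin defining the sublevel set.
#' @return Width in log10 units of `L`.
#' @export
valley_width <- function(landscape, frac = 0.05) {
  prof <- dplyr::summarise(dplyr::group_by(landscape, .data$L),
                           score = min(.data$score), .groups = "drop")
  smin <- min(prof$score)
  keep <- prof$L[prof$score <= (1 + frac) * smin]
  diff(range(log10(keep)))
}

#' Per-point residuals of a fit
#'
#' Model-minus-observation residuals of a fitted parameter set over the
#' datasets it was fitted to, in long tabular form.
#'
#' @param fit A `cam_fit` (or any list with a `par` element).
#' @param datasets The datasets the fit was computed on.
#' @return A tibble with columns `dataset`, `ca_free_molar`, `observed`,
#'   `model`, `residual`.
#' @export
fit_residuals <- function(fit, datasets) {
  datasets <- as_dataset_list(datasets)
  nms <- names(datasets) %||% paste0("dataset_", seq_along(datasets))
  purrr::map_dfr(seq_along(datasets), function(k) {
    d <- datasets[[k]]
    ym <- model_saturation_for(fit$par, d)
    tibble::tibble(dataset = nms[k], ca_free_molar = d$ca_free_molar,
                   observed = d$saturation, model = ym,
                   residual = ym - d$saturation)
  })
}

#' Bootstrap uncertainty for a TR2C fit
#'
#' Residual-resampling bootstrap: model residuals are resampled within
#' each dataset, added back to the fitted curves, and the full
#' constrained fit is repeated (with a reduced generation budget). The
#' parameter standard deviations across replicates estimate fit
#' uncertainty.
#'
#' @param fit A `cam_fit` from [fit_tr2c()].
#' @param datasets The datasets used for the fit.
#' @param n_boot Number of bootstrap replicates.
#' @param generations Generation budget per replicate.
#' @param seed Integer seed.
#' @return The `cam_fit` with a `boot_sd` element (named vector) added.
#' @export
bootstrap_fit <- function(fit, datasets, n_boot = 200, generations = 100,
                          seed = 1) {
  datasets <- as_dataset_list(datasets)
  fitted_curves <- lapply(datasets, function(d)
    model_saturation_for(fit$par, d))
  draws <- withr::with_seed(seed, {
    lapply(seq_len(n_boot), function(b) {
      boot_sets <- lapply(seq_along(datasets), function(k) {
        d <- datasets[[k]]
        r <- d$saturation - fitted_curves[[k]]
        d$saturation <- fitted_curves[[k]] + sample(r, replace = TRUE)
        d
      })
      bf <- fit_tr2c(boot_sets, constraints = fit$constraints,
                     pop_size = fit$pop_size, generations = generations,
                     seed = sample.int(2^30, 1),
                     fit_nav = "K_T_nav" %in% names(fit$par))
      unlist(bf$par)
    })
  })
  mat <- do.call(rbind, draws)
  fit$boot_sd <- apply(log10(mat), 2, stats::sd)  # sd in decades
  fit$n_boot <- n_boot
  fit
}
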