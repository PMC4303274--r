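#' Hill coefficient (Hill-plane slope) of a saturation curve
#'
#' The Hill coefficient is the slope of the saturation function in the Hill
#' plane, `nH = d log(Y/(1-Y)) / d log(ca)`. For curves produced by
#' [lobe_saturation_fun()] the exact analytic derivative of the two-site
#' MWC form is used; for arbitrary curves the slope is estimated by central
#' differences on the log-concentration axis (initial relative step 1e-3,
#' Richardson-refined until successive estimates agree to 1e-6).
#'
#' @param fn A saturation function `Y(ca_free)` (e.g. from
#'   [lobe_saturation_fun()] or [curve_fun()]).
#' @param ca_free Evaluation point(s), molar; `0 < Y < 1` required there.
#' @return Hill coefficient(s), dimensionless.
#' @examples
#' f <- lobe_saturation_fun(lobe_params(8.616e3, 1.979e-8, 6.241e-5))
#' hill_coefficient(f, half_saturation(f))
#' @export
hill_coefficient <- function(fn, ca_free) {
  stopifnot(is.function(fn))
  vapply(ca_free, function(ca) {
    y <- fn(ca)
    if (!is.finite(y) || y <= 0 || y >= 1)
      stop("Hill slope undefined where Y is 0 or 1 (ca = ", format(ca), ")")
    mwc <- attr(fn, "mwc")
    if (!is.null(mwc)) {
      hill_mwc_analytic(mwc$L_eff, mwc$c, ca / mwc$K_R)
    } else {
      hill_numeric(fn, ca)
    }
  }, 0)
}

## Exact Hill-plane slope of the two-identical-site MWC form:
## nH = 1 + a A'/A - a B'/B with A = (1+a) + Lc(1+ca), B = (1+a) + L(1+ca).
hill_mwc_analytic <- function(L, c, alpha) {
  A <- (1 + alpha) + L * c * (1 + c * alpha)
  B <- (1 + alpha) + L * (1 + c * alpha)
  1 + alpha * (1 + L * c^2) / A - alpha * (1 + L * c) / B
}

hill_numeric <- function(fn, ca, h0 = 1e-3, tol = 1e-6, max_refine = 12) {
  g <- function(h) {
    y <- fn(ca * exp(h))
    log(y / (1 - y))
  }
  est_at <- function(h) (g(h) - g(-h)) / (2 * h)
  h <- h0
  d_prev <- est_at(h)
  ## Richardson: halve the step and extrapolate the O(h^2) error away
  for (i in seq_len(max_refine)) {
    h <- h / 2
    d_new <- est_at(h)
    d_extrap <- (4 * d_new - d_prev) / 3
    if (abs(d_extrap - d_prev) < tol) return(d_extrap)
    d_prev <- d_extrap
  }
  d_prev
}

#' Half-saturation point of a saturation curve
#'
#' Finds the unique free calcium concentration where `Y = 0.5` by
#' bracketing bisection on the log-concentration axis (relative tolerance
#' 1e-10).
#'
#' @param fn Saturation function `Y(ca_free)`.
#' @param interval Initial bracketing interval (molar); expanded
#'   automatically if it does not straddle `Y = 0.5`.
#' @return Free calcium at half-saturation (molar).
#' @export
half_saturation <- function(fn, interval = c(1e-12, 1e-1)) {
  stopifnot(is.function(fn), length(interval) == 2, all(interval > 0))
  lo <- min(interval); hi <- max(interval)
  for (i in 1:60) {
    if (fn(lo) < 0.5) break
    lo <- lo / 10
  }
  for (i in 1:60) {
    if (fn(hi) > 0.5) break
    hi <- hi * 10
  }
  if (fn(lo) >= 0.5 || fn(hi) <= 0.5)
    stop("curve does not bracket Y = 0.5: no half-saturation root")
  r <- stats::uniroot(function(lg) fn(10^lg) - 0.5,
                      lower = log10(lo), upper = log10(hi),
                      tol = 1e-12)
  10^r$root
}

#' Hill-plane profile of a curve
#'
#' Evaluates saturation and the Hill coefficient along a calcium grid. For
#' a two-identical-site MWC lobe the profile is a symmetric bell on the
#' log-concentration axis with its maximum at the half-saturation point.
#'
#' @param fn Saturation function.
#' @param ca_grid Calcium grid (molar); default 60 log-spaced points
#'   between 10 nM and 1 mM.
#' @return A tibble (`cam_hill_profile`) with columns `ca_free_molar`,
#'   `saturation`, `n_H`.
#' @export
hill_profile <- function(fn, ca_grid = default_ca_grid()) {
  out <- tibble::tibble(ca_free_molar = ca_grid,
                        saturation = vapply(ca_grid, fn, 0),
                        n_H = hill_coefficient(fn, ca_grid))
  class(out) <- c("cam_hill_profile", class(out))
  out
}

#' Default log-spaced calcium grid
#'
#' 60 log-spaced points spanning 10 nM to 1 mM, the physiologically
#' plausible window used throughout.
#'
#' @param n Number of points.
#' @param range Concentration range (molar).
#' @return Numeric vector of concentrations (molar).
#' @export
default_ca_grid <- function(n = 60, range = c(1e-8, 1e-3)) {
  10^seq(log10(range[1]), log10(range[2]), length.out = n)
}

#' Summary Hill statistics of a saturation curve
#'
#' @param fn Saturation function.
#' @return A one-row tibble with `ca_half` (molar), `nH_at_half`, and
#'   `nH_max` (maximum of the Hill coefficient over the curve).
#' @export
hill_summary <- function(fn) {
  ca_half <- half_saturation(fn)
  nh_half <- hill_coefficient(fn, ca_half)
  opt <- stats::optimize(function(lg) hill_coefficient(fn, 10^lg),
                         lower = log10(ca_half) - 3,
                         upper = log10(ca_half) + 3, maximum = TRUE,
                         tol = 1e-8)
  tibble::tibble(ca_half = ca_half, nH_at_half = nh_half,
                 nH_max = max(nh_half, opt$objective))
}

#' Phenomenological Hill fit of a titration dataset
#'
#' Least-squares fit of the Hill function `Y = x^n / (K^n + x^n)` to a
#' titration dataset, with equal weight per point. Used for comparison
#' with the mechanistic MWC curves: over the physiological calcium range
#' the two lie close together even though they differ asymptotically in
#' the Hill plane.
#'
#' @param data A data frame with columns `ca_free_molar` and `saturation`
#'   (at least 4 points spanning both sides of half-saturation).
#' @return A `cam_hill_fit` object with elements `K_half` (molar),
#'   `n_H`, `rss`, and the fitted function `fn`.
#' @export
fit_hill <- function(data) {
  data <- as.data.frame(data)
  if (!all(c("ca_free_molar", "saturation") %in% names(data)))
    stop("data must have columns ca_free_molar and saturation")
  x <- data$ca_free_molar
  y <- data$saturation
  if (length(x) < 4) stop("need at least 4 points for a Hill fit")
  if (stats::sd(y) == 0) stop("degenerate data: all saturation values equal")
  if (min(y) > 0.5 || max(y) < 0.5)
    stop("data must span both sides of half-saturation")
  ## starting K: log-linear interpolation at Y = 0.5
  ord <- order(x)
  K0 <- 10^stats::approx(y[ord], log10(x[ord]), xout = 0.5, ties = mean)$y
  sse <- function(p) {
    K <- 10^p[1]; n <- exp(p[2])
    r <- y - hill_fn(x, K, n)
    sum(r^2)
  }
  p0 <- c(log10(K0), log(1.5))
  opt <- stats::optim(p0, sse, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  opt <- stats::optim(opt$par, sse, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  K <- 10^opt$par[1]; n <- exp(opt$par[2])
  structure(list(K_half = K, n_H = n, rss = opt$value,
                 n_points = length(x),
                 fn = function(ca) hill_fn(ca, K, n)),
            class = "cam_hill_fit")
}

hill_fn <- function(x, K, n) x^n / (K^n + x^n)

#' @export
print.cam_hill_fit <- function(x, ...) {
  cat(sprintf("<cam_hill_fit> K_half = %.4g M, n_H = %.3f, rss = %.3g (%d points)\n",
              x$K_half, x$n_H, x$rss, x$n_points))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' @export
tidy.cam_hill_fit <- function(x, ...) {
  tibble::tibble(term = c("K_half", "n_H"),
                 estimate = c(x$K_half, x$n_H),
                 unit = c("M", ""))
}

#' @export
glance.cam_hill_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, n_points = x$n_points)
}
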