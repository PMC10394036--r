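# Isotropic + two-von-Mises mixture model of axial orientation
# distributions: density, exact sampling, and constrained least-squares
# fitting on binned densities.

#' Isotropic + two-von-Mises mixture parameters
#'
#' Parameterizes the lamella orientation distribution as an isotropic
#' background plus two axial von Mises peaks, conventionally the
#' nasal-temporal (NT) and inferior-superior (IS) corneal axes:
#' `p(phi) = c_iso/pi + c_NT M(phi | mu_NT, k_NT) + c_IS M(phi | mu_IS, k_IS)`
#' with `M(phi | mu, k) = exp(k cos(2(phi - mu))) / (pi I0(k))`. Angles are
#' doubled in the exponential because orientations cover only half the full
#' circle; `1/kappa` plays the role of a variance.
#'
#' @param c_iso,c_nt,c_is non-negative weights summing to 1.
#' @param mu_nt_deg,mu_is_deg peak locations in degrees, wrapped to
#'   `[0, 180)`.
#' @param kappa_nt,kappa_is concentrations, `>= 0` (0 = flat).
#' @return an object of class `vm_mixture`.
#' @export
vm_mixture <- function(c_iso, c_nt, mu_nt_deg, kappa_nt,
                       c_is, mu_is_deg, kappa_is) {
  w <- c(c_iso, c_nt, c_is)
  stopifnot(all(w >= 0), abs(sum(w) - 1) < 1e-6,
            kappa_nt >= 0, kappa_is >= 0)
  structure(list(c_iso = c_iso,
                 c_nt = c_nt, mu_nt_deg = wrap_orientation(mu_nt_deg),
                 kappa_nt = kappa_nt,
                 c_is = c_is, mu_is_deg = wrap_orientation(mu_is_deg),
                 kappa_is = kappa_is),
            class = "vm_mixture")
}

# Axial von Mises density on [0, pi), per radian; numerically stable for
# large kappa via the exponentially scaled Bessel function.
vm_density <- function(phi_deg, mu_deg, kappa) {
  d <- deg2rad(phi_deg - mu_deg)
  exp(kappa * (cos(2 * d) - 1)) /
    (pi * besselI(kappa, 0, expon.scaled = TRUE))
}

#' Mixture density at given orientations
#'
#' @param params a [vm_mixture()].
#' @param phi_deg orientations in degrees (vectorized).
#' @return per-radian density; integrates to 1 over `[0, 180)` degrees.
#' @export
mixture_pdf <- function(params, phi_deg) {
  stopifnot(inherits(params, "vm_mixture"))
  params$c_iso / pi +
    params$c_nt * vm_density(phi_deg, params$mu_nt_deg, params$kappa_nt) +
    params$c_is * vm_density(phi_deg, params$mu_is_deg, params$kappa_is)
}

# Best-Fisher rejection sampler for the full-circle von Mises distribution
# (mean mu_rad, concentration kappa), vectorized in batches.
rvonmises <- function(n, mu_rad, kappa) {
  if (kappa < 1e-10) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- ceiling((n - length(out)) * 1.6) + 10
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    th <- sign(u3[ok] - 0.5) * acos(pmin(pmax(f[ok], -1), 1))
    out <- c(out, th)
  }
  (mu_rad + out[seq_len(n)]) %% (2 * pi)
}

#' Draw orientations from a mixture law
#'
#' Exact sampling: a component is chosen per draw, isotropic draws are
#' uniform on `[0, 180)`, and von Mises draws are taken on the doubled-angle
#' circle then halved back. Deterministic given `seed`.
#'
#' @param params a [vm_mixture()].
#' @param n number of draws.
#' @param seed optional RNG seed; `NULL` uses the current RNG state.
#' @return `n` orientations in `[0, 180)` degrees.
#' @export
sample_mixture <- function(params, n, seed = NULL) {
  stopifnot(inherits(params, "vm_mixture"), n > 0)
  if (!is.null(seed)) set.seed(seed)
  comp <- sample.int(3L, n, replace = TRUE,
                     prob = c(params$c_iso, params$c_nt, params$c_is))
  out <- numeric(n)
  n_iso <- sum(comp == 1L)
  if (n_iso) out[comp == 1L] <- stats::runif(n_iso, 0, 180)
  for (j in 2:3) {
    idx <- comp == j
    nj <- sum(idx)
    if (!nj) next
    mu <- if (j == 2L) params$mu_nt_deg else params$mu_is_deg
    ka <- if (j == 2L) params$kappa_nt else params$kappa_is
    out[idx] <- rad2deg(rvonmises(nj, deg2rad(2 * mu), ka)) / 2
  }
  wrap_orientation(out)
}

#' Circular separation between two peak locations
#'
#' Difference of axial angles folded to `[0, 90]` degrees — the angular
#' shift between the two fitted peaks.
#'
#' @param mu_a_deg,mu_b_deg peak locations in degrees.
#' @return separation in `[0, 90]` degrees.
#' @export
delta_mu <- function(mu_a_deg, mu_b_deg) angular_difference(mu_a_deg, mu_b_deg)

# Free parameterization used by the optimizer: weights through a softmax
# (isotropic logit pinned at 0), concentrations through a scaled logistic
# keeping kappa in (0, 100), peak locations unconstrained (circular).
par_to_mixture <- function(p) {
  e <- exp(c(0, p[1], p[2]) - max(0, p[1], p[2]))
  w <- e / sum(e)
  vm_mixture(c_iso = w[1],
             c_nt = w[2], mu_nt_deg = p[3] %% 180,
             kappa_nt = 100 * stats::plogis(p[5]),
             c_is = w[3], mu_is_deg = p[4] %% 180,
             kappa_is = 100 * stats::plogis(p[6]))
}

mixture_to_par <- function(m) {
  w <- pmax(c(m$c_iso, m$c_nt, m$c_is), 1e-6)
  ka <- pmin(pmax(c(m$kappa_nt, m$kappa_is), 1e-4), 99.99)
  c(log(w[2] / w[1]), log(w[3] / w[1]),
    m$mu_nt_deg, m$mu_is_deg,
    stats::qlogis(ka[1] / 100), stats::qlogis(ka[2] / 100))
}

# Initial peak locations: the two highest well-separated histogram modes
# (separation >= 30 degrees folded), falling back to 0 and 90.
initial_modes <- function(density) {
  centers <- 0:179 + 0.5
  ord <- order(density, decreasing = TRUE)
  m1 <- centers[ord[1]]
  m2 <- NA_real_
  for (i in ord[-1]) {
    if (angular_difference(centers[i], m1) >= 30) { m2 <- centers[i]; break }
  }
  if (is.na(m2) || max(density) <= 0) c(0, 90) else c(m1, m2)
}

#' Fit the isotropic + two-von-Mises mixture to a distribution
#'
#' Constrained least squares on the binned densities: weights on the
#' simplex, concentrations in `(0, 100)`, peak locations free circular.
#' Initialization places the peaks at the two highest well-separated
#' histogram modes (fallback 0 and 90 degrees) with `kappa = 3` and equal
#' weights; four deterministic perturbations of that start are also tried
#' and the best sum of squares kept. The component whose peak lies nearer
#' the 0-degree (X, nasal-temporal) axis of the registered frame is labeled
#' NT, the other IS.
#'
#' @param dist a non-empty `orientation_distribution`.
#' @param init optional [vm_mixture()] starting point.
#' @return an object of class `vm_mixture_fit`: `params` ([vm_mixture()]),
#'   `delta_mu_deg` (peak separation folded to `[0, 90]`), `fit_r2`
#'   (coefficient of determination on bin densities), `sse`, `degenerate`
#'   (TRUE when `delta_mu < 10` degrees or a peak weight `< 0.01`, where the
#'   peak separation is not identifiable), `converged`.
#' @export
fit_mixture <- function(dist, init = NULL) {
  stopifnot(inherits(dist, "orientation_distribution"), !dist$empty)
  centers <- 0:179 + 0.5
  y <- dist$density * 180 / pi  # bin mass -> per-radian density
  obj <- function(p) {
    m <- try(par_to_mixture(p), silent = TRUE)
    if (inherits(m, "try-error")) return(1e10)
    sum((mixture_pdf(m, centers) - y)^2)
  }
  modes <- initial_modes(dist$density)
  base <- if (is.null(init))
    vm_mixture(1 / 3, 1 / 3, modes[1], 3, 1 / 3, modes[2], 3)
  else init
  p0 <- mixture_to_par(base)
  starts <- list(p0,
                 p0 + c(0, 0, 15, -15, 0, 0),
                 p0 + c(0, 0, -15, 15, 0, 0),
                 p0 + c(0, 0, 0, 0, log(2), log(2)),
                 p0 + c(0.5, -0.5, 0, 0, -log(2), -log(2)))
  best <- NULL
  for (s in starts) {
    f <- try(stats::optim(s, obj, method = "BFGS",
                          control = list(maxit = 500, reltol = 1e-12)),
             silent = TRUE)
    if (inherits(f, "try-error")) next
    f <- try(stats::optim(f$par, obj, method = "Nelder-Mead",
                          control = list(maxit = 2000, reltol = 1e-14)),
             silent = TRUE)
    if (inherits(f, "try-error")) next
    if (is.null(best) || f$value < best$value) best <- f
  }
  if (is.null(best))
    return(structure(list(params = NULL, delta_mu_deg = NA_real_,
                          fit_r2 = NA_real_, sse = NA_real_,
                          degenerate = TRUE, converged = FALSE),
                     class = "vm_mixture_fit"))
  m <- par_to_mixture(best$par)
  # label by proximity to the 0-degree axis
  d_nt <- angular_difference(m$mu_nt_deg, 0)
  d_is <- angular_difference(m$mu_is_deg, 0)
  if (d_is < d_nt) {
    m <- vm_mixture(m$c_iso, m$c_is, m$mu_is_deg, m$kappa_is,
                    m$c_nt, m$mu_nt_deg, m$kappa_nt)
  }
  dm <- delta_mu(m$mu_nt_deg, m$mu_is_deg)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - best$value / ss_tot else NA_real_
  structure(list(params = m, delta_mu_deg = dm, fit_r2 = r2,
                 sse = best$value,
                 degenerate = dm < 10 || min(m$c_nt, m$c_is) < 0.01,
                 converged = TRUE),
            class = "vm_mixture_fit")
}

#' Maximum-likelihood mixture fit from raw orientation samples
#'
#' Alternative to the binned least-squares fit when individual orientations
#' (rather than a plotted distribution) are available: minimizes the
#' negative log-likelihood of [mixture_pdf()] under the same constraints
#' and labeling.
#'
#' @param angles_deg numeric vector of orientations in degrees.
#' @param init optional [vm_mixture()] starting point.
#' @return a `vm_mixture_fit` (with `sse` replaced by `nll`).
#' @export
fit_mixture_ml <- function(angles_deg, init = NULL) {
  stopifnot(length(angles_deg) > 10)
  phi <- wrap_orientation(angles_deg)
  obj <- function(p) {
    m <- try(par_to_mixture(p), silent = TRUE)
    if (inherits(m, "try-error")) return(1e10)
    -sum(log(pmax(mixture_pdf(m, phi), 1e-300)))
  }
  h <- orientation_histogram(phi)
  modes <- initial_modes(h$density)
  base <- if (is.null(init))
    vm_mixture(1 / 3, 1 / 3, modes[1], 3, 1 / 3, modes[2], 3)
  else init
  f <- stats::optim(mixture_to_par(base), obj, method = "Nelder-Mead",
                    control = list(maxit = 3000, reltol = 1e-12))
  m <- par_to_mixture(f$par)
  d_nt <- angular_difference(m$mu_nt_deg, 0)
  d_is <- angular_difference(m$mu_is_deg, 0)
  if (d_is < d_nt)
    m <- vm_mixture(m$c_iso, m$c_is, m$mu_is_deg, m$kappa_is,
                    m$c_nt, m$mu_nt_deg, m$kappa_nt)
  dm <- delta_mu(m$mu_nt_deg, m$mu_is_deg)
  structure(list(params = m, delta_mu_deg = dm, fit_r2 = NA_real_,
                 nll = f$value,
                 degenerate = dm < 10 || min(m$c_nt, m$c_is) < 0.01,
                 converged = f$convergence == 0),
            class = "vm_mixture_fit")
}
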