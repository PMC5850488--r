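#' Parameters of the bivariate wrapped-normal diffusion on the torus
#'
#' The wrapped-normal (WN) diffusion is the torus analogue of the
#' Ornstein-Uhlenbeck process. It is parameterized by a stationary mean
#' `mu` on T^2, per-coordinate drift strengths `alpha1` (phi) and `alpha2`
#' (psi), a coupling term `alpha3` capturing phi-psi correlation, and
#' per-coordinate infinitesimal standard deviations `sigma1`, `sigma2`.
#' The implied drift matrix is
#' \deqn{A = \begin{pmatrix} \alpha_1 & \alpha_3 \sigma_1/\sigma_2 \\
#'   \alpha_3 \sigma_2/\sigma_1 & \alpha_2 \end{pmatrix}, \quad
#'   \Sigma = \mathrm{diag}(\sigma_1^2, \sigma_2^2),}
#' constrained by \eqn{\alpha_1 \alpha_2 > \alpha_3^2} so that
#' \eqn{A^{-1}\Sigma} is symmetric positive definite and the stationary
#' distribution is a wrapped bivariate normal with covariance
#' \eqn{\frac{1}{2} A^{-1} \Sigma}.
#'
#' @param mu length-2 numeric, stationary mean (phi, psi) in radians.
#' @param alpha1,alpha2 positive drift coefficients.
#' @param alpha3 real coupling coefficient.
#' @param sigma1,sigma2 positive diffusion coefficients.
#' @return object of class `"wn_params"`.
#' @export
wn_params <- function(mu = c(0, 0), alpha1 = 1, alpha2 = 1, alpha3 = 0,
                      sigma1 = 1, sigma2 = 1) {
  p <- structure(
    list(mu = wrap_angle(as.numeric(mu)), alpha1 = alpha1, alpha2 = alpha2,
         alpha3 = alpha3, sigma1 = sigma1, sigma2 = sigma2),
    class = "wn_params")
  validate_wn_params(p)
}

#' Validate wrapped-normal diffusion parameters
#'
#' Checks positivity of the drift and diffusion coefficients and the
#' stability constraint `alpha1 * alpha2 > alpha3^2`, which guarantees a
#' symmetric positive-definite stationary covariance.
#'
#' @param p a `"wn_params"` object.
#' @return `p`, unchanged, if valid; otherwise an error naming the violated
#'   constraint.
#' @export
validate_wn_params <- function(p) {
  stopifnot(inherits(p, "wn_params"))
  if (length(p$mu) != 2L || any(!is.finite(p$mu))) {
    stop("wn_params: mu must be a finite (phi, psi) pair")
  }
  for (nm in c("alpha1", "alpha2", "sigma1", "sigma2")) {
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0) {
      stop(sprintf("wn_params: %s must be > 0", nm))
    }
  }
  if (!is.finite(p$alpha3)) stop("wn_params: alpha3 must be finite")
  if (p$alpha1 * p$alpha2 <= p$alpha3^2) {
    stop("wn_params: constraint alpha1 * alpha2 > alpha3^2 violated")
  }
  p
}

#' @rdname wn_params
#' @param p a `"wn_params"` object.
#' @return `wn_drift_matrix`: the 2x2 drift matrix A; `wn_sigma`: the 2x2
#'   diagonal infinitesimal covariance; `wn_stationary_cov`: the 2x2
#'   stationary covariance `A^{-1} Sigma / 2`.
#' @export
wn_drift_matrix <- function(p) {
  matrix(c(p$alpha1, p$alpha3 * p$sigma2 / p$sigma1,
           p$alpha3 * p$sigma1 / p$sigma2, p$alpha2), 2, 2)
}

#' @rdname wn_params
#' @export
wn_sigma <- function(p) diag(c(p$sigma1^2, p$sigma2^2))

#' @rdname wn_params
#' @export
wn_stationary_cov <- function(p) {
  A <- wn_drift_matrix(p)
  S <- solve(A, wn_sigma(p)) / 2
  (S + t(S)) / 2  # symmetrize rounding noise
}

# Winding offsets 2*pi*k for k in {-K..K}^2, as a (2K+1)^2 x 2 matrix
# (memoized; K is small and reused constantly).
.winding_cache <- new.env(parent = emptyenv())
.winding_offsets <- function(K) {
  stopifnot(K >= 0)
  key <- as.character(K)
  if (is.null(.winding_cache[[key]])) {
    ks <- seq.int(-K, K)
    n <- length(ks)
    .winding_cache[[key]] <- 2 * pi * cbind(rep(ks, times = n),
                                            rep(ks, each = n))
  }
  .winding_cache[[key]]
}

# Log-density of N(0, M) evaluated at rows of the n x 2 matrix x.
.lmvnorm2 <- function(x, M) {
  Mi <- solve(M)
  ld <- determinant(M, logarithm = TRUE)$modulus[1]
  q <- x[, 1]^2 * Mi[1, 1] + 2 * x[, 1] * x[, 2] * Mi[1, 2] + x[, 2]^2 * Mi[2, 2]
  -log(2 * pi) - 0.5 * ld - 0.5 * q
}

.logsumexp_rows <- function(m) {
  mx <- m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
  bad <- !is.finite(mx)
  out <- mx + log(rowSums(exp(m - mx)))
  out[bad] <- mx[bad]
  out
}

# Quadratic-form log N(0, M) terms over n deviations shifted by each of W
# offsets: returns n x W matrix of log-densities in one vectorized pass.
.lmvnorm2_shifted <- function(dev, offs, M) {
  Mi <- solve(M)
  ld <- determinant(M, logarithm = TRUE)$modulus[1]
  d1 <- outer(dev[, 1], offs[, 1], "+")
  d2 <- outer(dev[, 2], offs[, 2], "+")
  q <- d1^2 * Mi[1, 1] + 2 * d1 * d2 * Mi[1, 2] + d2^2 * Mi[2, 2]
  -log(2 * pi) - 0.5 * ld - 0.5 * q
}

# Wrapped bivariate normal log-density: sum over windings k of N(mu, M) at
# theta - mu + 2*pi*k. theta: n x 2 matrix (or length 2); mu may be n x 2.
.wn_lpdf <- function(theta, mu, M, K) {
  theta <- .as_point_matrix(theta)
  if (is.matrix(mu)) {
    dev <- theta - mu
  } else {
    dev <- sweep(theta, 2L, mu)
  }
  .logsumexp_rows(.lmvnorm2_shifted(dev, .winding_offsets(K), M))
}

#' Stationary log-density of the WN diffusion
#'
#' The stationary law is a wrapped bivariate normal centered at `mu` with
#' covariance `A^{-1} Sigma / 2`; its density is a sum of Gaussian copies
#' over winding numbers, truncated to `k` in `{-K..K}^2`.
#'
#' @param theta a (phi, psi) pair or an n x 2 matrix of pairs, radians.
#' @param p a `"wn_params"` object.
#' @param K winding truncation level (default 1, i.e. 3 x 3 windings).
#' @return numeric vector of log-densities.
#' @export
wn_stationary_lpdf <- function(theta, p, K = 1L) {
  .wn_lpdf(theta, p$mu, wn_stationary_cov(p), K)
}

#' Winding weights of the WN drift
#'
#' The weights \eqn{w_k(\theta)} that blend the linear Ornstein-Uhlenbeck
#' drifts across winding copies so that the resulting drift field is smooth
#' and periodic: proportional to the N(0, A^{-1}Sigma/2) density at
#' `theta - mu + 2*pi*k`, normalized over the truncated winding set.
#'
#' @inheritParams wn_stationary_lpdf
#' @return numeric vector of length `(2K+1)^2`, non-negative, summing to 1,
#'   in the row order of the winding grid `expand.grid(-K:K, -K:K)`.
#' @export
wn_drift_weights <- function(theta, p, K = 1L) {
  theta <- .as_point_matrix(theta)
  stopifnot(nrow(theta) == 1L)
  offs <- .winding_offsets(K)
  S <- wn_stationary_cov(p)
  dev <- sweep(offs, 2L, theta - p$mu, "+")
  lw <- .lmvnorm2(dev, S)
  w <- exp(lw - max(lw))
  w / sum(w)
}

#' Drift field of the WN diffusion
#'
#' Evaluates the periodic drift \eqn{A \sum_k (\mu - \theta - 2\pi k)
#' w_k(\theta)} at a torus point. Zero at `theta = mu`, periodic with
#' period \eqn{2\pi} in each coordinate.
#'
#' @inheritParams wn_stationary_lpdf
#' @return length-2 numeric drift vector (radians per unit time).
#' @export
wn_drift <- function(theta, p, K = 1L) {
  theta <- .as_point_matrix(theta)
  stopifnot(nrow(theta) == 1L)
  offs <- .winding_offsets(K)
  w <- wn_drift_weights(theta, p, K)
  dev <- sweep(-offs, 2L, p$mu - theta, "+")  # mu - theta - 2*pi*k
  as.numeric(wn_drift_matrix(p) %*% colSums(dev * w))
}

#' Transition covariance of the WN diffusion
#'
#' The covariance \eqn{\Gamma_t = \int_0^t e^{-sA} \Sigma e^{-sA^T} ds} of
#' the underlying linear process after time t, computed in closed form as
#' \eqn{\Gamma_\infty - e^{-tA}\Gamma_\infty e^{-tA^T}} with
#' \eqn{\Gamma_\infty = A^{-1}\Sigma/2}.
#'
#' @param p a `"wn_params"` object.
#' @param t evolutionary time, `t >= 0`.
#' @return symmetric positive semi-definite 2x2 matrix; the zero matrix at
#'   `t = 0`, converging to the stationary covariance as `t` grows.
#' @export
wn_gamma_t <- function(p, t) {
  if (t < 0) stop("wn_gamma_t: t must be >= 0")
  Ginf <- wn_stationary_cov(p)
  E <- .expm2(-t * wn_drift_matrix(p))
  G <- Ginf - E %*% Ginf %*% t(E)
  (G + t(G)) / 2
}

# Exact closed-form 2x2 matrix exponential:
# e^M = e^tau (cosh(d) I + sinh(d)/d (M - tau I)), tau = tr(M)/2,
# d = sqrt(tau^2 - det(M)); complex-safe, series for the defective case d=0.
.expm2 <- function(M) {
  tau <- (M[1, 1] + M[2, 2]) / 2
  d2 <- tau^2 - (M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1])
  if (abs(d2) < 1e-24) {
    ch <- 1 + d2 / 2
    sh_over_d <- 1 + d2 / 6
  } else if (d2 > 0) {
    d <- sqrt(d2)
    ch <- cosh(d)
    sh_over_d <- sinh(d) / d
  } else {
    d <- sqrt(-d2)
    ch <- cos(d)
    sh_over_d <- sin(d) / d
  }
  exp(tau) * (ch * diag(2) + sh_over_d * (M - tau * diag(2)))
}

#' Approximate transition log-density (pseudo-tpd) of the WN diffusion
#'
#' The multimodal pseudo transition density: a winding-weighted mixture of
#' wrapped Gaussians,
#' \deqn{\tilde p(\theta_2 \mid \theta_1, t) = \sum_m
#'   p_{WN}(\theta_2 \mid \mu_t^m, \Gamma_t)\, w_m(\theta_1),}
#' with \eqn{\mu_t^m = \mu + e^{-tA}(\theta_1 - \mu + 2\pi m)}. It collapses
#' to a Dirac delta at `theta1` as `t -> 0` and converges to the stationary
#' density as `t -> Inf`, and satisfies the time-reversibility identity with
#' respect to the stationary law.
#'
#' @param theta2,theta1 torus points; either may be an n x 2 matrix (equal
#'   row counts, or one of them a single point).
#' @param p a `"wn_params"` object.
#' @param t evolutionary time, `t >= 0`.
#' @param K winding truncation level.
#' @return numeric vector of log-densities of `theta2` given `theta1`.
#' @export
wn_pseudo_tpd_lpdf <- function(theta2, theta1, p, t, K = 1L) {
  if (t < 0) stop("wn_pseudo_tpd_lpdf: t must be >= 0")
  theta2 <- .as_point_matrix(theta2)
  theta1 <- .as_point_matrix(theta1)
  n <- max(nrow(theta1), nrow(theta2))
  if (nrow(theta1) == 1L && n > 1L) theta1 <- theta1[rep(1L, n), , drop = FALSE]
  if (nrow(theta2) == 1L && n > 1L) theta2 <- theta2[rep(1L, n), , drop = FALSE]
  stopifnot(nrow(theta1) == nrow(theta2))
  if (t < 1e-12) {
    # Dirac limit
    same <- angular_distance(theta1, theta2) < 1e-9
    return(ifelse(same, Inf, -Inf))
  }
  A <- wn_drift_matrix(p)
  E <- .expm2(-t * A)
  Gt <- wn_gamma_t(p, t)
  Sinf <- wn_stationary_cov(p)
  offs <- .winding_offsets(K)
  W <- nrow(offs)
  dev1 <- sweep(theta1, 2L, p$mu)
  # log winding weights of theta1, normalized per row
  lw <- .lmvnorm2_shifted(dev1, offs, Sinf)
  lw <- lw - .logsumexp_rows(lw)
  # base deviation theta2 - mu - e^{-tA}(theta1 - mu); per-(m,k) shift is
  # -e^{-tA} (2 pi m) + 2 pi k, all computed in one vectorized pass
  base <- sweep(theta2, 2L, p$mu) - dev1 %*% t(E)
  em <- offs %*% t(E)
  im <- rep(seq_len(W), each = W)
  ik <- rep(seq_len(W), times = W)
  shifts <- cbind(offs[ik, 1] - em[im, 1], offs[ik, 2] - em[im, 2])
  terms <- .lmvnorm2_shifted(base, shifts, Gt)   # n x (W*W)
  # single pass: weight each (m, k) term by w_m and sum them all
  .logsumexp_rows(terms + lw[, im, drop = FALSE])
}

#' Joint log-likelihood of a dihedral-angle pair under the WN diffusion
#'
#' Assumes the first observation is drawn from the stationary law and the
#' second from the pseudo transition density after time t:
#' `wn_pseudo_tpd_lpdf(x_b | x_a, t) + wn_stationary_lpdf(x_a)`. By
#' time-reversibility of the diffusion the value is symmetric in the two
#' observations.
#'
#' @param x_a,x_b torus points or n x 2 matrices of points.
#' @inheritParams wn_pseudo_tpd_lpdf
#' @return numeric vector of log-likelihoods.
#' @export
wn_pair_lpdf <- function(x_a, x_b, p, t, K = 1L) {
  wn_pseudo_tpd_lpdf(x_b, x_a, p, t, K) + wn_stationary_lpdf(x_a, p, K)
}

#' Sample from the stationary law of the WN diffusion
#'
#' Draws from the unwrapped Gaussian N(mu, A^{-1}Sigma/2) and wraps onto
#' the torus (wrapping is exact for the wrapped normal).
#'
#' @param p a `"wn_params"` object.
#' @param n number of draws.
#' @param seed optional integer; when given the draws are reproducible and
#'   the caller's RNG state is left untouched.
#' @return n x 2 matrix of (phi, psi) rows.
#' @export
wn_sample_stationary <- function(p, n, seed = NULL) {
  .with_seed(seed, {
    L <- chol(wn_stationary_cov(p))
    z <- matrix(stats::rnorm(2 * n), n, 2) %*% L
    wrap_angle(sweep(z, 2L, p$mu, "+"))
  })
}

#' Sample from the pseudo transition density of the WN diffusion
#'
#' Draws a winding `m` with weight `w_m(theta1)`, then a Gaussian with mean
#' `mu_t^m` and covariance `Gamma_t`, and wraps. At `t = 0` all draws equal
#' `theta1` exactly.
#'
#' @param theta1 starting torus point.
#' @inheritParams wn_sample_stationary
#' @param t evolutionary time, `t >= 0`.
#' @param K winding truncation level.
#' @return n x 2 matrix of (phi, psi) rows.
#' @export
wn_sample_transition <- function(theta1, p, t, n, seed = NULL, K = 1L) {
  if (t < 0) stop("wn_sample_transition: t must be >= 0")
  theta1 <- as.numeric(.as_point_matrix(theta1))
  if (t < 1e-12) {
    return(matrix(theta1, n, 2, byrow = TRUE))
  }
  .with_seed(seed, {
    offs <- .winding_offsets(K)
    w <- wn_drift_weights(theta1, p, K)
    E <- .expm2(-t * wn_drift_matrix(p))
    Gt <- wn_gamma_t(p, t)
    L <- chol(Gt)
    m_idx <- sample.int(nrow(offs), n, replace = TRUE, prob = w)
    mu_tm <- sweep((sweep(offs[m_idx, , drop = FALSE], 2L, theta1 - p$mu, "+")) %*% t(E),
                   2L, p$mu, "+")
    z <- matrix(stats::rnorm(2 * n), n, 2) %*% L
    wrap_angle(mu_tm + z)
  })
}

# Vectorized transition sampling from many starting points (ambient RNG):
# one draw per row of theta1.
.wn_sample_transition_multi <- function(theta1, p, t, K = 1L) {
  theta1 <- .as_point_matrix(theta1)
  n <- nrow(theta1)
  if (t < 1e-12) return(theta1)
  offs <- .winding_offsets(K)
  Sinf <- wn_stationary_cov(p)
  dev1 <- sweep(theta1, 2L, p$mu)
  lw <- .lmvnorm2_shifted(dev1, offs, Sinf)
  m_idx <- .sample_rows(lw)
  E <- .expm2(-t * wn_drift_matrix(p))
  Gt <- wn_gamma_t(p, t)
  L <- chol(Gt)
  mu_tm <- sweep((dev1 + offs[m_idx, , drop = FALSE]) %*% t(E), 2L, p$mu, "+")
  wrap_angle(mu_tm + matrix(stats::rnorm(2 * n), n, 2) %*% L)
}

#' Simulate a trajectory of the WN diffusion by Euler-Maruyama
#'
#' Direct stochastic integration of the diffusion's SDE with wrapping after
#' each step. Used to cross-check the pseudo transition density against the
#' exact dynamics.
#'
#' @param theta0 starting torus point.
#' @param p a `"wn_params"` object.
#' @param t time horizon.
#' @param dt step size.
#' @param n number of independent trajectories.
#' @param seed optional integer seed.
#' @param K winding truncation for the drift evaluation.
#' @return n x 2 matrix of endpoint (phi, psi) rows.
#' @export
wn_simulate_em <- function(theta0, p, t, dt = 1e-3, n = 1L, seed = NULL, K = 1L) {
  theta0 <- as.numeric(.as_point_matrix(theta0))
  A <- wn_drift_matrix(p)
  Sinf <- wn_stationary_cov(p)
  SinfI <- solve(Sinf)
  sig <- c(p$sigma1, p$sigma2)
  offs <- .winding_offsets(K)
  nsteps <- ceiling(t / dt)
  .with_seed(seed, {
    x <- matrix(theta0, n, 2, byrow = TRUE)
    for (s in seq_len(nsteps)) {
      h <- min(dt, t - (s - 1) * dt)
      # vectorized winding-weighted drift over all n trajectories
      dev <- sweep(x, 2L, p$mu)  # theta - mu
      lw <- vapply(seq_len(nrow(offs)), function(i) {
        d <- sweep(dev, 2L, offs[i, ], "+")
        -0.5 * (d[, 1]^2 * SinfI[1, 1] + 2 * d[, 1] * d[, 2] * SinfI[1, 2] +
                  d[, 2]^2 * SinfI[2, 2])
      }, numeric(n))
      if (n == 1L) lw <- matrix(lw, nrow = 1L)
      w <- exp(lw - apply(lw, 1L, max))
      w <- w / rowSums(w)
      # drift = A %*% sum_k (mu - theta - 2 pi k) w_k
      mdev <- -dev  # mu - theta
      db1 <- rowSums(w * outer(rep(1, n), -offs[, 1])) + mdev[, 1] * rowSums(w)
      db2 <- rowSums(w * outer(rep(1, n), -offs[, 2])) + mdev[, 2] * rowSums(w)
      drift <- cbind(db1, db2) %*% t(A)
      x <- x + h * drift +
        sqrt(h) * matrix(stats::rnorm(2 * n), n, 2) %*% diag(sig)
      x <- wrap_angle(x)
    }
    x
  })
}

# Evaluate expr with a fixed RNG seed without disturbing global RNG state;
# with seed = NULL the global stream is used as-is.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    force(expr)
  } else {
    withr::with_seed(as.integer(seed), expr)
  }
}
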