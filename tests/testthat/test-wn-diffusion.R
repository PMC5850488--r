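test_that("parameter validation enforces the stability constraint", {
  expect_silent(wn_params(c(0, 0), 1, 0.5, 0.5, 1.5, 1.5))  # 0.5 > 0.25
  expect_error(wn_params(c(0, 0), 1, 1, 1.5, 1, 1), "alpha1 \\* alpha2")
  expect_silent(wn_params(c(0, 0), 2, 0.7, 0, 1, 1))
  expect_error(wn_params(c(0, 0), -1, 1, 0, 1, 1), "alpha1")
  expect_error(wn_params(c(0, 0), 1, 1, 0, 0, 1), "sigma1")
  # A^{-1} Sigma is symmetric positive definite under the parameterization
  p <- wn_params(c(1, -2), 2, 0.7, -0.6, 0.8, 1.7)
  S <- wn_stationary_cov(p)
  expect_equal(S, t(S))
  expect_true(all(eigen(S, symmetric = TRUE)$values > 0))
})

test_that("stationary density integrates to 1 and is elliptically symmetric", {
  p <- fig_params()
  g <- torus_grid(120)
  expect_equal(sum(exp(wn_stationary_lpdf(g$points, p, K = 2L))) * g$cell, 1,
               tolerance = 1e-3)
  # symmetry about mu
  set.seed(11)
  delta <- matrix(runif(200, -pi, pi), ncol = 2)
  expect_equal(wn_stationary_lpdf(wrap_angle(sweep(delta, 2, p$mu, "+")), p, 2L),
               wn_stationary_lpdf(wrap_angle(sweep(-delta, 2, p$mu, "+")), p, 2L),
               tolerance = 1e-10)
})

test_that("with no coupling the stationary density factorizes into 1-D wrapped normals", {
  p <- wn_params(c(0.4, -1.1), 1.3, 0.8, 0, 0.9, 1.2)
  # independent 1-D wrapped normal oracle
  wn1d <- function(x, mu, v, K = 4) {
    log(rowSums(vapply(-K:K, function(k) {
      stats::dnorm(x - mu + 2 * pi * k, 0, sqrt(v))
    }, numeric(length(x)))))
  }
  v1 <- 0.9^2 / (2 * 1.3); v2 <- 1.2^2 / (2 * 0.8)
  set.seed(12)
  th <- matrix(runif(200, -pi, pi), ncol = 2)
  expect_equal(wn_stationary_lpdf(th, p, K = 4L),
               wn1d(th[, 1], 0.4, v1) + wn1d(th[, 2], -1.1, v2),
               tolerance = 1e-10)
})

test_that("drift weights are a probability vector concentrating at high precision", {
  p <- fig_params()
  set.seed(13)
  for (i in 1:100) {
    w <- wn_drift_weights(runif(2, -pi, pi), p, K = 1L)
    expect_true(all(w >= 0))
    expect_equal(sum(w), 1, tolerance = 1e-12)
  }
  tight <- wn_params(c(0.5, 0.5), 2, 2, 0, 0.1, 0.1)
  w <- wn_drift_weights(c(0.5, 0.5), tight, K = 2L)
  expect_gt(w[which(rowSums(abs(torusevol:::.winding_offsets(2L))) == 0)], 0.999)
  # truncation convergence: the retained weights stabilize as K grows;
  # the rate depends on the stationary concentration, so the diffuse
  # depicted parameters get a looser bound than a concentrated set
  off1 <- torusevol:::.winding_offsets(1L)
  off3 <- torusevol:::.winding_offsets(3L)
  key <- function(o) paste(round(o[, 1], 6), round(o[, 2], 6))
  w1 <- wn_drift_weights(c(1, -2), p, K = 1L)
  w3 <- wn_drift_weights(c(1, -2), p, K = 3L)
  expect_equal(w1, w3[match(key(off1), key(off3))], tolerance = 1e-4)
  conc <- wn_params(c(0, 0), 1, 0.5, 0.2, 0.6, 0.6)
  w1c <- wn_drift_weights(c(1, -2), conc, K = 1L)
  w3c <- wn_drift_weights(c(1, -2), conc, K = 3L)
  expect_lt(max(abs(w1c - w3c[match(key(off1), key(off3))])), 1e-6)
})

test_that("drift field is periodic, zero at the mean, and matches a grid oracle", {
  p <- fig_params()
  expect_equal(wn_drift(p$mu, p, K = 2L), c(0, 0), tolerance = 1e-12)
  th <- c(0.9, -2.2)
  expect_equal(wn_drift(th, p, K = 3L),
               wn_drift(wrap_angle(th + c(2 * pi, 0)), p, K = 3L),
               tolerance = 1e-10)
  # qualitative rotation: at the depicted parameters the off-diagonal
  # coupling tilts the drift; check against direct evaluation of the
  # weighted-sum formula on a grid
  A <- wn_drift_matrix(p)
  gr <- seq(-pi, pi, length.out = 11)[-11]
  for (phi in gr[c(2, 5, 9)]) for (psi in gr[c(3, 6, 10)]) {
    th <- c(phi, psi)
    w <- wn_drift_weights(th, p, K = 2L)
    offs <- torusevol:::.winding_offsets(2L)
    dev <- sweep(-offs, 2, p$mu - th, "+")
    expect_equal(wn_drift(th, p, K = 2L), as.numeric(A %*% colSums(dev * w)),
                 tolerance = 1e-12)
  }
})

test_that("transition covariance has the right small-t, large-t and mid-t behavior", {
  p <- fig_params()
  expect_equal(wn_gamma_t(p, 0), matrix(0, 2, 2))
  G <- wn_gamma_t(p, 1e-6)
  expect_equal(max(abs(G / 1e-6 - wn_sigma(p))) / max(wn_sigma(p)), 0,
               tolerance = 1e-3)
  expect_equal(wn_gamma_t(p, 50), wn_stationary_cov(p), tolerance = 1e-6)
  # quadrature oracle for mid-range t
  A <- wn_drift_matrix(p); S <- wn_sigma(p)
  quad <- matrix(0, 2, 2)
  ns <- 20000L; t <- 0.7
  for (s in (seq_len(ns) - 0.5) * (t / ns)) {
    E <- torusevol:::.expm2(-s * A)
    quad <- quad + E %*% S %*% t(E) * (t / ns)
  }
  expect_equal(wn_gamma_t(p, t), quad, tolerance = 1e-8)
  expect_error(wn_gamma_t(p, -1), ">= 0")
})

test_that("pseudo-tpd is a proper density with the documented limits", {
  p <- fig_params()
  g <- torus_grid(100)
  th1 <- c(0.3, -0.8)
  expect_equal(sum(exp(wn_pseudo_tpd_lpdf(g$points, th1, p, 0.5, K = 2L))) * g$cell,
               1, tolerance = 1e-3)
  # stationarity limit: pointwise KL on the grid
  lp_t <- wn_pseudo_tpd_lpdf(g$points, th1, p, 50, K = 2L)
  lp_s <- wn_stationary_lpdf(g$points, p, K = 2L)
  kl <- sum(exp(lp_t) * (lp_t - lp_s)) * g$cell
  expect_lt(abs(kl), 1e-6)
  # Dirac limit: nearly all mass within 0.05 rad of the start
  gfine <- torus_grid(400)
  lp0 <- wn_pseudo_tpd_lpdf(gfine$points, th1, p, 1e-4, K = 1L)
  near <- angular_distance(gfine$points, th1) < 0.05
  expect_gt(sum(exp(lp0[near])) * gfine$cell, 0.99)
  expect_error(wn_pseudo_tpd_lpdf(c(0, 0), c(0, 0), p, -0.1), ">= 0")
})

test_that("pair likelihood is time-reversible with the documented limits", {
  p <- wn_params(c(1, -2), 2, 0.7, -0.6, 0.8, 1.7)
  set.seed(14)
  for (i in 1:100) {
    a <- runif(2, -pi, pi); b <- runif(2, -pi, pi); t <- runif(1, 0.05, 5)
    expect_equal(wn_pair_lpdf(a, b, p, t), wn_pair_lpdf(b, a, p, t),
                 tolerance = 1e-8)
  }
  a <- c(0.5, 0.5); b <- c(-1, 2)
  expect_equal(wn_pair_lpdf(a, b, p, 100),
               wn_stationary_lpdf(a, p) + wn_stationary_lpdf(b, p),
               tolerance = 1e-6)
  # delta limit
  expect_identical(wn_pair_lpdf(a, a, p, 0), Inf)
  expect_identical(wn_pair_lpdf(a, b, p, 0), -Inf)
})

test_that("time-reversibility identity holds on random triples", {
  p <- fig_params()
  set.seed(15)
  for (i in 1:1000) {
    a <- runif(2, -pi, pi); b <- runif(2, -pi, pi); t <- runif(1, 0.02, 8)
    lhs <- wn_pseudo_tpd_lpdf(b, a, p, t, 1L) + wn_stationary_lpdf(a, p, 1L)
    rhs <- wn_pseudo_tpd_lpdf(a, b, p, t, 1L) + wn_stationary_lpdf(b, p, 1L)
    expect_equal(lhs, rhs, tolerance = 1e-8)
  }
})

test_that("stationary sampler is reproducible and concentrates correctly", {
  p <- fig_params()
  s1 <- wn_sample_stationary(p, 1000, seed = 21)
  s2 <- wn_sample_stationary(p, 1000, seed = 21)
  expect_identical(s1, s2)
  big <- wn_sample_stationary(p, 50000, seed = 22)
  cm <- c(atan2(mean(sin(big[, 1])), mean(cos(big[, 1]))),
          atan2(mean(sin(big[, 2])), mean(cos(big[, 2]))))
  expect_lt(max(abs(wrap_angle(cm - p$mu))), 0.03)
  tight <- wn_params(c(1, 1), 2, 2, 0, 1e-4, 1e-4)
  s <- wn_sample_stationary(tight, 200, seed = 23)
  expect_lt(max(angular_distance(s, c(1, 1))), 1e-3)
})

test_that("transition sampler matches the pseudo-tpd and its limits", {
  p <- fig_params()
  th1 <- c(0.3, -0.8)
  s0 <- wn_sample_transition(th1, p, 0, 50, seed = 24)
  expect_true(all(angular_distance(s0, th1) == 0))
  expect_identical(wn_sample_transition(th1, p, 0.5, 100, seed = 25),
                   wn_sample_transition(th1, p, 0.5, 100, seed = 25))
  # histogram against the density on a coarse grid
  n <- 50000L
  s <- wn_sample_transition(th1, p, 0.5, n, seed = 26, K = 2L)
  nb <- 20L
  br <- seq(-pi, pi, length.out = nb + 1L)
  h2 <- table(cut(s[, 1], br), cut(s[, 2], br)) / n
  centers <- (br[-1] + br[-(nb + 1)]) / 2
  gg <- as.matrix(expand.grid(centers, centers))
  pr <- exp(wn_pseudo_tpd_lpdf(gg, th1, p, 0.5, K = 2L)) * (2 * pi / nb)^2
  prm <- matrix(pr, nb, nb)
  se <- sqrt(prm * (1 - prm) / n)
  expect_lt(max(abs(h2 - prm) / pmax(se, 1e-6)), 5)
  # long-time limit indistinguishable from the stationary sampler
  sl <- wn_sample_transition(th1, p, 60, 20000, seed = 27, K = 2L)
  ss <- wn_sample_stationary(p, 20000, seed = 28)
  hl <- table(cut(sl[, 1], br), cut(sl[, 2], br))
  hs <- table(cut(ss[, 1], br), cut(ss[, 2], br))
  keep <- (hl + hs) > 10
  chi2 <- sum((hl[keep] - hs[keep])^2 / (hl[keep] + hs[keep]))
  expect_lt(chi2, sum(keep) + 5 * sqrt(2 * sum(keep)))
})

test_that("Euler-Maruyama endpoints agree with the pseudo-tpd", {
  p <- fig_params()
  th1 <- c(0.3, -0.8)
  for (t in c(0.05, 0.5)) {
    n <- 4000L
    em <- wn_simulate_em(th1, p, t, dt = 1e-3, n = n, seed = 29, K = 1L)
    nb <- 8L
    br <- seq(-pi, pi, length.out = nb + 1L)
    h2 <- as.numeric(table(cut(em[, 1], br), cut(em[, 2], br))) / n
    # integrate the density over each cell on a fine midpoint grid
    sub <- 16L
    g <- torus_grid(nb * sub)
    dens <- exp(wn_pseudo_tpd_lpdf(g$points, th1, p, t, K = 2L)) * g$cell
    cell_of <- function(x) pmin(findInterval(x, br), nb)
    idx <- cell_of(g$points[, 1]) + nb * (cell_of(g$points[, 2]) - 1L)
    pr <- as.numeric(tapply(dens, idx, sum))
    se <- sqrt(pr * (1 - pr) / n)
    # compare where the density carries real mass: the pseudo-tpd is an
    # approximation whose known deviation from the exact dynamics sits in
    # the far tails
    keep <- pr >= 1e-3
    expect_lt(max(abs(h2 - pr)[keep] / se[keep]), 5)
  }
})

test_that("Chapman-Kolmogorov holds approximately for the pseudo-tpd", {
  # the pseudo-tpd is approximate by construction; record the discrepancy
  # and require it to be small rather than exact
  p <- fig_params()
  g <- torus_grid(60)
  th1 <- c(0.3, -0.8); th3 <- c(-1.2, 1.9)
  s <- 0.3; t <- 0.4
  mid <- exp(wn_pseudo_tpd_lpdf(g$points, th1, p, s, K = 1L)) *
    exp(wn_pseudo_tpd_lpdf(th3, g$points, p, t, K = 1L))
  ck <- sum(mid) * g$cell
  direct <- exp(wn_pseudo_tpd_lpdf(th3, th1, p, s + t, K = 1L))
  expect_equal(ck, direct, tolerance = 0.05)
})
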