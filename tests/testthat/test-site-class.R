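test_that("site-class pair distribution has the documented endpoints", {
  m <- random_model(1, seed = 8)
  h <- m$states[[1]]
  p1 <- h$class_equilibrium[1]; p2 <- h$class_equilibrium[2]
  expect_equal(unname(site_class_pair_probs(h, 0)), c(p1, 0, 0, p2))
  expect_equal(unname(site_class_pair_probs(h, 1e6)),
               c(p1^2, p1 * p2, p1 * p2, p2^2), tolerance = 1e-12)
  for (t in c(0.01, 0.1, 1, 7)) {
    pr <- site_class_pair_probs(h, t)
    expect_equal(sum(pr), 1, tolerance = 1e-12)
    expect_equal(pr[["12"]], pr[["21"]])
    # marginals equal the class equilibrium on both sides
    expect_equal(unname(pr[["11"]] + pr[["12"]]), p1, tolerance = 1e-12)
    expect_equal(unname(pr[["11"]] + pr[["21"]]), p1, tolerance = 1e-12)
  }
  expect_error(site_class_pair_probs(h, -1), ">= 0")
})

test_that("discordant-pair curves coincide at the printed state parameters", {
  # equilibria 0.691/0.309 and jump rate 31.76: the two discordant-pair
  # probability curves superimpose exactly at all times
  cls <- random_model(1, seed = 9)$states[[1]]$classes
  h <- hidden_state(cls[[1]], cls[[2]], c(0.691, 0.309), 31.76)
  ts <- seq(0, 0.5, length.out = 50)
  p12 <- vapply(ts, function(t) site_class_pair_probs(h, t)[["12"]], numeric(1))
  p21 <- vapply(ts, function(t) site_class_pair_probs(h, t)[["21"]], numeric(1))
  expect_equal(p12, p21)
})

test_that("constant-evolution likelihood factorizes over observation types", {
  m <- random_model(1, seed = 10)
  sc <- m$states[[1]]$classes[[1]]
  sim <- simulate_pair(m, 30, 0.5, seed = 11)
  o <- sim$obs
  t <- 0.5
  full <- obs_pair_loglik_constant(o, sc, t, m$S, m$V)
  # factor-by-factor oracle
  aa_chain <- reversible_ctmc(m$S, sc$aa_equilibrium, sc$aa_scale)
  ss_chain <- reversible_ctmc(m$V, sc$ss_equilibrium, 1)
  oracle <- ctmc_pair_loglik(o$aa_a, o$aa_b, aa_chain, t) +
    ctmc_pair_loglik(o$ss_a, o$ss_b, ss_chain, t) +
    wn_pair_lpdf(cbind(o$phi_a, o$psi_a), cbind(o$phi_b, o$psi_b), sc$wn, t)
  expect_equal(full, unname(oracle), tolerance = 1e-10)
  # empty product: all fields missing
  expect_equal(obs_pair_loglik_constant(obs_pairs(n = 3), sc, t, m$S, m$V),
               rep(0, 3))
  # amino acids only
  oa <- obs_pairs(aa_a = o$aa_a, aa_b = o$aa_b)
  expect_equal(obs_pair_loglik_constant(oa, sc, t, m$S, m$V),
               unname(ctmc_pair_loglik(o$aa_a, o$aa_b, aa_chain, t)),
               tolerance = 1e-10)
})

test_that("jump likelihood is a time-free product of stationary terms", {
  m <- random_model(1, seed = 12)
  st <- m$states[[1]]
  sim <- simulate_pair(m, 20, 0.3, seed = 13)
  o <- sim$obs
  j1 <- obs_pair_loglik_jump(o, st$classes[[1]], st$classes[[2]], m$S, m$V)
  # no dependence on t by construction: recompute after changing nothing
  # else but going through the full mixture at two times
  sc_a <- st$classes[[1]]; sc_b <- st$classes[[2]]
  # term-by-term oracle: six stationary factors
  oracle <- log(sc_a$aa_equilibrium[o$aa_a]) + log(sc_b$aa_equilibrium[o$aa_b]) +
    log(sc_a$ss_equilibrium[o$ss_a]) + log(sc_b$ss_equilibrium[o$ss_b]) +
    wn_stationary_lpdf(cbind(o$phi_a, o$psi_a), sc_a$wn) +
    wn_stationary_lpdf(cbind(o$phi_b, o$psi_b), sc_b$wn)
  expect_equal(j1, unname(oracle), tolerance = 1e-10)
  # amino-acid-only input
  oa <- obs_pairs(aa_a = o$aa_a, aa_b = o$aa_b)
  expect_equal(obs_pair_loglik_jump(oa, sc_a, sc_b, m$S, m$V),
               unname(log(sc_a$aa_equilibrium[o$aa_a]) +
                        log(sc_b$aa_equilibrium[o$aa_b])),
               tolerance = 1e-12)
})

test_that("site marginal equals the explicit four-term mixture", {
  set.seed(14)
  for (rep in 1:4) {
    m <- random_model(1, seed = 14 + rep)
    st <- m$states[[1]]
    t <- runif(1, 0.05, 2)
    o <- simulate_pair(m, 50, t, seed = 30 + rep)$obs
    # randomly blank some fields to exercise the missing-data contract
    mask <- function(v) ifelse(runif(length(v)) < 0.3, NA, v)
    o$aa_a <- mask(o$aa_a); o$aa_b <- mask(o$aa_b)
    o$ss_a <- mask(o$ss_a); o$ss_b <- mask(o$ss_b)
    drop_x <- runif(nrow(o)) < 0.3
    o$phi_a[drop_x] <- NA; o$psi_a[drop_x] <- NA
    w4 <- site_class_pair_probs(st, t)
    br <- cbind(
      obs_pair_loglik_constant(o, st$classes[[1]], t, m$S, m$V),
      obs_pair_loglik_jump(o, st$classes[[1]], st$classes[[2]], m$S, m$V),
      obs_pair_loglik_jump(o, st$classes[[2]], st$classes[[1]], m$S, m$V),
      obs_pair_loglik_constant(o, st$classes[[2]], t, m$S, m$V))
    manual <- log(exp(sweep(br, 2, log(w4), "+")) %*% rep(1, 4))[, 1]
    expect_equal(obs_pair_loglik(o, st, t, m$S, m$V), manual, tolerance = 1e-10)
    # swapping sides never changes the likelihood
    expect_equal(obs_pair_loglik(obs_swap(o), st, t, m$S, m$V),
                 obs_pair_loglik(o, st, t, m$S, m$V), tolerance = 1e-10)
  }
})

test_that("gamma -> 0 reduces the mixture to the two constant branches", {
  m <- random_model(1, seed = 19)
  st0 <- m$states[[1]]
  st <- hidden_state(st0$classes[[1]], st0$classes[[2]],
                     st0$class_equilibrium, 1e-30)
  o <- simulate_pair(m, 10, 0.4, seed = 20)$obs
  lw <- log(st$class_equilibrium)
  expected <- apply(cbind(
    lw[1] + obs_pair_loglik_constant(o, st$classes[[1]], 0.4, m$S, m$V),
    lw[2] + obs_pair_loglik_constant(o, st$classes[[2]], 0.4, m$S, m$V)),
    1, logsumexp)
  expect_equal(obs_pair_loglik(o, st, 0.4, m$S, m$V), expected,
               tolerance = 1e-6)
})

test_that("site-class posterior is the Bayes posterior", {
  set.seed(21)
  for (rep in 1:4) {
    m <- random_model(1, seed = 40 + rep)
    st <- m$states[[1]]
    t <- runif(1, 0.05, 2)
    o <- simulate_pair(m, 50, t, seed = 50 + rep)$obs
    w4 <- site_class_pair_probs(st, t)
    br <- cbind(
      obs_pair_loglik_constant(o, st$classes[[1]], t, m$S, m$V),
      obs_pair_loglik_jump(o, st$classes[[1]], st$classes[[2]], m$S, m$V),
      obs_pair_loglik_jump(o, st$classes[[2]], st$classes[[1]], m$S, m$V),
      obs_pair_loglik_constant(o, st$classes[[2]], t, m$S, m$V))
    lj <- sweep(br, 2, log(w4), "+")
    brute <- exp(lj) / rowSums(exp(lj))
    post <- posterior_site_class_pair(o, st, t, m$S, m$V)
    expect_equal(unname(post), unname(brute), tolerance = 1e-8)
    expect_equal(rowSums(post), rep(1, nrow(o)), tolerance = 1e-10)
  }
  # no observations: posterior equals the prior
  m <- random_model(1, seed = 60)
  st <- m$states[[1]]
  post0 <- posterior_site_class_pair(obs_pairs(n = 1), st, 0.7, m$S, m$V)
  expect_equal(post0[1, ], site_class_pair_probs(st, 0.7),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("posterior concentrates on (2,2) when both sides favor class 2", {
  # classes with well-separated angle basins; observations in class 2's
  # basin on both sides at a tiny evolutionary time
  c1 <- site_class(rep(0.05, 20), 1, c(1, 1, 1) / 3,
                   wn_params(c(-1, -1), 2, 2, 0, 0.4, 0.4))
  c2 <- site_class(rep(0.05, 20), 1, c(1, 1, 1) / 3,
                   wn_params(c(2, 2), 2, 2, 0, 0.4, 0.4))
  st <- hidden_state(c1, c2, c(0.5, 0.5), 1)
  o <- obs_pairs(x_a = matrix(c(2, 2), 1), x_b = matrix(c(2, 2), 1))
  m <- random_model(1, seed = 61)
  post <- posterior_site_class_pair(o, st, 0.01, m$S, m$V)
  expect_gt(post[1, "22"], 0.99)
})

test_that("sampled sites follow the site-class pair distribution", {
  m <- random_model(1, seed = 62)
  st <- m$states[[1]]
  # t = 0: both sides identical in every field
  for (i in 1:20) {
    s <- sample_site(st, 0, m$S, m$V, seed = i)
    expect_identical(s$obs$aa_a, s$obs$aa_b)
    expect_identical(s$obs$ss_a, s$obs$ss_b)
    expect_equal(angular_distance(c(s$obs$phi_a, s$obs$psi_a),
                                  c(s$obs$phi_b, s$obs$psi_b)), 0)
  }
  # jump frequency matches the prior within Monte-Carlo error
  t <- 0.25
  n <- 20000L
  draws <- withr::with_seed(63, {
    replicate(n, {
      pr <- site_class_pair_probs(st, t)
      idx <- sample.int(4, 1, prob = pr)
      idx %in% c(2, 3)
    })
  })
  pj <- sum(site_class_pair_probs(st, t)[c("12", "21")])
  se <- sqrt(pj * (1 - pj) / n)
  expect_lt(abs(mean(draws) - pj), 3 * se)
  # conditioning on side a's fields leaves them unchanged
  cond <- simulate_pair(m, 1, 0.4, seed = 64)$obs
  cond$aa_b <- NA; cond$ss_b <- NA; cond$phi_b <- NA; cond$psi_b <- NA
  s <- sample_site(st, 0.4, m$S, m$V, seed = 65, condition = cond)
  expect_identical(s$obs$aa_a, cond$aa_a)
  expect_identical(s$obs$ss_a, cond$ss_a)
  expect_identical(s$obs$phi_a, cond$phi_a)
  expect_false(is.na(s$obs$aa_b))
})

test_that("summing over all amino-acid pairs gives total mass 1", {
  m <- random_model(1, seed = 66)
  st <- m$states[[1]]
  grid <- expand.grid(a = AA_ALPHABET, b = AA_ALPHABET,
                      stringsAsFactors = FALSE)
  o <- obs_pairs(aa_a = grid$a, aa_b = grid$b)
  ll <- obs_pair_loglik(o, st, 0.8, m$S, m$V)
  expect_equal(sum(exp(ll)), 1, tolerance = 1e-10)
})
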