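#' Site-class: one coupled parameter bundle
#'
#' A site-class couples the three per-site evolutionary processes: an
#' amino-acid equilibrium (with its rate scale, applied to the global
#' exchangeability matrix), a secondary-structure equilibrium, and a
#' wrapped-normal diffusion for the dihedral angles. Each hidden state
#' holds two site-classes; a difference in site-class between the two
#' proteins at a site is a jump event.
#'
#' @param aa_equilibrium length-20 probability vector (order `AA_ALPHABET`).
#' @param aa_scale positive amino-acid rate multiplier.
#' @param ss_equilibrium length-3 probability vector (order `SS_ALPHABET`).
#' @param wn a `"wn_params"` object for the dihedral-angle diffusion.
#' @return object of class `"site_class"`.
#' @export
site_class <- function(aa_equilibrium, aa_scale, ss_equilibrium, wn) {
  stopifnot(length(aa_equilibrium) == 20L, length(ss_equilibrium) == 3L)
  if (any(aa_equilibrium <= 0) || abs(sum(aa_equilibrium) - 1) > 1e-8) {
    stop("site_class: aa_equilibrium must be a positive probability vector")
  }
  if (any(ss_equilibrium <= 0) || abs(sum(ss_equilibrium) - 1) > 1e-8) {
    stop("site_class: ss_equilibrium must be a positive probability vector")
  }
  if (!is.finite(aa_scale) || aa_scale <= 0) stop("site_class: aa_scale must be > 0")
  validate_wn_params(wn)
  structure(list(
    aa_equilibrium = stats::setNames(as.numeric(aa_equilibrium) /
                                       sum(aa_equilibrium), AA_ALPHABET),
    aa_scale = aa_scale,
    ss_equilibrium = stats::setNames(as.numeric(ss_equilibrium) /
                                       sum(ss_equilibrium), SS_ALPHABET),
    wn = wn), class = "site_class")
}

#' Evolutionary hidden state
#'
#' One HMM state: two site-classes, their equilibrium probabilities
#' `(pi1, pi2)`, and the jump rate `gamma` governing how quickly the
#' site-class identity decorrelates along the evolutionary time separating
#' the two proteins.
#'
#' @param class1,class2 `"site_class"` objects.
#' @param class_equilibrium length-2 probability vector `(pi1, pi2)`.
#' @param jump_rate positive jump rate gamma.
#' @return object of class `"hidden_state"`.
#' @export
hidden_state <- function(class1, class2, class_equilibrium = c(0.5, 0.5),
                         jump_rate = 1) {
  stopifnot(inherits(class1, "site_class"), inherits(class2, "site_class"))
  if (length(class_equilibrium) != 2L || any(class_equilibrium <= 0) ||
      abs(sum(class_equilibrium) - 1) > 1e-8) {
    stop("hidden_state: class_equilibrium must be a positive 2-simplex point")
  }
  if (!is.finite(jump_rate) || jump_rate <= 0) {
    stop("hidden_state: jump_rate must be > 0")
  }
  structure(list(classes = list(class1, class2),
                 class_equilibrium = as.numeric(class_equilibrium) /
                   sum(class_equilibrium),
                 jump_rate = jump_rate),
            class = "hidden_state")
}

#' Joint distribution over the site-class pair
#'
#' Probabilities of the four site-class pairs `(1,1), (1,2), (2,1), (2,2)`
#' at evolutionary time t, under the reversible jump kernel
#' \deqn{p(r_a \mid r_b, t) = e^{-\gamma t}\,1[r_a = r_b] +
#'   \pi_{r_a} (1 - e^{-\gamma t}),}
#' with the starting class drawn from `(pi1, pi2)`. The kernel normalizes,
#' satisfies detailed balance (so `p(1,2) = p(2,1)` for all t), and gives
#' `(pi1, 0, 0, pi2)` at `t = 0` and the independence products as
#' `t -> Inf`.
#'
#' @param h a `"hidden_state"`.
#' @param t evolutionary time, `t >= 0`.
#' @return named numeric vector of 4 probabilities summing to 1, in the
#'   order `c("11", "12", "21", "22")`.
#' @export
site_class_pair_probs <- function(h, t) {
  if (t < 0) stop("site_class_pair_probs: t must be >= 0")
  e <- exp(-h$jump_rate * t)
  p1 <- h$class_equilibrium[1]; p2 <- h$class_equilibrium[2]
  c("11" = p1 * (e + p1 * (1 - e)),
    "12" = p1 * p2 * (1 - e),
    "21" = p1 * p2 * (1 - e),
    "22" = p2 * (e + p2 * (1 - e)))
}

# ---- Vectorized per-site likelihood terms --------------------------------
#
# For an obs_pairs table and one site-class, computes per site:
#   const  : log-lik under constant evolution (shared class, time t); each
#            factor drops to its single-sided stationary log-density when
#            one side is missing and is omitted when both sides are missing
#   stat_a : single-sided stationary log-lik of side a's observed fields
#   stat_b : same for side b
# The jump branch for classes (ca, cb) is stat_a(ca) + stat_b(cb) and does
# not depend on t.
.sc_terms <- function(o, sc, t, S, V, K = 1L) {
  n <- nrow(o)
  aa_chain <- reversible_ctmc(S, sc$aa_equilibrium, sc$aa_scale, AA_ALPHABET)
  ss_chain <- reversible_ctmc(V, sc$ss_equilibrium, 1, SS_ALPHABET)
  Pa <- ctmc_transition_matrix(aa_chain, t)
  Ps <- ctmc_transition_matrix(ss_chain, t)
  lpi_aa <- log(sc$aa_equilibrium)
  lpi_ss <- log(sc$ss_equilibrium)

  disc_terms <- function(sa, sb, alphabet, lpi, P) {
    ia <- match(sa, alphabet); ib <- match(sb, alphabet)
    both <- !is.na(ia) & !is.na(ib)
    ca <- ifelse(is.na(ia), 0, lpi[pmax(ia, 1L)])
    cb <- ifelse(is.na(ib), 0, lpi[pmax(ib, 1L)])
    const <- ca + cb
    const[both] <- lpi[ia[both]] + log(P[cbind(ia[both], ib[both])])
    list(const = const, stat_a = ca, stat_b = cb)
  }
  aa <- disc_terms(o$aa_a, o$aa_b, AA_ALPHABET, lpi_aa, Pa)
  ss <- disc_terms(o$ss_a, o$ss_b, SS_ALPHABET, lpi_ss, Ps)

  ha <- !is.na(o$phi_a); hb <- !is.na(o$phi_b)
  sx_a <- numeric(n); sx_b <- numeric(n); cx <- numeric(n)
  if (any(ha)) {
    sx_a[ha] <- wn_stationary_lpdf(cbind(o$phi_a[ha], o$psi_a[ha]), sc$wn, K)
  }
  if (any(hb)) {
    sx_b[hb] <- wn_stationary_lpdf(cbind(o$phi_b[hb], o$psi_b[hb]), sc$wn, K)
  }
  cx <- sx_a + sx_b
  both <- ha & hb
  if (any(both)) {
    cx[both] <- wn_pair_lpdf(cbind(o$phi_a[both], o$psi_a[both]),
                             cbind(o$phi_b[both], o$psi_b[both]), sc$wn, t, K)
  }
  list(const = aa$const + ss$const + cx,
       stat_a = aa$stat_a + ss$stat_a + sx_a,
       stat_b = aa$stat_b + ss$stat_b + sx_b)
}

# Per-site log-likelihood vector and per-site 4-column branch matrix for
# one hidden state. Returns list(loglik (n), branches (n x 4 log joint
# lik*prior), terms (per-class .sc_terms)).
.state_site_lik <- function(o, h, t, S, V, K = 1L) {
  w4 <- site_class_pair_probs(h, t)
  t1 <- .sc_terms(o, h$classes[[1]], t, S, V, K)
  t2 <- .sc_terms(o, h$classes[[2]], t, S, V, K)
  br <- cbind(t1$const, t1$stat_a + t2$stat_b,
              t2$stat_a + t1$stat_b, t2$const)
  lj <- sweep(br, 2L, log(w4), "+")
  ll <- .logsumexp_rows(lj)
  # non-homologous columns: single-sided mixture over the class equilibrium
  nh <- !o$homologous
  if (any(nh)) {
    has_a <- !is.na(o$aa_a) | !is.na(o$phi_a) | !is.na(o$ss_a)
    side_a <- nh & has_a
    side_b <- nh & !has_a
    lp <- log(h$class_equilibrium)
    if (any(side_a)) {
      ll[side_a] <- .logsumexp_rows(cbind(lp[1] + t1$stat_a[side_a],
                                          lp[2] + t2$stat_a[side_a]))
    }
    if (any(side_b)) {
      ll[side_b] <- .logsumexp_rows(cbind(lp[1] + t1$stat_b[side_b],
                                          lp[2] + t2$stat_b[side_b]))
    }
    lj[nh, ] <- NA_real_
  }
  list(loglik = ll, branches = lj, t1 = t1, t2 = t2)
}

#' Log-likelihood of a site observation pair under constant evolution
#'
#' The constant-evolution branch: both proteins share site-class `sc` and
#' the three observation-pair factors (amino acid, dihedral angles,
#' secondary structure) are evaluated under their time-t transition kernels
#' and multiplied. A factor is replaced by its single-sided stationary
#' density when observed on one side only, and dropped when missing on
#' both sides.
#'
#' @param o an `"obs_pairs"` data.frame (all rows evaluated).
#' @param sc a `"site_class"`.
#' @param t evolutionary time.
#' @param S,V global amino-acid (20 x 20) and secondary-structure (3 x 3)
#'   exchangeability matrices.
#' @param K winding truncation for the dihedral factor.
#' @return numeric vector of per-site log-likelihoods.
#' @export
obs_pair_loglik_constant <- function(o, sc, t, S, V, K = 1L) {
  .sc_terms(validate_obs_pairs(o), sc, t, S, V, K)$const
}

#' Log-likelihood of a site observation pair under a jump event
#'
#' After a jump the two sides are independent draws from the stationary
#' laws of their own site-classes, so the value is a sum of single-sided
#' stationary log-densities and does not depend on the evolutionary time.
#'
#' @param o an `"obs_pairs"` data.frame.
#' @param sc_a,sc_b `"site_class"` objects for sides a and b.
#' @inheritParams obs_pair_loglik_constant
#' @return numeric vector of per-site log-likelihoods.
#' @export
obs_pair_loglik_jump <- function(o, sc_a, sc_b, S, V, K = 1L) {
  o <- validate_obs_pairs(o)
  ta <- .sc_terms(o, sc_a, 1, S, V, K)
  tb <- .sc_terms(o, sc_b, 1, S, V, K)
  ta$stat_a + tb$stat_b
}

#' Marginal log-likelihood of a site observation pair given a hidden state
#'
#' Sums the constant-evolution and jump branches over the four site-class
#' pairs weighted by [site_class_pair_probs()]. Non-homologous columns
#' (insertions/deletions) contribute the single-sided stationary mixture
#' over the two site-classes.
#'
#' @param o an `"obs_pairs"` data.frame.
#' @param h a `"hidden_state"`.
#' @inheritParams obs_pair_loglik_constant
#' @return numeric vector of per-site log-likelihoods.
#' @export
obs_pair_loglik <- function(o, h, t, S, V, K = 1L) {
  .state_site_lik(validate_obs_pairs(o), h, t, S, V, K)$loglik
}

#' Posterior distribution over the site-class pair
#'
#' Bayes posterior over the four site-class pairs given the observations at
#' each (homologous) site; the posterior jump probability summed over the
#' discordant pairs is the evolutionary-motif detection statistic.
#'
#' @inheritParams obs_pair_loglik
#' @return n x 4 matrix of posterior probabilities (columns `11, 12, 21,
#'   22`), each row summing to 1; NA rows for non-homologous columns.
#' @export
posterior_site_class_pair <- function(o, h, t, S, V, K = 1L) {
  lj <- .state_site_lik(validate_obs_pairs(o), h, t, S, V, K)$branches
  post <- exp(lj - .logsumexp_rows(lj))
  colnames(post) <- c("11", "12", "21", "22")
  post
}

#' Sample one site observation pair from a hidden state
#'
#' Generative counterpart of the site likelihood: draws the site-class pair
#' from its prior (or from its posterior given any observed fields in
#' `condition`), then fills each missing field. Under constant evolution
#' the ancestral side is drawn from the stationary law and the descendant
#' side from the time-t transition kernel (either side may condition the
#' other by reversibility); under a jump each side is drawn from its own
#' class's stationary law. Observed fields are never altered.
#'
#' @param h a `"hidden_state"`.
#' @param t evolutionary time.
#' @param S,V global exchangeability matrices.
#' @param seed optional integer seed.
#' @param condition optional single-row `"obs_pairs"` data.frame of
#'   observed fields to keep and condition on.
#' @param K winding truncation.
#' @return list with the completed single-row `"obs_pairs"` and the drawn
#'   site-class pair `c(ra, rb)`.
#' @export
sample_site <- function(h, t, S, V, seed = NULL, condition = NULL, K = 1L) {
  .with_seed(seed, {
    if (is.null(condition)) {
      condition <- obs_pairs(n = 1L)
      pr <- site_class_pair_probs(h, t)
    } else {
      stopifnot(nrow(condition) == 1L)
      pr <- posterior_site_class_pair(condition, h, t, S, V, K)[1L, ]
    }
    idx <- sample.int(4L, 1L, prob = pr)
    rab <- list(c(1L, 1L), c(1L, 2L), c(2L, 1L), c(2L, 2L))[[idx]]
    o <- .fill_site(condition, h, rab[1], rab[2], t, S, V, K)
    list(obs = o, classes = rab)
  })
}

# Precompute the discrete transition kernels used by repeated imputation
# from one hidden state at a fixed time.
.state_kernels <- function(h, t, S, V) {
  lapply(1:2, function(cl) {
    sc <- h$classes[[cl]]
    list(aa_eq = sc$aa_equilibrium,
         aa_P = ctmc_transition_matrix(
           reversible_ctmc(S, sc$aa_equilibrium, sc$aa_scale, AA_ALPHABET), t),
         ss_eq = sc$ss_equilibrium,
         ss_P = ctmc_transition_matrix(
           reversible_ctmc(V, sc$ss_equilibrium, 1, SS_ALPHABET), t))
  })
}

# Impute the missing fields of a single obs row given the site-class pair.
# Uses the ambient RNG stream (callers manage seeding).
.fill_site <- function(o, h, ra, rb, t, S, V, K = 1L, kernels = NULL) {
  if (is.null(kernels)) kernels <- .state_kernels(h, t, S, V)
  sc_a <- h$classes[[ra]]; sc_b <- h$classes[[rb]]
  ka <- kernels[[ra]]; kb <- kernels[[rb]]
  jump <- ra != rb
  # amino acids
  o$aa_a <- .fill_disc(o$aa_a, o$aa_b, ka$aa_eq, ka$aa_P, jump)
  o$aa_b <- .fill_disc(o$aa_b, o$aa_a, kb$aa_eq, kb$aa_P, jump)
  # secondary structure
  o$ss_a <- .fill_disc(o$ss_a, o$ss_b, ka$ss_eq, ka$ss_P, jump)
  o$ss_b <- .fill_disc(o$ss_b, o$ss_a, kb$ss_eq, kb$ss_P, jump)
  # dihedral angles
  xa_missing <- is.na(o$phi_a); xb_missing <- is.na(o$phi_b)
  if (jump) {
    if (xa_missing) {
      v <- wn_sample_stationary(sc_a$wn, 1L)
      o$phi_a <- v[1]; o$psi_a <- v[2]
    }
    if (xb_missing) {
      v <- wn_sample_stationary(sc_b$wn, 1L)
      o$phi_b <- v[1]; o$psi_b <- v[2]
    }
  } else {
    if (xa_missing && xb_missing) {
      va <- wn_sample_stationary(sc_a$wn, 1L)
      vb <- wn_sample_transition(as.numeric(va), sc_a$wn, t, 1L, K = K)
      o$phi_a <- va[1]; o$psi_a <- va[2]; o$phi_b <- vb[1]; o$psi_b <- vb[2]
    } else if (xa_missing) {
      va <- wn_sample_transition(c(o$phi_b, o$psi_b), sc_a$wn, t, 1L, K = K)
      o$phi_a <- va[1]; o$psi_a <- va[2]
    } else if (xb_missing) {
      vb <- wn_sample_transition(c(o$phi_a, o$psi_a), sc_a$wn, t, 1L, K = K)
      o$phi_b <- vb[1]; o$psi_b <- vb[2]
    }
  }
  o
}

# Fill one side of a discrete pair. `own`/`other` are scalar states or NA;
# eq/P are this side's class equilibrium and time-t transition matrix.
.fill_disc <- function(own, other, eq, P, jump) {
  if (!is.na(own)) return(own)
  if (jump || is.na(other)) {
    # jump: own stationary; constant with both missing: draw marginal
    return(sample(names(eq), 1L, prob = eq))
  }
  # constant evolution conditioned on the partner: by reversibility the
  # conditional is the partner's transition row (shared class)
  sample(colnames(P), 1L, prob = P[match(other, rownames(P)), ])
}
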