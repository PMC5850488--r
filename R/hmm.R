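# ---- Emission computation ------------------------------------------------

# Per-site, per-state emission log-likelihoods (m x h), with the per-state
# branch matrices retained for posterior computations.
.emissions <- function(o, m, t) {
  h <- n_states(m)
  res <- lapply(m$states, function(st) {
    .state_site_lik(o, st, t, m$S, m$V, m$K)
  })
  E <- vapply(res, function(r) r$loglik, numeric(nrow(o)))
  if (nrow(o) == 1L) E <- matrix(E, nrow = 1L)
  list(E = E, per_state = res)
}

.logsumexp <- function(x) {
  mx <- max(x)
  if (!is.finite(mx)) return(mx)
  mx + log(sum(exp(x - mx)))
}

# Forward pass in log space: returns alpha (m x h) and the log-likelihood.
.forward <- function(E, lT, linit) {
  n <- nrow(E); h <- ncol(E)
  alpha <- matrix(-Inf, n, h)
  alpha[1, ] <- linit + E[1, ]
  if (n > 1L) {
    for (i in 2:n) {
      for (k in seq_len(h)) {
        alpha[i, k] <- .logsumexp(alpha[i - 1, ] + lT[, k])
      }
      alpha[i, ] <- alpha[i, ] + E[i, ]
    }
  }
  list(alpha = alpha, loglik = .logsumexp(alpha[n, ]))
}

.backward <- function(E, lT) {
  n <- nrow(E); h <- ncol(E)
  beta <- matrix(0, n, h)
  if (n > 1L) {
    for (i in (n - 1L):1L) {
      for (k in seq_len(h)) {
        beta[i, k] <- .logsumexp(lT[k, ] + E[i + 1, ] + beta[i + 1, ])
      }
    }
  }
  beta
}

#' HMM log-likelihood of an aligned observation sequence
#'
#' Forward recursion over the hidden states for a fixed alignment: computes
#' `log p(observations | model, t)`, marginalizing the hidden path and, at
#' each site, the site-class pair. Numerically stable in log space for long
#' alignments.
#'
#' @param o an `"obs_pairs"` data.frame (one row per alignment column).
#' @param m an `"evo_model"`.
#' @param t evolutionary time separating the two proteins, `t >= 0`.
#' @return log-likelihood (scalar).
#' @export
forward_loglik <- function(o, m, t) {
  o <- validate_obs_pairs(o)
  if (nrow(o) == 0L) stop("forward_loglik: empty observation sequence")
  em <- .emissions(o, m, t)
  .forward(em$E, log(m$transition), log(m$initial))$loglik
}

#' Posterior distribution over hidden states at each site
#'
#' Forward-backward smoothing: returns `p(H_i = k | observations)` for
#' every aligned site i and hidden state k.
#'
#' @inheritParams forward_loglik
#' @return m x h matrix of posteriors; each row sums to 1.
#' @export
posterior_hidden <- function(o, m, t) {
  o <- validate_obs_pairs(o)
  em <- .emissions(o, m, t)
  lT <- log(m$transition)
  fw <- .forward(em$E, lT, log(m$initial))
  bw <- .backward(em$E, lT)
  lp <- fw$alpha + bw - fw$loglik
  post <- exp(lp)
  post / rowSums(post)
}

#' Joint posterior of hidden state and jump event
#'
#' Per site, the joint posterior `p(H_i = k, r_a != r_b | observations)`
#' combining the hidden-state smoothing posterior with the per-state
#' posterior over site-class pairs. This is the detection statistic for
#' jump-event evolutionary motifs.
#'
#' @inheritParams forward_loglik
#' @return m x h matrix; entry (i, k) is the joint posterior probability of
#'   being in state k with a jump at site i. Rows of the full
#'   (state x jump/no-jump) table sum to 1, so the returned entries are
#'   bounded by the state posteriors.
#' @export
posterior_jump <- function(o, m, t) {
  o <- validate_obs_pairs(o)
  em <- .emissions(o, m, t)
  lT <- log(m$transition)
  fw <- .forward(em$E, lT, log(m$initial))
  bw <- .backward(em$E, lT)
  post_h <- exp(fw$alpha + bw - fw$loglik)
  post_h <- post_h / rowSums(post_h)
  jump_given_state <- vapply(em$per_state, function(r) {
    lj <- r$branches
    pj <- exp(lj - .logsumexp_rows(lj))
    out <- pj[, 2] + pj[, 3]
    out[is.na(out)] <- 0  # non-homologous columns carry no pair
    out
  }, numeric(nrow(o)))
  if (nrow(o) == 1L) jump_given_state <- matrix(jump_given_state, nrow = 1L)
  post_h * jump_given_state
}

# Forward-filter backward-sample of the hidden path (ambient RNG).
.sample_hidden_path <- function(E, lT, linit) {
  n <- nrow(E); h <- ncol(E)
  fw <- .forward(E, lT, linit)
  path <- integer(n)
  lw <- fw$alpha[n, ]
  path[n] <- sample.int(h, 1L, prob = exp(lw - max(lw)))
  if (n > 1L) {
    for (i in (n - 1L):1L) {
      lw <- fw$alpha[i, ] + lT[, path[i + 1L]]
      path[i] <- sample.int(h, 1L, prob = exp(lw - max(lw)))
    }
  }
  path
}

#' Impute missing observations by conditional simulation
#'
#' Samples completions of an aligned observation sequence with missing
#' fields: forward-filter backward-sample of the hidden path, a draw of
#' each site's site-class pair from its posterior given the observed
#' fields, then imputation of each missing field from its conditional
#' (time-t transition kernel given the observed partner under constant
#' evolution; the class's stationary law under a jump). Observed fields
#' are never altered.
#'
#' @inheritParams forward_loglik
#' @param n_samples number of independent completions.
#' @param seed optional integer seed.
#' @return list of `n_samples` completed `"obs_pairs"` data.frames.
#' @export
sample_missing <- function(o, m, t, n_samples = 1L, seed = NULL) {
  o <- validate_obs_pairs(o)
  em <- .emissions(o, m, t)
  lT <- log(m$transition)
  linit <- log(m$initial)
  kernels <- lapply(m$states, .state_kernels, t = t, S = m$S, V = m$V)
  .with_seed(seed, {
    lapply(seq_len(n_samples), function(s) {
      path <- .sample_hidden_path(em$E, lT, linit)
      rows <- vector("list", nrow(o))
      for (i in seq_len(nrow(o))) {
        st <- m$states[[path[i]]]
        row <- o[i, , drop = FALSE]
        if (row$homologous) {
          lj <- em$per_state[[path[i]]]$branches[i, ]
          pr <- exp(lj - max(lj))
          idx <- sample.int(4L, 1L, prob = pr)
          rab <- list(c(1L, 1L), c(1L, 2L), c(2L, 1L), c(2L, 2L))[[idx]]
          rows[[i]] <- .fill_site(row, st, rab[1], rab[2], t, m$S, m$V, m$K,
                                  kernels = kernels[[path[i]]])
        } else {
          rows[[i]] <- .fill_indel_site(row, st, m$S, m$V)
        }
      }
      validate_obs_pairs(do.call(rbind, rows))
    })
  })
}

# Non-homologous column: sample the class of the present side from its
# single-sided posterior and draw that side's missing fields from the
# class stationary laws. The absent side stays absent.
.fill_indel_site <- function(row, st, S, V) {
  has_a <- !is.na(row$aa_a) || !is.na(row$phi_a) || !is.na(row$ss_a)
  t1 <- .sc_terms(row, st$classes[[1]], 1, S, V)
  t2 <- .sc_terms(row, st$classes[[2]], 1, S, V)
  side <- if (has_a) "stat_a" else "stat_b"
  lw <- log(st$class_equilibrium) + c(t1[[side]], t2[[side]])
  cl <- st$classes[[sample.int(2L, 1L, prob = exp(lw - max(lw)))]]
  fill1 <- function(val, pi_v) {
    if (!is.na(val)) val else sample(names(pi_v), 1L, prob = pi_v)
  }
  if (has_a) {
    row$aa_a <- fill1(row$aa_a, cl$aa_equilibrium)
    row$ss_a <- fill1(row$ss_a, cl$ss_equilibrium)
    if (is.na(row$phi_a)) {
      v <- wn_sample_stationary(cl$wn, 1L)
      row$phi_a <- v[1]; row$psi_a <- v[2]
    }
  } else {
    row$aa_b <- fill1(row$aa_b, cl$aa_equilibrium)
    row$ss_b <- fill1(row$ss_b, cl$ss_equilibrium)
    if (is.na(row$phi_b)) {
      v <- wn_sample_stationary(cl$wn, 1L)
      row$phi_b <- v[1]; row$psi_b <- v[2]
    }
  }
  row
}

#' Simulate an aligned homologous pair from the model
#'
#' Full generative simulation for a fixed number of homologous sites: the
#' hidden path is drawn from the chain (stationary initial distribution,
#' then the transition matrix), and each site's observation pair from its
#' hidden state via the site-class mechanism.
#'
#' @param m an `"evo_model"`.
#' @param length number of aligned sites.
#' @param t evolutionary time, `t >= 0`.
#' @param seed optional integer seed.
#' @return list with `obs` (an `"obs_pairs"` data.frame), `hidden`
#'   (integer path) and `classes` (length x 2 matrix of site-class pairs).
#' @export
simulate_pair <- function(m, length, t, seed = NULL) {
  stopifnot(length >= 1L, t >= 0)
  h <- n_states(m)
  .with_seed(seed, {
    path <- integer(length)
    path[1] <- sample.int(h, 1L, prob = m$initial)
    if (length > 1L) {
      for (i in 2:length) {
        path[i] <- sample.int(h, 1L, prob = m$transition[path[i - 1L], ])
      }
    }
    classes <- matrix(0L, length, 2L)
    aa_a <- character(length); aa_b <- character(length)
    ss_a <- character(length); ss_b <- character(length)
    x_a <- matrix(0, length, 2); x_b <- matrix(0, length, 2)
    for (k in unique(path)) {
      st <- m$states[[k]]
      in_k <- which(path == k)
      pr <- site_class_pair_probs(st, t)
      idx <- sample.int(4L, base::length(in_k), replace = TRUE, prob = pr)
      classes[in_k, 1] <- c(1L, 1L, 2L, 2L)[idx]
      classes[in_k, 2] <- c(1L, 2L, 1L, 2L)[idx]
      for (cl_pair in unique(idx)) {
        rows <- in_k[idx == cl_pair]
        nr <- base::length(rows)
        ra <- c(1L, 1L, 2L, 2L)[cl_pair]; rb <- c(1L, 2L, 1L, 2L)[cl_pair]
        sc_a <- st$classes[[ra]]; sc_b <- st$classes[[rb]]
        draw_disc <- function(pi_v) {
          sample(names(pi_v), nr, replace = TRUE, prob = pi_v)
        }
        aa_a[rows] <- draw_disc(sc_a$aa_equilibrium)
        ss_a[rows] <- draw_disc(sc_a$ss_equilibrium)
        x_a[rows, ] <- wn_sample_stationary(sc_a$wn, nr)
        if (ra == rb) {
          # constant evolution: descendant side from the time-t kernels
          aa_chain <- reversible_ctmc(m$S, sc_a$aa_equilibrium, sc_a$aa_scale)
          ss_chain <- reversible_ctmc(m$V, sc_a$ss_equilibrium, 1)
          Pa <- log(ctmc_transition_matrix(aa_chain, t))
          Ps <- log(ctmc_transition_matrix(ss_chain, t))
          ia <- match(aa_a[rows], AA_ALPHABET)
          aa_b[rows] <- AA_ALPHABET[.sample_rows(Pa[ia, , drop = FALSE])]
          is_ <- match(ss_a[rows], SS_ALPHABET)
          ss_b[rows] <- SS_ALPHABET[.sample_rows(Ps[is_, , drop = FALSE])]
          x_b[rows, ] <- .wn_sample_transition_multi(x_a[rows, , drop = FALSE],
                                                     sc_a$wn, t, m$K)
        } else {
          # jump: the descendant side restarts in its own stationary laws
          aa_b[rows] <- draw_disc(sc_b$aa_equilibrium)
          ss_b[rows] <- draw_disc(sc_b$ss_equilibrium)
          x_b[rows, ] <- wn_sample_stationary(sc_b$wn, nr)
        }
      }
    }
    obs <- obs_pairs(aa_a = aa_a, aa_b = aa_b, x_a = x_a, x_b = x_b,
                     ss_a = ss_a, ss_b = ss_b)
    list(obs = obs, hidden = path, classes = classes)
  })
}

# Split a simulated homologous pair into two protein tracks.
#' Extract the two protein tracks from an aligned observation table
#'
#' @param o an `"obs_pairs"` data.frame.
#' @param ids character vector of two protein identifiers.
#' @return list of two `"protein_track"` objects (sides a and b), built
#'   from the columns where each side is present.
#' @export
obs_to_tracks <- function(o, ids = c("protein_a", "protein_b")) {
  o <- validate_obs_pairs(o)
  has_a <- !is.na(o$aa_a) | !is.na(o$phi_a) | !is.na(o$ss_a)
  has_b <- !is.na(o$aa_b) | !is.na(o$phi_b) | !is.na(o$ss_b)
  mk <- function(rows, aa, phi, psi, ss, id) {
    protein_track(id, aa[rows],
                  angles = cbind(phi[rows], psi[rows]),
                  ss = ss[rows])
  }
  list(a = mk(which(has_a), o$aa_a, o$phi_a, o$psi_a, o$ss_a, ids[1]),
       b = mk(which(has_b), o$aa_b, o$phi_b, o$psi_b, o$ss_b, ids[2]))
}
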