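#' Maximum-likelihood evolutionary time for a homologous pair
#'
#' Bounded one-dimensional search on log t of the pair's log-likelihood,
#' using either a fixed alignment (HMM forward) or the TKF92
#' alignment-marginal likelihood. Any subset of the observation tracks can
#' be used (e.g. sequences only, or dihedral angles only).
#'
#' @param o an `"obs_pairs"` data.frame (fixed-alignment mode), or NULL
#'   when `track_a`/`track_b` are given in marginalized mode.
#' @param m an `"evo_model"`.
#' @param subset character vector of tracks to condition on, from
#'   `c("aa", "angles", "ss")`; default all available.
#' @param bounds search interval for t.
#' @param alignment `"fixed"` or `"marginalized"`.
#' @param track_a,track_b `"protein_track"` objects (marginalized mode).
#' @param tkf a `"tkf92_params"` object (marginalized mode).
#' @param tol relative tolerance of the optimizer.
#' @return list with `t_hat` and the attained `loglik`.
#' @export
estimate_time <- function(o = NULL, m, subset = c("aa", "angles", "ss"),
                          bounds = c(1e-4, 20), alignment = c("fixed", "marginalized"),
                          track_a = NULL, track_b = NULL, tkf = NULL,
                          tol = 1e-6) {
  alignment <- match.arg(alignment)
  subset <- match.arg(subset, c("aa", "angles", "ss"), several.ok = TRUE)
  keep <- c(if ("aa" %in% subset) c("aa_a", "aa_b"),
            if ("angles" %in% subset) c("x_a", "x_b"),
            if ("ss" %in% subset) c("ss_a", "ss_b"))
  if (alignment == "fixed") {
    stopifnot(!is.null(o))
    o <- obs_mask(validate_obs_pairs(o), keep)
    has_a <- any(!is.na(o$aa_a)) || any(!is.na(o$phi_a)) || any(!is.na(o$ss_a))
    has_b <- any(!is.na(o$aa_b)) || any(!is.na(o$phi_b)) || any(!is.na(o$ss_b))
    if (!has_a || !has_b) {
      stop("estimate_time: no shared observation track between the proteins")
    }
    f <- function(lt) forward_loglik(o, m, exp(lt))
  } else {
    stopifnot(!is.null(track_a), !is.null(track_b), !is.null(tkf))
    mask_track <- function(tr) {
      protein_track(tr$id, tr$sequence,
                    angles = if ("angles" %in% subset) tr$angles,
                    ss = if ("ss" %in% subset) tr$ss)
    }
    ta <- mask_track(track_a); tb <- mask_track(track_b)
    f <- function(lt) alignment_forward(ta, tb, m, tkf, exp(lt))
  }
  opt <- stats::optimize(f, interval = log(bounds), maximum = TRUE, tol = tol)
  list(t_hat = exp(opt$maximum), loglik = opt$objective)
}

#' Bayesian information criterion
#'
#' `BIC = -2 loglik + p log(n)` with `p` the model's free-parameter count
#' and `n` the number of aligned site observation pairs in the dataset.
#'
#' @param m an `"evo_model"`.
#' @param n_observations number of aligned site observation pairs.
#' @param loglik total log-likelihood of the dataset under `m`.
#' @return numeric BIC (lower is better).
#' @export
bic <- function(m, n_observations, loglik) {
  -2 * loglik + count_free_parameters(m) * log(n_observations)
}

#' Configuration for stochastic-EM fitting
#'
#' @param n_hidden_states number of hidden states to fit.
#' @param em_iterations number of StEM iterations.
#' @param samples_per_estep hidden-path samples drawn per pair per E-step.
#' @param seed integer seed controlling the whole fit.
#' @param time_update_interval re-estimate per-pair evolutionary times
#'   every this many iterations (0 disables; times stay at their initial
#'   or supplied values).
#' @param n_restarts random restarts; the fit with the best final objective
#'   is kept.
#' @param update_exchangeability update S and V by expected-count
#'   reweighting (logical).
#' @param wn_maxit optimizer iteration cap for the per-class diffusion
#'   parameter updates.
#' @return list of class `"fit_config"`.
#' @export
fit_config <- function(n_hidden_states = 2L, em_iterations = 10L,
                       samples_per_estep = 1L, seed = 1L,
                       time_update_interval = 0L, n_restarts = 1L,
                       update_exchangeability = FALSE, wn_maxit = 40L) {
  stopifnot(n_hidden_states >= 1L, em_iterations >= 1L,
            samples_per_estep >= 1L, n_restarts >= 1L)
  structure(list(n_hidden_states = as.integer(n_hidden_states),
                 em_iterations = as.integer(em_iterations),
                 samples_per_estep = as.integer(samples_per_estep),
                 seed = as.integer(seed),
                 time_update_interval = as.integer(time_update_interval),
                 n_restarts = as.integer(n_restarts),
                 update_exchangeability = isTRUE(update_exchangeability),
                 wn_maxit = as.integer(wn_maxit)),
            class = "fit_config")
}

#' Fit the model by stochastic expectation-maximization
#'
#' E-step: for each pair, sample hidden paths by forward-filter
#' backward-sampling and site-class pairs from their per-site posteriors.
#' M-step: closed-form count updates for the hidden transition matrix,
#' class equilibria, amino-acid and secondary-structure equilibria;
#' numerical maximization for the per-class diffusion parameters, rate
#' scales and jump rates; optional expected-count reweighting of the
#' global exchangeability matrices. Evolutionary times are optionally
#' re-estimated by bounded 1-D search. Reproducible under the
#' configuration seed.
#'
#' @param dataset list of `"obs_pairs"` data.frames (fixed alignments).
#' @param cfg a `"fit_config"`.
#' @param times optional numeric vector of per-pair evolutionary times used
#'   as starting values (defaults to 0.3).
#' @param init optional `"evo_model"` used as the starting point.
#' @return list with the fitted `model`, per-pair `t_hat`, and the
#'   `objective` trace (complete-data log-likelihood per iteration).
#' @export
stem_fit <- function(dataset, cfg = fit_config(), times = NULL, init = NULL) {
  stopifnot(length(dataset) >= 1L)
  dataset <- lapply(dataset, validate_obs_pairs)
  any_data <- vapply(dataset, function(o) {
    any(!is.na(o$aa_a)) || any(!is.na(o$aa_b)) || any(!is.na(o$phi_a)) ||
      any(!is.na(o$phi_b)) || any(!is.na(o$ss_a)) || any(!is.na(o$ss_b))
  }, logical(1))
  if (!any(any_data)) stop("stem_fit: dataset has no observations")
  if (is.null(times)) times <- rep(0.3, length(dataset))
  stopifnot(length(times) == length(dataset))
  best <- NULL
  for (rs in seq_len(cfg$n_restarts)) {
    res <- .with_seed(cfg$seed + (rs - 1L) * 1000L, {
      .stem_fit_once(dataset, cfg, times, init, randomize = (rs > 1L || is.null(init)))
    })
    if (is.null(best) || res$objective[length(res$objective)] >
        best$objective[length(best$objective)]) {
      best <- res
    }
  }
  best
}

# One StEM run (ambient RNG; caller seeds).
.stem_fit_once <- function(dataset, cfg, times, init, randomize) {
  h <- cfg$n_hidden_states
  model <- if (!is.null(init) && !randomize) init else
    .init_from_data(dataset, h)
  objective <- numeric(0)
  for (iter in seq_len(cfg$em_iterations)) {
    stats_acc <- .empty_suffstats(h)
    obj <- 0
    for (d in seq_along(dataset)) {
      o <- dataset[[d]]
      t <- times[d]
      em <- .emissions(o, model, t)
      lT <- log(model$transition); linit <- log(model$initial)
      for (s in seq_len(cfg$samples_per_estep)) {
        path <- .sample_hidden_path(em$E, lT, linit)
        stats_acc <- .accumulate_suffstats(stats_acc, o, t, path, em, model)
      }
      fw <- .forward(em$E, lT, linit)
      # Rao-Blackwellized statistics for the chain-structure parameters:
      # exact posterior expected counts converge much faster than the
      # random walk of sampled hard counts
      stats_acc <- .accumulate_soft_stats(stats_acc, o, t, em, fw, lT, model)
      obj <- obj + fw$loglik
    }
    objective <- c(objective, obj)
    model <- .m_step(model, stats_acc, cfg)
    if (cfg$time_update_interval > 0L &&
        iter %% cfg$time_update_interval == 0L) {
      times <- vapply(dataset, function(o) {
        estimate_time(o, model, tol = 1e-4)$t_hat
      }, numeric(1))
    }
  }
  list(model = model, t_hat = times, objective = objective)
}

# Data-driven initialization: cluster the pooled dihedral observations on
# their circle embedding (k-means with 2h centers) and seed the 2h
# site-class diffusion means from the cluster centers; equilibria start
# at jittered pooled frequencies.
.init_from_data <- function(dataset, h) {
  allx <- do.call(rbind, lapply(dataset, function(o) {
    rbind(cbind(o$phi_a, o$psi_a), cbind(o$phi_b, o$psi_b))
  }))
  allx <- allx[!is.na(allx[, 1]), , drop = FALSE]
  aa_all <- unlist(lapply(dataset, function(o) c(o$aa_a, o$aa_b)))
  aa_freq <- table(factor(aa_all, levels = AA_ALPHABET))
  aa_eq <- (as.numeric(aa_freq) + 1) / sum(aa_freq + 1)
  ss_all <- unlist(lapply(dataset, function(o) c(o$ss_a, o$ss_b)))
  ss_freq <- table(factor(ss_all, levels = SS_ALPHABET))
  ss_eq <- (as.numeric(ss_freq) + 1) / sum(ss_freq + 1)
  centers <- .merge_centers(.angle_clusters(allx, 2L * h))
  pairing <- .pair_centers_by_flux(dataset, centers, h)
  states <- lapply(seq_len(h), function(i) {
    mk <- function(center) {
      site_class(.jitter_simplex(aa_eq), stats::runif(1, 0.7, 1.4),
                 .jitter_simplex(ss_eq),
                 wn_params(center$mu + stats::rnorm(2, 0, 0.05),
                           2, 2, 0, center$sigma, center$sigma))
    }
    hidden_state(mk(centers[[pairing[i, 1]]]), mk(centers[[pairing[i, 2]]]),
                 class_equilibrium = c(0.6, 0.4),
                 jump_rate = stats::runif(1, 1, 5))
  })
  trans <- matrix(0.2 / max(1, h - 1), h, h)
  diag(trans) <- if (h == 1L) 1 else 0.8
  evo_model(states, trans, .default_aa_exchangeability(),
            .default_ss_exchangeability())
}

# Merge k-means centers closer than 0.9 rad (chord): over-segmentation of
# a heavily populated basin would otherwise produce duplicate seeds and
# spurious within-basin "jumps". The threshold sits at the geometry of
# the Ramachandran plot: halves of one over-split basin lie well under
# it, while distinct conformational basins (e.g. sheet vs polyproline II)
# are farther apart. Distinct basins may be shared across hidden states,
# as in real helix/sheet/coil structure.
.merge_centers <- function(centers) {
  merged <- list()
  for (c1 in centers) {
    dup <- any(vapply(merged, function(c2) {
      angular_distance(c1$mu, c2$mu) < 0.9
    }, logical(1)))
    if (!dup) merged[[length(merged) + 1L]] <- c1
  }
  merged
}

# Pair the 2h cluster centers into h (class1, class2) seeds using the
# cross-cluster flux of strongly discordant sites: sites whose two sides
# sit in different angle clusters and far apart (> 1 rad chord distance)
# are candidate jump events, and the most frequent cluster pairs they
# connect seed the hidden states' class pairs. States beyond the observed
# flux pairs fall back to size-ordered pairing.
.pair_centers_by_flux <- function(dataset, centers, h) {
  n_c <- length(centers)
  # recycled pairing over however many distinct centers survive merging
  fb1 <- ((seq_len(h) * 2L - 2L) %% n_c) + 1L
  fb2 <- ((seq_len(h) * 2L - 1L) %% n_c) + 1L
  if (n_c >= 2L) fb2[fb2 == fb1] <- (fb1[fb2 == fb1] %% n_c) + 1L
  fallback <- cbind(fb1, fb2)
  mus <- do.call(rbind, lapply(centers, `[[`, "mu"))
  both <- do.call(rbind, lapply(dataset, function(o) {
    ok <- o$homologous & !is.na(o$phi_a) & !is.na(o$phi_b)
    cbind(o$phi_a[ok], o$psi_a[ok], o$phi_b[ok], o$psi_b[ok])
  }))
  if (is.null(both) || nrow(both) < 20L) return(fallback)
  disc <- angular_distance(both[, 1:2], both[, 3:4]) > 1
  if (sum(disc) < 10L) return(fallback)
  near <- function(x) {
    d <- vapply(seq_len(n_c), function(j) {
      angular_distance(x, matrix(mus[j, ], nrow(x), 2, byrow = TRUE))
    }, numeric(nrow(x)))
    max.col(-d, ties.method = "first")
  }
  ca <- near(both[disc, 1:2, drop = FALSE])
  cb <- near(both[disc, 3:4, drop = FALSE])
  keep <- ca != cb
  if (sum(keep) < 10L) return(fallback)
  key <- paste(pmin(ca[keep], cb[keep]), pmax(ca[keep], cb[keep]))
  top <- names(sort(table(key), decreasing = TRUE))
  pairing <- fallback
  n_top <- min(h, length(top))
  for (i in seq_len(n_top)) {
    pairing[i, ] <- as.integer(strsplit(top[i], " ")[[1]])
  }
  pairing
}

# k-means on the (cos, sin) embedding of the pooled angle observations;
# returns a list of n_centers (mu, sigma) seeds, recycled if the data
# support fewer clusters.
.angle_clusters <- function(allx, n_centers) {
  fallback <- lapply(seq_len(n_centers), function(i) {
    list(mu = stats::runif(2, -pi, pi), sigma = 1)
  })
  if (nrow(allx) < 10L * n_centers) return(fallback)
  if (nrow(allx) > 20000L) {
    allx <- allx[sample.int(nrow(allx), 20000L), , drop = FALSE]
  }
  emb <- cbind(cos(allx[, 1]), sin(allx[, 1]), cos(allx[, 2]), sin(allx[, 2]))
  km <- tryCatch(stats::kmeans(emb, centers = n_centers, nstart = 5L,
                               iter.max = 30L),
                 error = function(e) NULL)
  if (is.null(km)) return(fallback)
  ord <- order(-km$size)
  lapply(seq_len(n_centers), function(j) {
    k <- ord[j]
    mu <- c(atan2(km$centers[k, 2], km$centers[k, 1]),
            atan2(km$centers[k, 4], km$centers[k, 3]))
    rows <- which(km$cluster == k)
    dev <- wrap_angle(sweep(allx[rows, , drop = FALSE], 2L, mu))
    sigma <- max(min(sqrt(mean(dev^2)) , 1.5), 0.2)
    # stationary sd ~ sigma/sqrt(2 alpha) with alpha = 2 at init
    list(mu = mu, sigma = sigma * 2)
  })
}

.jitter_simplex <- function(p) {
  q <- p * exp(stats::rnorm(length(p), 0, 0.3))
  q / sum(q)
}

.empty_suffstats <- function(h) {
  per_state <- function() list(
    class_counts = c(0, 0), jump_pairs = matrix(0, 2, 2),
    per_class = lapply(1:2, function(i) list(
      aa_counts = stats::setNames(numeric(20), AA_ALPHABET),
      ss_counts = stats::setNames(numeric(3), SS_ALPHABET),
      # angle observations: constant-evolution pairs (chunks sharing one
      # t) and single draws (jump branch or one-sided)
      pairs = list(), singles = list(),
      aa_pairs = list())))
  list(trans_counts = matrix(0, h, h),
       states = lapply(seq_len(h), function(i) per_state()),
       aa_flux = matrix(0, 20, 20, dimnames = list(AA_ALPHABET, AA_ALPHABET)),
       ss_flux = matrix(0, 3, 3, dimnames = list(SS_ALPHABET, SS_ALPHABET)),
       sum_t = 0, n_t = 0,
       soft_trans = matrix(0, h, h),
       # per state: 4-cell expected class-pair counts, stacked by the
       # evolutionary time they were observed at
       soft_jump = lapply(seq_len(h), function(i) list()))
}

# Vectorized categorical draw from rows of an unnormalized log-weight
# matrix (ambient RNG).
.sample_rows <- function(lw) {
  pr <- exp(lw - apply(lw, 1L, max))
  pr <- pr / rowSums(pr)
  cp <- pr
  for (j in 2:ncol(pr)) cp[, j] <- cp[, j - 1] + pr[, j]
  u <- stats::runif(nrow(pr))
  idx <- rep(1L, nrow(pr))
  for (j in 1:(ncol(pr) - 1L)) idx <- idx + (u > cp[, j])
  idx
}

# Accumulate sampled sufficient statistics for one pair and one sampled
# hidden path; site-class pairs drawn from their per-site posteriors.
.accumulate_suffstats <- function(acc, o, t, path, em, model) {
  n <- nrow(o)
  if (n > 1L) {
    for (step in seq_len(n - 1L)) {
      acc$trans_counts[path[step], path[step + 1L]] <-
        acc$trans_counts[path[step], path[step + 1L]] + 1
    }
  }
  acc$sum_t <- acc$sum_t + t * sum(o$homologous)
  acc$n_t <- acc$n_t + sum(o$homologous)
  ia <- match(o$aa_a, AA_ALPHABET); ib <- match(o$aa_b, AA_ALPHABET)
  sa <- match(o$ss_a, SS_ALPHABET); sb <- match(o$ss_b, SS_ALPHABET)
  has_xa <- !is.na(o$phi_a); has_xb <- !is.na(o$phi_b)
  ra <- integer(n); rb <- integer(n)
  for (k in unique(path)) {
    hom_k <- which(path == k & o$homologous)
    if (length(hom_k)) {
      idx <- .sample_rows(em$per_state[[k]]$branches[hom_k, , drop = FALSE])
      ra[hom_k] <- c(1L, 1L, 2L, 2L)[idx]
      rb[hom_k] <- c(1L, 2L, 1L, 2L)[idx]
    }
    nh_k <- which(path == k & !o$homologous)
    if (length(nh_k)) {
      side_a <- !is.na(o$aa_a[nh_k]) | has_xa[nh_k] | !is.na(o$ss_a[nh_k])
      lp <- log(model$states[[k]]$class_equilibrium)
      s1 <- ifelse(side_a, em$per_state[[k]]$t1$stat_a[nh_k],
                   em$per_state[[k]]$t1$stat_b[nh_k])
      s2 <- ifelse(side_a, em$per_state[[k]]$t2$stat_a[nh_k],
                   em$per_state[[k]]$t2$stat_b[nh_k])
      cl <- .sample_rows(cbind(lp[1] + s1, lp[2] + s2))
      ra[nh_k] <- cl; rb[nh_k] <- cl
    }
  }
  constant <- ra == rb & o$homologous
  for (k in unique(path)) {
    in_k <- path == k
    st_acc <- acc$states[[k]]
    st_acc$class_counts <- st_acc$class_counts +
      tabulate(ra[in_k], 2) + tabulate(rb[in_k & o$homologous], 2)
    jp <- table(factor(ra[in_k & o$homologous], 1:2),
                factor(rb[in_k & o$homologous], 1:2))
    st_acc$jump_pairs <- st_acc$jump_pairs + as.matrix(jp)
    for (cl in 1:2) {
      pc <- st_acc$per_class[[cl]]
      rows_a <- in_k & ra == cl
      rows_b <- in_k & rb == cl & (o$homologous | !is.na(ib) | has_xb | !is.na(sb))
      pc$aa_counts <- pc$aa_counts + tabulate(ia[rows_a], 20) +
        tabulate(ib[rows_b], 20)
      pc$ss_counts <- pc$ss_counts + tabulate(sa[rows_a], 3) +
        tabulate(sb[rows_b], 3)
      cc <- in_k & constant & ra == cl
      xpair <- cc & has_xa & has_xb
      if (any(xpair)) {
        pc$pairs[[length(pc$pairs) + 1L]] <- list(
          xa = cbind(o$phi_a[xpair], o$psi_a[xpair]),
          xb = cbind(o$phi_b[xpair], o$psi_b[xpair]), t = t)
      }
      sing_a <- rows_a & has_xa & !(constant & has_xb)
      sing_b <- rows_b & has_xb & !(constant & has_xa)
      sing <- rbind(cbind(o$phi_a[sing_a], o$psi_a[sing_a]),
                    cbind(o$phi_b[sing_b], o$psi_b[sing_b]))
      if (nrow(sing)) {
        pc$singles[[length(pc$singles) + 1L]] <- sing
      }
      ap <- cc & !is.na(ia) & !is.na(ib)
      if (any(ap)) {
        pc$aa_pairs[[length(pc$aa_pairs) + 1L]] <- list(
          a = o$aa_a[ap], b = o$aa_b[ap], t = t)
      }
      st_acc$per_class[[cl]] <- pc
    }
    cf <- in_k & constant & !is.na(ia) & !is.na(ib)
    if (any(cf)) {
      ft <- table(factor(o$aa_a[cf], AA_ALPHABET), factor(o$aa_b[cf], AA_ALPHABET))
      acc$aa_flux <- acc$aa_flux + as.matrix(ft)
    }
    sf <- in_k & constant & !is.na(sa) & !is.na(sb)
    if (any(sf)) {
      ft <- table(factor(o$ss_a[sf], SS_ALPHABET), factor(o$ss_b[sf], SS_ALPHABET))
      acc$ss_flux <- acc$ss_flux + as.matrix(ft)
    }
    acc$states[[k]] <- st_acc
  }
  acc
}

# Exact posterior expected counts (forward-backward) for the hidden
# transition matrix and, per state, the site-class pair distribution.
.accumulate_soft_stats <- function(acc, o, t, em, fw, lT, model) {
  n <- nrow(o); h <- ncol(em$E)
  bw <- .backward(em$E, lT)
  post_h <- exp(fw$alpha + bw - fw$loglik)
  post_h <- post_h / rowSums(post_h)
  if (n > 1L) {
    for (k in seq_len(h)) {
      for (l in seq_len(h)) {
        acc$soft_trans[k, l] <- acc$soft_trans[k, l] +
          sum(exp(fw$alpha[-n, k] + lT[k, l] + em$E[-1, l] + bw[-1, l] -
                    fw$loglik))
      }
    }
  }
  hom <- o$homologous
  for (k in seq_len(h)) {
    lj <- em$per_state[[k]]$branches[hom, , drop = FALSE]
    if (nrow(lj) == 0L) next
    p4 <- exp(lj - .logsumexp_rows(lj))
    cell <- colSums(post_h[hom, k] * p4)
    key <- as.character(signif(t, 10))
    prev <- acc$soft_jump[[k]][[key]]
    acc$soft_jump[[k]][[key]] <- if (is.null(prev)) cell else prev + cell
  }
  acc
}

# M-step: closed-form updates where available, numeric elsewhere.
.m_step <- function(model, acc, cfg) {
  h <- n_states(model)
  use_soft <- sum(acc$soft_trans) > 0 || h == 1L
  trans <- (if (use_soft) acc$soft_trans else acc$trans_counts) + 0.5
  trans <- trans / rowSums(trans)
  S <- model$S; V <- model$V
  if (cfg$update_exchangeability) {
    S <- .reweight_exchangeability(acc$aa_flux, 20)
    V <- .reweight_exchangeability(acc$ss_flux, 3)
  }
  mean_t <- if (acc$n_t > 0) acc$sum_t / acc$n_t else 0.3
  states <- lapply(seq_len(h), function(k) {
    st <- model$states[[k]]
    sa <- acc$states[[k]]
    soft <- acc$soft_jump[[k]]
    if (length(soft)) {
      cells <- Reduce(`+`, soft)
      n1 <- 2 * cells[1] + cells[2] + cells[3]
      n2 <- 2 * cells[4] + cells[2] + cells[3]
      class_eq <- c(n1 + 1, n2 + 1) / (n1 + n2 + 2)
      gamma <- .update_gamma_mle(soft, class_eq, st$jump_rate)
    } else {
      class_eq <- (sa$class_counts + 1) / sum(sa$class_counts + 1)
      gamma <- .update_gamma(sa$jump_pairs, class_eq, st$jump_rate, mean_t)
    }
    classes <- lapply(1:2, function(cl) {
      pc <- sa$per_class[[cl]]
      old <- st$classes[[cl]]
      aa_eq <- (pc$aa_counts + 0.5) / sum(pc$aa_counts + 0.5)
      ss_eq <- (pc$ss_counts + 0.5) / sum(pc$ss_counts + 0.5)
      wn <- .update_wn(pc$pairs, pc$singles, old$wn, cfg$wn_maxit)
      scale <- .update_aa_scale(pc$aa_pairs, S, aa_eq, old$aa_scale)
      site_class(aa_eq, scale, ss_eq, wn)
    })
    hidden_state(classes[[1]], classes[[2]], class_eq, gamma)
  })
  evo_model(states, trans, S, V, model$K)
}

# Jump-rate MLE from expected class-pair cell counts grouped by the
# evolutionary time at which they were observed.
.update_gamma_mle <- function(soft, class_eq, old) {
  ts <- as.numeric(names(soft))
  nll <- function(lg) {
    g <- exp(lg)
    tot <- 0
    for (i in seq_along(ts)) {
      e <- exp(-g * ts[i])
      p1 <- class_eq[1]; p2 <- class_eq[2]
      pr <- c(p1 * (e + p1 * (1 - e)), p1 * p2 * (1 - e),
              p1 * p2 * (1 - e), p2 * (e + p2 * (1 - e)))
      tot <- tot - sum(soft[[i]] * log(pmax(pr, 1e-300)))
    }
    tot
  }
  opt <- tryCatch(stats::optimize(nll, c(log(1e-3), log(200)), tol = 1e-5),
                  error = function(e) NULL)
  if (is.null(opt)) return(old)
  exp(opt$minimum)
}

# Jump-rate MLE from sampled site-class pairs: the discordance probability
# is 2 pi1 pi2 (1 - e^{-gamma t}); solve on the mean-time scale.
.update_gamma <- function(jump_pairs, class_eq, old, mean_t) {
  n <- sum(jump_pairs)
  if (n < 5) return(old)
  disc <- (jump_pairs[1, 2] + jump_pairs[2, 1]) / n
  cap <- 2 * class_eq[1] * class_eq[2]
  frac <- min(disc / cap, 0.995)
  if (frac <= 0) return(max(old * 0.5, 1e-3))
  max(-log(1 - frac) / max(mean_t, 1e-3), 1e-3)
}

# Diffusion-parameter update: penalized MLE over (mu, log alpha, atanh rho,
# log sigma) from the class's assigned angle pairs and singles.
.update_wn <- function(pairs, singles, old, maxit) {
  pairs <- .merge_chunks_by_t(pairs, c("xa", "xb"))
  n_pair <- sum(vapply(pairs, function(p) nrow(p$xa), numeric(1)), 0)
  sm <- if (length(singles)) do.call(rbind, singles) else NULL
  if (n_pair + NROW(sm) < 8) return(old)
  xs <- do.call(rbind, c(lapply(pairs, function(p) rbind(p$xa, p$xb)),
                         list(sm)))
  # circular-moment initialization for the mean
  mu0 <- c(atan2(mean(sin(xs[, 1])), mean(cos(xs[, 1]))),
           atan2(mean(sin(xs[, 2])), mean(cos(xs[, 2]))))
  par0 <- c(mu0, log(old$alpha1), log(old$alpha2),
            atanh(max(min(old$alpha3 / sqrt(old$alpha1 * old$alpha2), 0.95), -0.95)),
            log(old$sigma1), log(old$sigma2))
  nll <- function(par) {
    a1 <- exp(par[3]); a2 <- exp(par[4]); rho <- tanh(par[5])
    p <- tryCatch(
      wn_params(par[1:2], a1, a2, rho * sqrt(a1 * a2) * 0.999,
                exp(par[6]), exp(par[7])),
      error = function(e) NULL)
    if (is.null(p)) return(1e10)
    ll <- 0
    for (ch in pairs) {
      ll <- ll + sum(wn_pair_lpdf(ch$xa, ch$xb, p, ch$t))
    }
    if (!is.null(sm)) ll <- ll + sum(wn_stationary_lpdf(sm, p))
    if (!is.finite(ll)) return(1e10)
    -ll + 0.01 * sum(par[3:7]^2)   # mild ridge keeps parameters bounded
  }
  opt <- tryCatch(
    stats::optim(par0, nll, method = "Nelder-Mead",
                 control = list(maxit = maxit)),
    error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$value)) return(old)
  par <- opt$par
  a1 <- exp(par[3]); a2 <- exp(par[4]); rho <- tanh(par[5])
  tryCatch(
    wn_params(par[1:2], a1, a2, rho * sqrt(a1 * a2) * 0.999,
              exp(par[6]), exp(par[7])),
    error = function(e) old)
}

# Merge per-pair statistic chunks that share an evolutionary time, so the
# objective evaluations scale with the number of distinct times.
.merge_chunks_by_t <- function(chunks, fields) {
  if (length(chunks) < 2L) return(chunks)
  ts <- vapply(chunks, `[[`, numeric(1), "t")
  lapply(unique(ts), function(tv) {
    sel <- chunks[ts == tv]
    out <- lapply(fields, function(f) {
      parts <- lapply(sel, `[[`, f)
      if (is.matrix(parts[[1]])) do.call(rbind, parts) else unlist(parts)
    })
    names(out) <- fields
    out$t <- tv
    out
  })
}

# Amino-acid scale MLE from constant-evolution substitution pairs.
.update_aa_scale <- function(aa_pairs, S, aa_eq, old) {
  aa_pairs <- .merge_chunks_by_t(aa_pairs, c("a", "b"))
  n_tot <- sum(vapply(aa_pairs, function(p) length(p$a), numeric(1)), 0)
  if (n_tot < 20) return(old)
  f <- function(ls) {
    chain <- reversible_ctmc(S, aa_eq, exp(ls), AA_ALPHABET)
    ll <- 0
    for (ch in aa_pairs) {
      ll <- ll + sum(ctmc_pair_loglik(ch$a, ch$b, chain, ch$t))
    }
    -ll
  }
  opt <- tryCatch(stats::optimize(f, c(log(1e-3), log(50)), tol = 1e-4),
                  error = function(e) NULL)
  if (is.null(opt)) return(old)
  exp(opt$minimum)
}

# Expected-count reweighting of an exchangeability matrix: symmetrized
# substitution counts, normalized to unit mean off-diagonal rate, floored.
.reweight_exchangeability <- function(flux, n) {
  C <- flux + t(flux)
  diag(C) <- 0
  C <- C + 0.1
  diag(C) <- 0
  C / mean(C[upper.tri(C)])
}

#' Select the number of hidden states by BIC
#'
#' Fits the model for each candidate number of hidden states and returns
#' the BIC table and the best model.
#'
#' @param dataset list of `"obs_pairs"`.
#' @param h_grid integer vector of candidate state counts.
#' @param cfg base `"fit_config"`; its `n_hidden_states` is overridden.
#' @param times optional fixed per-pair evolutionary times.
#' @return list with `table` (data.frame h, loglik, n_params, bic), `best_h`
#'   and `fits`.
#' @export
select_n_states <- function(dataset, h_grid = c(1, 2, 3, 4), cfg = fit_config(),
                            times = NULL) {
  n_obs <- sum(vapply(dataset, function(o) sum(o$homologous), numeric(1)))
  fits <- lapply(h_grid, function(h) {
    cfg_h <- cfg
    cfg_h$n_hidden_states <- as.integer(h)
    fit <- stem_fit(dataset, cfg_h, times = times)
    ll <- sum(vapply(seq_along(dataset), function(d) {
      forward_loglik(dataset[[d]], fit$model, fit$t_hat[d])
    }, numeric(1)))
    list(fit = fit, loglik = ll)
  })
  tab <- data.frame(
    h = h_grid,
    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
    n_params = vapply(fits, function(f) count_free_parameters(f$fit$model),
                      numeric(1)))
  tab$bic <- -2 * tab$loglik + tab$n_params * log(n_obs)
  list(table = tab, best_h = h_grid[which.min(tab$bic)], fits = fits)
}
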