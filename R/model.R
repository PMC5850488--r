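#' Evolutionary model over aligned sites
#'
#' The full model: `h` evolutionary hidden states, a stochastic transition
#' matrix encoding neighboring dependencies along the alignment, and the
#' two global exchangeability matrices shared by all site-classes. The
#' initial distribution of the hidden chain is its stationary distribution
#' (computed, not a free parameter), keeping the chain marginally
#' homogeneous.
#'
#' @param states list of `"hidden_state"` objects.
#' @param transition h x h stochastic matrix (rows sum to 1); defaults to
#'   uniform.
#' @param S 20 x 20 symmetric amino-acid exchangeability matrix, zero diag.
#' @param V 3 x 3 symmetric secondary-structure exchangeability matrix.
#' @param K winding truncation used in likelihood evaluations (default 1).
#' @return object of class `"evo_model"`.
#' @export
evo_model <- function(states, transition = NULL, S, V, K = 1L) {
  h <- length(states)
  stopifnot(h >= 1L)
  for (st in states) stopifnot(inherits(st, "hidden_state"))
  if (is.null(transition)) transition <- matrix(1 / h, h, h)
  transition <- as.matrix(transition)
  if (nrow(transition) != h || ncol(transition) != h ||
      any(transition < 0) || max(abs(rowSums(transition) - 1)) > 1e-8) {
    stop("evo_model: transition must be an h x h stochastic matrix")
  }
  transition <- transition / rowSums(transition)
  .check_exch(S, 20L, "S"); .check_exch(V, 3L, "V")
  m <- structure(list(states = states, transition = transition,
                      initial = .chain_stationary(transition),
                      S = as.matrix(S), V = as.matrix(V), K = as.integer(K)),
                 class = "evo_model")
  m
}

.check_exch <- function(M, n, nm) {
  M <- as.matrix(M)
  if (nrow(M) != n || ncol(M) != n) stop(sprintf("%s must be %d x %d", nm, n, n))
  if (max(abs(M - t(M))) > 1e-10) stop(sprintf("%s must be symmetric", nm))
  if (any(M < 0) || any(abs(diag(M)) > 1e-12)) {
    stop(sprintf("%s must be non-negative with zero diagonal", nm))
  }
  invisible(M)
}

# Stationary distribution of a finite stochastic matrix.
.chain_stationary <- function(P) {
  h <- nrow(P)
  if (h == 1L) return(1)
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- abs(Re(e$vectors[, i]))
  v / sum(v)
}

#' Number of hidden states of a model
#' @param m an `"evo_model"`.
#' @return integer.
#' @export
n_states <- function(m) length(m$states)

#' Count the free parameters of a model
#'
#' Deterministic accounting: 190 for the global amino-acid exchangeability
#' (symmetric 20 x 20, zero diagonal), 3 for the secondary-structure
#' exchangeability, and per hidden state two site-classes at
#' `19 (aa frequencies) + 1 (aa scale) + 2 (ss frequencies) + 6 (diffusion
#' parameters)` each, plus 1 class-equilibrium and 1 jump rate; the hidden
#' transition matrix contributes `h (h - 1)`.
#'
#' @param m an `"evo_model"`.
#' @return integer count of free parameters.
#' @export
count_free_parameters <- function(m) {
  h <- n_states(m)
  per_class <- 19L + 1L + 2L + 6L
  per_state <- 2L * per_class + 1L + 1L
  190L + 3L + h * per_state + h * (h - 1L)
}

# ---- Example/generator models -------------------------------------------

# Canonical Ramachandran basins used by the example model builders.
.rama_basins <- list(
  helix = c(-1.05, -0.79),   # right-handed alpha helix
  sheet = c(-2.36, 2.36),    # beta sheet
  ppii  = c(-1.31, 2.71),    # polyproline II / extended coil
  lhelix = c(1.05, 0.79))    # left-handed helix (glycine-rich)

# A site-class concentrated on one Ramachandran basin with an amino-acid
# equilibrium biased toward `favored` residues.
.basin_site_class <- function(basin, favored = NULL, spread = 0.35,
                              drift = 2, ss_eq = c(1, 1, 1) / 3,
                              aa_scale = 1) {
  aa_eq <- rep(1, 20)
  if (!is.null(favored)) aa_eq[match(favored, AA_ALPHABET)] <- 8
  aa_eq <- aa_eq / sum(aa_eq)
  sig <- spread * sqrt(2 * drift)  # stationary sd ~= spread per coordinate
  site_class(aa_eq, aa_scale, ss_eq / sum(ss_eq),
             wn_params(mu = basin, alpha1 = drift, alpha2 = drift,
                       alpha3 = 0.1 * drift, sigma1 = sig, sigma2 = sig))
}

#' Example evolutionary model with Ramachandran-basin states
#'
#' Builds a small, fully specified model whose hidden states occupy
#' canonical basins of the Ramachandran plot (helix, sheet, polyproline
#' II / coil, left-handed helix), with secondary-structure equilibria and
#' amino-acid preferences to match. Used as the default generator for
#' synthetic data and in examples; `h` up to 4 distinct basins (states
#' beyond 4 reuse basins with perturbed means).
#'
#' @param h number of hidden states (>= 1).
#' @param jump_rate jump rate shared by the states.
#' @param self_transition probability of remaining in the same hidden state
#'   between adjacent sites (captures secondary-structure runs).
#' @return an `"evo_model"`.
#' @export
example_model <- function(h = 3L, jump_rate = 2, self_transition = 0.85) {
  basins <- .rama_basins
  ss_eqs <- list(helix = c(0.90, 0.04, 0.06), sheet = c(0.04, 0.90, 0.06),
                 ppii = c(0.05, 0.15, 0.80), lhelix = c(0.10, 0.05, 0.85))
  favored <- list(helix = c("A", "E", "L"), sheet = c("V", "I", "Y"),
                  ppii = c("P", "S", "T"), lhelix = c("G", "N"))
  states <- vector("list", h)
  for (i in seq_len(h)) {
    b1 <- ((i - 1L) %% 4L) + 1L
    b2 <- (i %% 4L) + 1L
    shift <- 0.15 * ((i - 1L) %/% 4L)
    c1 <- .basin_site_class(basins[[b1]] + shift, favored[[b1]],
                            ss_eq = ss_eqs[[b1]])
    c2 <- .basin_site_class(basins[[b2]] - shift, favored[[b2]],
                            ss_eq = ss_eqs[[b2]], spread = 0.45)
    states[[i]] <- hidden_state(c1, c2, class_equilibrium = c(0.7, 0.3),
                                jump_rate = jump_rate)
  }
  trans <- matrix((1 - self_transition) / max(1, h - 1), h, h)
  diag(trans) <- if (h == 1L) 1 else self_transition
  evo_model(states, trans,
            S = .default_aa_exchangeability(),
            V = .default_ss_exchangeability())
}

# Flat default exchangeabilities (uniform rates); estimation replaces them.
.default_aa_exchangeability <- function() {
  M <- matrix(1, 20, 20); diag(M) <- 0
  dimnames(M) <- list(AA_ALPHABET, AA_ALPHABET)
  M
}

.default_ss_exchangeability <- function() {
  M <- matrix(1, 3, 3); diag(M) <- 0
  dimnames(M) <- list(SS_ALPHABET, SS_ALPHABET)
  M
}

#' Random valid model (property tests and fit initialization)
#'
#' Draws a structurally valid model with random equilibria, exchangeability
#' matrices, diffusion parameters and transition structure. Intended for
#' property-style tests and as a randomized initializer for fitting.
#'
#' @param h number of hidden states.
#' @param seed optional integer seed.
#' @param jump_rate_range range for the per-state jump rates.
#' @return an `"evo_model"`.
#' @export
random_model <- function(h = 2L, seed = NULL, jump_rate_range = c(0.5, 10)) {
  .with_seed(seed, {
    states <- lapply(seq_len(h), function(i) {
      mk_class <- function() {
        mu <- stats::runif(2, -pi, pi)
        a12 <- stats::runif(2, 0.5, 3)
        a3 <- stats::runif(1, -0.8, 0.8) * sqrt(prod(a12))
        site_class(.random_simplex(20, 2), stats::runif(1, 0.3, 2.5),
                   .random_simplex(3, 2),
                   wn_params(mu, a12[1], a12[2], a3,
                             stats::runif(1, 0.4, 1.2),
                             stats::runif(1, 0.4, 1.2)))
      }
      hidden_state(mk_class(), mk_class(),
                   class_equilibrium = .random_simplex(2, 4),
                   jump_rate = stats::runif(1, jump_rate_range[1],
                                            jump_rate_range[2]))
    })
    trans <- t(vapply(seq_len(h), function(i) .random_simplex(h, 3),
                      numeric(h)))
    if (h == 1L) trans <- matrix(1, 1, 1)
    evo_model(states, trans,
              S = .random_exchangeability(20),
              V = .random_exchangeability(3))
  })
}
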