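#' Alphabets used by the substitution processes
#'
#' Amino acids are the 20 canonical residues in alphabetical one-letter
#' order; this order is fixed and used for all matrices and serialization.
#' Secondary structure uses three classes: helix (H), sheet (S), coil (C).
#'
#' @format character vectors.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' @rdname AA_ALPHABET
#' @export
SS_ALPHABET <- c("H", "S", "C")

#' Reversible continuous-time Markov chain for substitution processes
#'
#' A general time-reversible (GTR-style) CTMC defined by a symmetric
#' exchangeability matrix with zero diagonal, an equilibrium frequency
#' vector, and a positive rate scale. The rate matrix is
#' `Q[i,j] = scale * exch[i,j] * eq[j]` off the diagonal, with the diagonal
#' set so rows sum to zero; detailed balance `eq[i] Q[i,j] = eq[j] Q[j,i]`
#' holds by construction.
#'
#' @param exchangeability symmetric non-negative matrix, zero diagonal.
#' @param equilibrium probability vector (all entries > 0, sums to 1).
#' @param scale positive rate multiplier (per-site-class rate variation for
#'   amino acids; fixed to 1 for secondary structure).
#' @param alphabet character vector of state labels; defaults to the
#'   dimnames of `exchangeability` or `AA_ALPHABET`/`SS_ALPHABET` by size.
#' @return object of class `"reversible_ctmc"`.
#' @export
reversible_ctmc <- function(exchangeability, equilibrium, scale = 1,
                            alphabet = NULL) {
  exchangeability <- as.matrix(exchangeability)
  n <- nrow(exchangeability)
  if (is.null(alphabet)) {
    alphabet <- rownames(exchangeability)
    if (is.null(alphabet)) {
      alphabet <- if (n == 20L) AA_ALPHABET else if (n == 3L) SS_ALPHABET
                  else as.character(seq_len(n))
    }
  }
  if (ncol(exchangeability) != n) stop("exchangeability must be square")
  if (max(abs(exchangeability - t(exchangeability))) > 1e-10) {
    stop("exchangeability matrix must be symmetric")
  }
  if (any(exchangeability < 0) || any(abs(diag(exchangeability)) > 1e-12)) {
    stop("exchangeability must be non-negative with zero diagonal")
  }
  if (length(equilibrium) != n || any(equilibrium <= 0) ||
      abs(sum(equilibrium) - 1) > 1e-8) {
    stop("equilibrium must be a strictly positive probability vector")
  }
  if (!is.finite(scale) || scale <= 0) stop("scale must be > 0")
  equilibrium <- as.numeric(equilibrium) / sum(equilibrium)
  dimnames(exchangeability) <- list(alphabet, alphabet)
  names(equilibrium) <- alphabet
  structure(list(exchangeability = exchangeability,
                 equilibrium = equilibrium,
                 scale = scale, alphabet = alphabet),
            class = "reversible_ctmc")
}

#' Rate matrix of a reversible CTMC
#'
#' @param c a `"reversible_ctmc"` object.
#' @return square rate matrix Q with zero row sums satisfying detailed
#'   balance with respect to the equilibrium frequencies.
#' @export
ctmc_rate_matrix <- function(c) {
  Q <- c$scale * c$exchangeability * rep(c$equilibrium, each = length(c$equilibrium))
  diag(Q) <- -rowSums(Q)
  Q
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' Computed by eigendecomposition of the pi-symmetrized rate matrix, which
#' is exact for reversible chains.
#'
#' @param c a `"reversible_ctmc"` object (or a rate matrix plus equilibrium
#'   via the `...` internal form).
#' @param t time, `t >= 0`.
#' @return stochastic matrix: rows sum to 1, entries in `[0, 1]`, `P(0)` is
#'   the identity and the equilibrium is invariant.
#' @export
ctmc_transition_matrix <- function(c, t) {
  if (t < 0) stop("ctmc_transition_matrix: t must be >= 0")
  if (t == 0) {
    P <- diag(length(c$equilibrium))
    dimnames(P) <- list(c$alphabet, c$alphabet)
    return(P)
  }
  Q <- ctmc_rate_matrix(c)
  sp <- sqrt(c$equilibrium)
  B <- Q * (sp / rep(sp, each = length(sp)))  # diag(sp) Q diag(1/sp), symmetric
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  P <- (t(e$vectors) * exp(t * e$values))
  P <- e$vectors %*% P
  P <- P * (rep(sp, each = length(sp)) / sp)   # diag(1/sp) ... diag(sp)
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- dimnames(Q)
  P
}

#' Pair log-likelihood under a reversible CTMC
#'
#' Log-probability `log(pi[a] * P[a,b](t))` of observing state `a` in one
#' protein and state `b` at the homologous site of the other, with `a`
#' drawn from equilibrium. Symmetric in `(a, b)` by time-reversibility.
#'
#' @param a,b state labels (single characters from the chain's alphabet);
#'   vectors are evaluated elementwise.
#' @param c a `"reversible_ctmc"` object.
#' @param t time, `t >= 0`.
#' @return numeric vector of log-likelihoods.
#' @export
ctmc_pair_loglik <- function(a, b, c, t) {
  P <- ctmc_transition_matrix(c, t)
  ia <- match(a, c$alphabet)
  ib <- match(b, c$alphabet)
  if (any(is.na(ia)) || any(is.na(ib))) {
    stop("ctmc_pair_loglik: unknown state symbol")
  }
  log(c$equilibrium[ia]) + log(P[cbind(ia, ib)])
}

#' Sample a homologous state pair from a reversible CTMC
#'
#' Draws the ancestral-side state from equilibrium and the descendant-side
#' state from the corresponding row of `P(t)`.
#'
#' @inheritParams ctmc_pair_loglik
#' @param n number of pairs.
#' @param seed optional integer seed.
#' @return n x 2 character matrix with columns `a`, `b`.
#' @export
ctmc_sample_pair <- function(c, t, n = 1L, seed = NULL) {
  P <- ctmc_transition_matrix(c, t)
  .with_seed(seed, {
    ia <- sample.int(length(c$alphabet), n, replace = TRUE, prob = c$equilibrium)
    ib <- vapply(ia, function(i) {
      sample.int(length(c$alphabet), 1L, prob = P[i, ])
    }, integer(1))
    cbind(a = c$alphabet[ia], b = c$alphabet[ib])
  })
}

# Random symmetric exchangeability with zero diagonal (testing / init).
.random_exchangeability <- function(n, rate = 1) {
  m <- matrix(0, n, n)
  v <- stats::rexp(n * (n - 1) / 2, rate = rate)
  m[upper.tri(m)] <- v
  m <- m + t(m)
  m
}

# Random point on the simplex (testing / init).
.random_simplex <- function(n, concentration = 1) {
  x <- stats::rgamma(n, shape = concentration)
  x <- x + 1e-6
  x / sum(x)
}
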