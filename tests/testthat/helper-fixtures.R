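# Shared fixtures and independent oracles used across the test files.

# Diffusion parameters of the depicted drift field: A = (1, 0.5; 0.5, 0.5),
# mu = (0,0), Sigma = (1.5)^2 I  =>  alpha1 = 1, alpha2 = 0.5, alpha3 = 0.5,
# sigma1 = sigma2 = 1.5 (sigma ratio 1).
fig_params <- function() {
  wn_params(mu = c(0, 0), alpha1 = 1, alpha2 = 0.5, alpha3 = 0.5,
            sigma1 = 1.5, sigma2 = 1.5)
}

# Midpoint quadrature grid over the torus.
torus_grid <- function(n = 100L) {
  gr <- seq(-pi, pi, length.out = n + 1L)[-(n + 1L)] + pi / n
  list(points = as.matrix(expand.grid(phi = gr, psi = gr)),
       cell = (2 * pi / n)^2)
}

logsumexp <- function(x) {
  mx <- max(x)
  if (!is.finite(mx)) return(mx)
  mx + log(sum(exp(x - mx)))
}

# Enumerate all alignment column paths of an na x nb pair.
enum_alignments <- function(na, nb) {
  res <- list()
  rec <- function(i, j, cols) {
    if (i == na && j == nb) {
      res[[length(res) + 1L]] <<- cols
      return(invisible())
    }
    if (i < na && j < nb) rec(i + 1L, j + 1L, c(cols, "match"))
    if (i < na) rec(i + 1L, j, c(cols, "delete"))
    if (j < nb) rec(i, j + 1L, c(cols, "insert"))
  }
  rec(0L, 0L, character(0))
  res
}

make_alignment <- function(types) {
  ia <- rep(NA_integer_, length(types)); ib <- ia
  ia[types != "insert"] <- seq_len(sum(types != "insert"))
  ib[types != "delete"] <- seq_len(sum(types != "delete"))
  pair_alignment(types, ia, ib)
}

# Log prior of an alignment under TKF92 (path product; independent of the
# package's DP code path).
tkf_prior_oracle <- function(al, p, t) {
  tk <- tkf92_transitions(p, t)
  lT <- log(tk$trans)
  st <- c(match = "M", delete = "D", insert = "I")[al$type]
  states <- c("S", st)
  lp <- 0
  for (i in seq_along(st)) lp <- lp + lT[states[i], st[i]]
  lp + lT[states[length(states)], "E"]
}

# Truncate a protein track to its first n residues.
head_track <- function(tr, n) {
  protein_track(tr$id, tr$sequence[seq_len(n)],
                angles = if (!is.null(tr$angles)) tr$angles[seq_len(n), , drop = FALSE],
                ss = if (!is.null(tr$ss)) tr$ss[seq_len(n)])
}

# Tiny deterministic pair of tracks with all three observation types.
tiny_tracks <- function(n = 3L, model = random_model(2, seed = 20),
                        t = 0.4, seed = 77) {
  sim <- simulate_pair(model, n, t, seed = seed)
  c(obs_to_tracks(sim$obs), list(obs = sim$obs))
}
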