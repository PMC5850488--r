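# Independent TKF91 oracle: birth-death link probabilities coded directly
# from the classic formulas (no fragment extension).
tkf91_oracle <- function(lambda, mu, t) {
  kappa <- lambda / mu
  alpha <- exp(-mu * t)
  ed <- exp((lambda - mu) * t)
  beta <- lambda * (1 - ed) / (mu - lambda * ed)
  gamma <- 1 - mu * beta / (lambda * (1 - alpha))
  row <- function(p_ins) c(M = (1 - p_ins) * kappa * alpha,
                           D = (1 - p_ins) * kappa * (1 - alpha),
                           I = p_ins,
                           E = (1 - p_ins) * (1 - kappa))
  rbind(S = row(beta), M = row(beta), D = row(gamma), I = row(beta))
}

test_that("TKF92 transition rows normalize and vanish for indels at t = 0", {
  set.seed(120)
  for (i in 1:20) {
    lam <- runif(1, 0.01, 0.5)
    p <- tkf92_params(lam, lam + runif(1, 0.01, 0.5), runif(1, 0, 0.9))
    t <- runif(1, 0.01, 5)
    tr <- tkf92_transitions(p, t)$trans
    expect_equal(rowSums(tr), rep(1, 4), tolerance = 1e-12, ignore_attr = TRUE)
    expect_true(all(tr >= 0 & tr <= 1))
  }
  p <- tkf92_params(0.04, 0.05, 0.4)
  tr0 <- tkf92_transitions(p, 0)$trans
  expect_equal(unname(tr0["S", "D"]), 0)
  expect_equal(unname(tr0["S", "I"]), 0)
  expect_equal(unname(tr0["M", "D"]), 0)
  expect_error(tkf92_params(0.06, 0.05, 0.4), "exceed")
})

test_that("r = 0 reduces the fragment model to TKF91", {
  set.seed(121)
  for (i in 1:10) {
    lam <- runif(1, 0.01, 0.5)
    mu <- lam + runif(1, 0.01, 0.5)
    t <- runif(1, 0.05, 4)
    got <- tkf92_transitions(tkf92_params(lam, mu, 0), t)$trans
    expect_equal(got, tkf91_oracle(lam, mu, t), tolerance = 1e-12)
  }
})

test_that("alignment marginal equals enumeration on tiny instances", {
  m <- random_model(2, seed = 122)
  tk <- tkf92_params(0.04, 0.05, 0.3)
  t <- 0.5
  trks <- tiny_tracks(2, model = m, t = t, seed = 123)
  for (case in list(c(1, 1), c(2, 2), c(2, 1))) {
    ta <- head_track(trks$a, case[1]); tb <- head_track(trks$b, case[2])
    total <- -Inf
    for (types in enum_alignments(case[1], case[2])) {
      al <- make_alignment(types)
      o <- align_tracks(ta, tb, al)
      total <- logsumexp(c(total, tkf_prior_oracle(al, tk, t) +
                             forward_loglik(o, m, t)))
    }
    expect_equal(alignment_forward(ta, tb, m, tk, t), total, tolerance = 1e-8)
  }
})

test_that("a point-mass alignment prior recovers the fixed-alignment likelihood", {
  # the marginal dominates every single alignment's prior + conditional,
  # and conditioning on the diagonal alignment reproduces the HMM forward
  m <- random_model(2, seed = 124)
  tk <- tkf92_params(0.04, 0.05, 0.3)
  t <- 0.4
  trks <- tiny_tracks(3, model = m, t = t, seed = 125)
  al <- make_alignment(rep("match", 3))
  o <- align_tracks(trks$a, trks$b, al)
  single <- tkf_prior_oracle(al, tk, t) + forward_loglik(o, m, t)
  marg <- alignment_forward(trks$a, trks$b, m, tk, t)
  expect_gte(marg + 1e-10, single)
  # near-degenerate prior: at a tiny evolutionary time the indel states
  # carry vanishing prior mass and (for data generated at t = 0) the
  # diagonal alignment carries essentially the whole marginal, so the
  # marginal reduces to prior + conditional of that single alignment
  sim0 <- simulate_pair(m, 3, 0, seed = 140)$obs
  trk0 <- obs_to_tracks(sim0)
  o0 <- align_tracks(trk0$a, trk0$b, al)
  t0 <- 1e-4
  expect_equal(alignment_forward(trk0$a, trk0$b, m, tk, t0),
               tkf_prior_oracle(al, tk, t0) + forward_loglik(o0, m, t0),
               tolerance = 1e-6)
})

test_that("MAP alignment is deterministic and optimal on small instances", {
  m1 <- random_model(1, seed = 126)
  tk <- tkf92_params(0.04, 0.05, 0.3)
  t <- 0.5
  trks <- tiny_tracks(3, model = m1, t = t, seed = 127)
  map1 <- map_alignment(trks$a, trks$b, m1, tk, t)
  map2 <- map_alignment(trks$a, trks$b, m1, tk, t)
  expect_identical(map1, map2)
  # exact argmax over enumerated alignments (single hidden state, where
  # the joint and alignment-marginal optima coincide)
  best <- -Inf; best_al <- NULL
  for (types in enum_alignments(3, 3)) {
    al <- make_alignment(types)
    o <- align_tracks(trks$a, trks$b, al)
    lp <- tkf_prior_oracle(al, tk, t) + forward_loglik(o, m1, t)
    if (lp > best) { best <- lp; best_al <- al }
  }
  expect_equal(map1$type, best_al$type)
  # identical sequences at tiny t: the diagonal alignment wins
  m <- random_model(2, seed = 128)
  sim <- simulate_pair(m, 5, 0, seed = 129)$obs
  trk <- obs_to_tracks(sim)
  map0 <- map_alignment(trk$a, trk$b, m, tk, 1e-4)
  expect_true(all(map0$type == "match"))
  # MAP posterior dominates sampled alignments
  m2 <- random_model(2, seed = 130)
  trks2 <- tiny_tracks(4, model = m2, t = 0.6, seed = 131)
  weight <- function(al) {
    tkf_prior_oracle(al, tk, 0.6) +
      forward_loglik(align_tracks(trks2$a, trks2$b, al), m2, 0.6)
  }
  mapw <- weight(map_alignment(trks2$a, trks2$b, m2, tk, 0.6))
  samps <- sample_alignments(trks2$a, trks2$b, m2, tk, 0.6, n = 1000, seed = 132)
  sw <- vapply(samps, weight, numeric(1))
  expect_gte(mapw + 1e-9, max(sw))
})

test_that("sampled alignments follow their enumerated posterior", {
  m <- random_model(2, seed = 133)
  tk <- tkf92_params(0.04, 0.05, 0.3)
  t <- 0.5
  trks <- tiny_tracks(1, model = m, t = t, seed = 134)
  ta <- head_track(trks$a, 1); tb <- head_track(trks$b, 1)
  marg <- alignment_forward(ta, tb, m, tk, t)
  post <- vapply(enum_alignments(1, 1), function(types) {
    al <- make_alignment(types)
    exp(tkf_prior_oracle(al, tk, t) +
          forward_loglik(align_tracks(ta, tb, al), m, t) - marg)
  }, numeric(1))
  keys <- vapply(enum_alignments(1, 1), function(types) {
    paste(types, collapse = ",")
  }, character(1))
  n <- 20000L
  samps <- sample_alignments(ta, tb, m, tk, t, n = n, seed = 135)
  skey <- vapply(samps, function(a) paste(a$type, collapse = ","), character(1))
  emp <- vapply(keys, function(k) mean(skey == k), numeric(1))
  se <- sqrt(post * (1 - post) / n)
  expect_true(all(abs(emp - post) < 3 * se + 1e-4))
  # reproducibility and MAP dominance among samples
  s2 <- sample_alignments(ta, tb, m, tk, t, n = 50, seed = 136)
  s3 <- sample_alignments(ta, tb, m, tk, t, n = 50, seed = 136)
  expect_identical(s2, s3)
  expect_equal(names(sort(table(skey), decreasing = TRUE))[1],
               keys[which.max(post)])
})

test_that("alignment similarity and homology precision follow their definitions", {
  ref <- make_alignment(c("match", "match", "delete", "match", "insert"))
  expect_equal(alignment_similarity(ref, ref), 1)
  expect_equal(homology_precision(ref, ref), 1)
  # disjoint homologous pairings
  a1 <- make_alignment(c("match", "match", "delete", "insert"))
  a2 <- make_alignment(c("delete", "match", "match", "insert"))
  expect_equal(homology_precision(a1, a2), 0)
  # hand-built half-overlap: pred shares 3 of its 4 homologous pairs
  pred <- make_alignment(c("match", "match", "match", "match", "delete", "insert"))
  ref2 <- make_alignment(c("match", "match", "match", "delete", "insert", "match"))
  # shared homologous pairs: (1,1), (2,2), (3,3); shared full columns add
  # delete(5->4 index) check by explicit key comparison
  expect_equal(homology_precision(pred, ref2), 3 / 4)
  shared_cols <- length(intersect(
    paste(pred$type, pred$index_a, pred$index_b),
    paste(ref2$type, ref2$index_a, ref2$index_b)))
  expect_equal(alignment_similarity(pred, ref2),
               2 * shared_cols / (nrow(pred) + nrow(ref2)))
  set.seed(137)
  # random-case property: similarity in [0,1], equals set arithmetic
  for (i in 1:20) {
    na <- sample(2:5, 1); nb <- sample(2:5, 1)
    als <- enum_alignments(na, nb)
    p <- make_alignment(als[[sample(length(als), 1)]])
    r <- make_alignment(als[[sample(length(als), 1)]])
    s <- alignment_similarity(p, r)
    expect_gte(s, 0); expect_lte(s, 1)
    hp <- paste(p$index_a[p$type == "match"], p$index_b[p$type == "match"])
    hr <- paste(r$index_a[r$type == "match"], r$index_b[r$type == "match"])
    if (length(hp)) {
      expect_equal(homology_precision(p, r),
                   length(intersect(hp, hr)) / length(hp))
    }
  }
  expect_error(homology_precision(make_alignment(c("delete", "insert")),
                                  make_alignment(c("match"))),
               "no homologous")
})

test_that("structural observations sharpen the posterior of the true alignment", {
  # on simulated instances, adding the angle tracks should (in tendency)
  # increase the posterior probability of the generating alignment
  m <- example_model(2)
  tk <- tkf92_params(0.08, 0.1, 0.3)
  t <- 0.4
  set.seed(138)
  wins <- 0; ties <- 0; nrep <- 200
  for (rep in 1:nrep) {
    sim <- simulate_pair(m, 6, t, seed = 200 + rep)$obs
    trks <- obs_to_tracks(sim)
    truth <- make_alignment(rep("match", 6))
    post_of_truth <- function(with_angles) {
      strip <- function(tr) protein_track(tr$id, tr$sequence,
                                          angles = if (with_angles) tr$angles)
      ta <- strip(trks$a); tb <- strip(trks$b)
      o <- align_tracks(ta, tb, truth)
      exp(tkf_prior_oracle(truth, tk, t) + forward_loglik(o, m, t) -
            alignment_forward(ta, tb, m, tk, t))
    }
    d <- post_of_truth(TRUE) - post_of_truth(FALSE)
    if (d > 1e-12) wins <- wins + 1 else if (abs(d) <= 1e-12) ties <- ties + 1
  }
  # sign test: angles help in a clear majority of instances
  expect_lt(stats::binom.test(wins, nrep - ties,
                              alternative = "greater")$p.value, 0.01)
})

test_that("column-record TSV round-trips alignments", {
  al <- make_alignment(c("match", "delete", "insert", "match"))
  tmp <- tempfile(fileext = ".tsv")
  write_alignment_tsv(al, tmp)
  back <- read_alignment_tsv(tmp)
  expect_equal(back$type, al$type)
  expect_equal(back$index_a, al$index_a)
  expect_equal(back$index_b, al$index_b)
})

test_that("gapped FASTA round-trips alignments", {
  al <- make_alignment(c("match", "delete", "match", "insert", "match"))
  g <- alignment_to_gapped(al, "ACDE", "ACDF")
  expect_equal(nchar(g[1]), nchar(g[2]))
  back <- gapped_to_alignment(g[1], g[2])
  expect_equal(back$type, al$type)
  expect_equal(back$index_a, al$index_a)
  expect_equal(back$index_b, al$index_b)
  expect_error(gapped_to_alignment("A-", "C-"), "both sides")
})
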