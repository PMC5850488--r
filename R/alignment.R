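#' TKF92 insertion-deletion model parameters
#'
#' The Thorne-Kishino-Felsenstein fragment model: fragments are born at
#' rate `lambda`, die at rate `mu > lambda` (so expected sequence length is
#' finite) and have geometric length with extension probability `r`.
#' Expected sequence length is `lambda / (mu - lambda) / (1 - r)` residues.
#'
#' @param lambda birth rate, > 0.
#' @param mu death rate, > lambda.
#' @param r fragment extension probability in `[0, 1)`.
#' @return object of class `"tkf92_params"`.
#' @export
tkf92_params <- function(lambda, mu, r = 0.5) {
  if (!is.finite(lambda) || lambda <= 0) stop("tkf92_params: lambda must be > 0")
  if (!is.finite(mu) || mu <= lambda) stop("tkf92_params: mu must exceed lambda")
  if (!is.finite(r) || r < 0 || r >= 1) stop("tkf92_params: r must be in [0, 1)")
  structure(list(lambda = lambda, mu = mu, r = r), class = "tkf92_params")
}

#' TKF92 parameters matched to a mean sequence length
#'
#' Sets `lambda / mu` so that the expected stationary sequence length
#' equals `mean_length` given the fragment extension probability.
#'
#' @param mean_length target expected length (residues).
#' @param r fragment extension probability.
#' @param mu death rate (sets the indel time scale).
#' @return a `"tkf92_params"` object.
#' @export
tkf92_from_length <- function(mean_length, r = 0.5, mu = 0.1) {
  nfrag <- mean_length * (1 - r)  # expected number of fragments
  kappa <- nfrag / (1 + nfrag)    # lambda/mu: E[#frag] = kappa/(1-kappa)
  tkf92_params(lambda = kappa * mu, mu = mu, r = r)
}

#' Pair-HMM transition probabilities of the TKF92 model
#'
#' The standard fragment pair HMM with states M (homologous column),
#' D (deletion, ancestral side only) and I (insertion, descendant side
#' only). Within a fragment the current state self-loops with probability
#' `r`; between fragments the TKF91 birth-death probabilities apply, built
#' from the survival probability `alpha = exp(-mu t)` and the birth
#' function `beta(t)`. Each row, including the transition to the end
#' state, sums to 1. At `t = 0` all indel probabilities vanish.
#'
#' @param p a `"tkf92_params"` object.
#' @param t evolutionary time, `t >= 0`.
#' @return list with `trans`: 4 x 4 matrix of transition probabilities with
#'   rows `S` (start), `M`, `D`, `I` and columns `M`, `D`, `I`, `E` (end),
#'   and the underlying quantities `alpha`, `beta`, `gamma`, `kappa`.
#' @export
tkf92_transitions <- function(p, t) {
  if (t < 0) stop("tkf92_transitions: t must be >= 0")
  lam <- p$lambda; mu <- p$mu; r <- p$r
  kappa <- lam / mu
  alpha <- exp(-mu * t)
  if (t == 0) {
    beta <- 0
    gamma <- 0
  } else {
    ed <- exp((lam - mu) * t)
    beta <- lam * (1 - ed) / (mu - lam * ed)
    gamma <- 1 - mu * beta / (lam * (1 - alpha))
  }
  row_for <- function(p_ins) {
    # p_ins: probability the next event is a birth (I); otherwise advance
    # to the next ancestral fragment (M/D) or finish
    nxt <- 1 - p_ins
    c(M = nxt * kappa * alpha,
      D = nxt * kappa * (1 - alpha),
      I = p_ins,
      E = nxt * (1 - kappa))
  }
  trans <- rbind(
    S = row_for(beta),
    M = c(r, 0, 0, 0) + (1 - r) * row_for(beta),
    D = c(0, r, 0, 0) + (1 - r) * row_for(gamma),
    I = c(0, 0, r, 0) + (1 - r) * row_for(beta))
  colnames(trans) <- c("M", "D", "I", "E")
  list(trans = trans, alpha = alpha, beta = beta, gamma = gamma, kappa = kappa)
}

#' Pairwise alignment record
#'
#' An alignment is an ordered sequence of columns, each homologous
#' (`"match"`, consuming one residue of each protein), a deletion
#' (`"delete"`, protein a only) or an insertion (`"insert"`, protein b
#' only). Indices are 1-based; the projections onto each protein must be
#' strictly increasing and cover every residue exactly once.
#'
#' @param type character vector in `{"match", "delete", "insert"}`.
#' @param index_a,index_b integer indices into proteins a and b (NA where
#'   the column does not touch the protein).
#' @return data.frame of class `"pair_alignment"`.
#' @export
pair_alignment <- function(type, index_a, index_b) {
  al <- data.frame(type = as.character(type),
                   index_a = as.integer(index_a),
                   index_b = as.integer(index_b),
                   stringsAsFactors = FALSE)
  validate_pair_alignment(al)
}

#' @rdname pair_alignment
#' @param al a candidate alignment data.frame.
#' @export
validate_pair_alignment <- function(al) {
  if (!all(al$type %in% c("match", "delete", "insert"))) {
    stop("pair_alignment: unknown column type")
  }
  need_a <- al$type %in% c("match", "delete")
  need_b <- al$type %in% c("match", "insert")
  if (any(is.na(al$index_a[need_a])) || any(!is.na(al$index_a[!need_a]))) {
    stop("pair_alignment: index_a must be set exactly on match/delete columns")
  }
  if (any(is.na(al$index_b[need_b])) || any(!is.na(al$index_b[!need_b]))) {
    stop("pair_alignment: index_b must be set exactly on match/insert columns")
  }
  ia <- al$index_a[need_a]; ib <- al$index_b[need_b]
  if (length(ia) && !identical(ia, seq_along(ia))) {
    stop("pair_alignment: protein-a indices must cover 1..n in order")
  }
  if (length(ib) && !identical(ib, seq_along(ib))) {
    stop("pair_alignment: protein-b indices must cover 1..n in order")
  }
  class(al) <- unique(c("pair_alignment", class(al)))
  al
}

# Log prior probability of an alignment's column path under TKF92.
tkf92_alignment_logprior <- function(al, p, t) {
  tk <- tkf92_transitions(p, t)
  lT <- log(tk$trans)
  st <- c(match = "M", delete = "D", insert = "I")[al$type]
  states <- c("S", st)
  lp <- 0
  for (i in seq_along(st)) lp <- lp + lT[states[i], st[i]]
  lp + lT[states[length(states)], "E"]
}

# ---- Alignment-marginal dynamic programming ------------------------------

# Emission tables for the DP: match (na x nb x h), delete (na x h),
# insert (nb x h), all in log space.
.alignment_emissions <- function(track_a, track_b, m, t) {
  na <- track_a$length; nb <- track_b$length; h <- n_states(m)
  grid_a <- rep(seq_len(na), times = nb)
  grid_b <- rep(seq_len(nb), each = na)
  # build obs for all (i, j) match pairs directly
  take <- function(tr, idx, what) {
    if (what == "aa") tr$sequence[idx]
    else if (what == "ang") {
      if (is.null(tr$angles)) matrix(NA_real_, length(idx), 2)
      else tr$angles[idx, , drop = FALSE]
    } else {
      if (is.null(tr$ss)) rep(NA_character_, length(idx)) else tr$ss[idx]
    }
  }
  obs_match <- obs_pairs(aa_a = take(track_a, grid_a, "aa"),
                         aa_b = take(track_b, grid_b, "aa"),
                         x_a = take(track_a, grid_a, "ang"),
                         x_b = take(track_b, grid_b, "ang"),
                         ss_a = take(track_a, grid_a, "ss"),
                         ss_b = take(track_b, grid_b, "ss"))
  Em <- .emissions(obs_match, m, t)$E            # (na*nb) x h
  obs_del <- obs_pairs(aa_a = take(track_a, seq_len(na), "aa"),
                       x_a = take(track_a, seq_len(na), "ang"),
                       ss_a = take(track_a, seq_len(na), "ss"),
                       homologous = rep(FALSE, na), n = na)
  Ed <- .emissions(obs_del, m, t)$E              # na x h
  obs_ins <- obs_pairs(aa_b = take(track_b, seq_len(nb), "aa"),
                       x_b = take(track_b, seq_len(nb), "ang"),
                       ss_b = take(track_b, seq_len(nb), "ss"),
                       homologous = rep(FALSE, nb), n = nb)
  Ei <- .emissions(obs_ins, m, t)$E              # nb x h
  list(match = array(Em, dim = c(na, nb, h)), del = Ed, ins = Ei)
}

# Core DP. mode "sum" returns log marginal + full table for sampling;
# mode "max" returns Viterbi table + backpointers.
.alignment_dp <- function(track_a, track_b, m, p, t, mode = c("sum", "max")) {
  mode <- match.arg(mode)
  na <- track_a$length; nb <- track_b$length; h <- n_states(m)
  em <- .alignment_emissions(track_a, track_b, m, t)
  tk <- tkf92_transitions(p, t)
  lA <- log(tk$trans)
  lT <- log(m$transition)
  linit <- log(m$initial)
  NEG <- -Inf
  # F[i+1, j+1, s, k]: log mass of paths consuming i residues of a and j of
  # b, last emitted column of pair-state s (1=M,2=D,3=I) and hidden state k
  F <- array(NEG, dim = c(na + 1L, nb + 1L, 3L, h))
  comb <- if (mode == "sum") function(x) .logsumexp(x) else function(x) max(x)
  # incoming mass to a column of pair-state s, hidden k, from cell (pi,pj)
  gather <- function(pi, pj, s_new) {
    # returns h-vector: logsum over s_prev, k_prev; origin handled by caller
    acc <- rep(NEG, h)
    for (sp in 1:3) {
      prev <- F[pi, pj, sp, ]
      if (all(prev == NEG)) next
      w <- prev + lA[sp + 1L, s_new]   # rows S,M,D,I -> sp+1
      for (k in seq_len(h)) {
        cand <- w + lT[, k]
        acc[k] <- comb(c(acc[k], cand))
      }
    }
    acc
  }
  for (i in 0:na) {
    for (j in 0:nb) {
      if (i == 0L && j == 0L) next
      # match
      if (i > 0L && j > 0L) {
        inc <- if (i == 1L && j == 1L && mode == "sum") NULL else NULL
        acc <- gather(i, j, 1L)
        if (i == 1L && j == 1L) {
          acc <- .pairmax_vec(acc, lA["S", "M"] + linit, comb)
        }
        F[i + 1L, j + 1L, 1L, ] <- acc + em$match[i, j, ]
      }
      # delete (consumes a_i)
      if (i > 0L) {
        acc <- gather(i, j + 1L, 2L)
        if (i == 1L && j == 0L) {
          acc <- .pairmax_vec(acc, lA["S", "D"] + linit, comb)
        }
        F[i + 1L, j + 1L, 2L, ] <- acc + em$del[i, ]
      }
      # insert (consumes b_j)
      if (j > 0L) {
        acc <- gather(i + 1L, j, 3L)
        if (i == 0L && j == 1L) {
          acc <- .pairmax_vec(acc, lA["S", "I"] + linit, comb)
        }
        F[i + 1L, j + 1L, 3L, ] <- acc + em$ins[j, ]
      }
    }
  }
  ends <- F[na + 1L, nb + 1L, , ] + lA[2:4, "E"]
  total <- comb(as.numeric(ends))
  list(F = F, total = total, lA = lA, lT = lT, linit = linit, em = em,
       na = na, nb = nb, h = h)
}

.pairmax_vec <- function(acc, extra, comb) {
  vapply(seq_along(acc), function(k) comb(c(acc[k], extra[k])), numeric(1))
}

#' Marginal log-likelihood over all pairwise alignments
#'
#' Dynamic program jointly over alignment columns (TKF92 prior), hidden
#' states and site-class pairs: computes the log probability of the two
#' observation tracks summed over every possible pairwise alignment.
#' Homologous columns emit the site-pair likelihood; indel columns emit
#' the single-sided stationary mixture. Hidden-state transitions apply
#' between consecutive emitted columns regardless of column type.
#'
#' @param track_a,track_b `"protein_track"` objects.
#' @param m an `"evo_model"`.
#' @param p a `"tkf92_params"` object.
#' @param t evolutionary time, `t >= 0`.
#' @return log marginal likelihood (scalar).
#' @export
alignment_forward <- function(track_a, track_b, m, p, t) {
  .alignment_dp(track_a, track_b, m, p, t, "sum")$total
}

#' Maximum a posteriori pairwise alignment
#'
#' Viterbi decoding of the alignment dynamic program: the jointly most
#' probable alignment path (maximizing over alignment columns, hidden
#' states and site-class pairs marginalized per site). Deterministic.
#'
#' @inheritParams alignment_forward
#' @return a `"pair_alignment"`.
#' @export
map_alignment <- function(track_a, track_b, m, p, t) {
  dp <- .alignment_dp(track_a, track_b, m, p, t, "max")
  .traceback(dp, sample = FALSE)
}

#' Sample pairwise alignments from their posterior
#'
#' Stochastic backtrace through the summed dynamic program: draws
#' alignments with probability proportional to their marginal posterior.
#'
#' @inheritParams alignment_forward
#' @param n number of alignments to draw.
#' @param seed optional integer seed.
#' @return list of `"pair_alignment"` objects.
#' @export
sample_alignments <- function(track_a, track_b, m, p, t, n = 1L, seed = NULL) {
  dp <- .alignment_dp(track_a, track_b, m, p, t, "sum")
  .with_seed(seed, {
    lapply(seq_len(n), function(s) .traceback(dp, sample = TRUE))
  })
}

# Backtrace through the DP table; sample = FALSE takes argmax (MAP),
# sample = TRUE draws proportionally (ambient RNG).
.traceback <- function(dp, sample = FALSE) {
  F <- dp$F; lA <- dp$lA; lT <- dp$lT; h <- dp$h
  pick <- function(lw) {
    lw[is.na(lw)] <- -Inf
    if (sample) {
      w <- exp(lw - max(lw))
      sample.int(length(lw), 1L, prob = w)
    } else which.max(lw)
  }
  ends <- F[dp$na + 1L, dp$nb + 1L, , ] + lA[2:4, "E"]
  if (h == 1L) ends <- matrix(ends, ncol = 1L)
  idx <- pick(as.numeric(ends))
  s_cur <- ((idx - 1L) %% 3L) + 1L
  k_cur <- ((idx - 1L) %/% 3L) + 1L
  i <- dp$na; j <- dp$nb
  types <- c("match", "delete", "insert")
  cols <- list()
  while (TRUE) {
    cols[[length(cols) + 1L]] <- list(type = types[s_cur],
                                      i = if (s_cur != 3L) i else NA_integer_,
                                      j = if (s_cur != 2L) j else NA_integer_)
    pi <- i - (s_cur != 3L); pj <- j - (s_cur != 2L)
    if (pi == 0L && pj == 0L) break
    # choose predecessor (s_prev, k_prev)
    lw <- matrix(-Inf, 3L, h)
    for (sp in 1:3) {
      lw[sp, ] <- F[pi + 1L, pj + 1L, sp, ] + lA[sp + 1L, s_cur] + lT[, k_cur]
    }
    idx <- pick(as.numeric(lw))
    s_cur <- ((idx - 1L) %% 3L) + 1L
    k_cur <- ((idx - 1L) %/% 3L) + 1L
    i <- pi; j <- pj
  }
  cols <- rev(cols)
  pair_alignment(type = vapply(cols, `[[`, character(1), "type"),
                 index_a = vapply(cols, function(c) c$i %||% NA_integer_, integer(1)),
                 index_b = vapply(cols, function(c) c$j %||% NA_integer_, integer(1)))
}

# ---- Evaluation metrics --------------------------------------------------

.column_keys <- function(al) {
  paste(al$type, ifelse(is.na(al$index_a), "-", al$index_a),
        ifelse(is.na(al$index_b), "-", al$index_b), sep = ":")
}

#' Alignment similarity
#'
#' Similarity between two alignments of the same sequence pair:
#' `2 * |shared columns| / (m_pred + m_ref)`, where columns are compared by
#' type and the residue indices they implicate. 1 for identical alignments
#' and 0 when no column is shared.
#'
#' @param pred,ref `"pair_alignment"` objects over the same sequence pair.
#' @return numeric in `[0, 1]`.
#' @export
alignment_similarity <- function(pred, ref) {
  .check_same_pair(pred, ref)
  shared <- length(intersect(.column_keys(pred), .column_keys(ref)))
  2 * shared / (nrow(pred) + nrow(ref))
}

#' Precision of homology prediction
#'
#' The fraction of predicted homologous (match) columns that are also
#' homologous columns of the reference alignment.
#'
#' @inheritParams alignment_similarity
#' @return numeric in `[0, 1]`; errors when `pred` has no match columns.
#' @export
homology_precision <- function(pred, ref) {
  .check_same_pair(pred, ref)
  hp <- pred[pred$type == "match", c("index_a", "index_b")]
  hr <- ref[ref$type == "match", c("index_a", "index_b")]
  if (nrow(hp) == 0L) {
    stop("homology_precision: prediction contains no homologous columns")
  }
  keys <- function(d) paste(d$index_a, d$index_b)
  length(intersect(keys(hp), keys(hr))) / nrow(hp)
}

.check_same_pair <- function(pred, ref) {
  la <- function(al) c(sum(al$type != "insert"), sum(al$type != "delete"))
  if (!identical(la(pred), la(ref))) {
    stop("alignments cover different sequence lengths")
  }
  invisible(TRUE)
}

# ---- Gapped-FASTA conversion --------------------------------------------

#' Convert between pair alignments and gapped sequence strings
#'
#' `alignment_to_gapped` renders an alignment as two equal-length gapped
#' strings; `gapped_to_alignment` parses them back.
#'
#' @param al a `"pair_alignment"`.
#' @param seq_a,seq_b ungapped character vectors (or strings) of the two
#'   sequences.
#' @return `alignment_to_gapped`: character vector of two gapped strings.
#' @export
alignment_to_gapped <- function(al, seq_a, seq_b) {
  if (length(seq_a) == 1L) seq_a <- strsplit(seq_a, "")[[1]]
  if (length(seq_b) == 1L) seq_b <- strsplit(seq_b, "")[[1]]
  if (sum(al$type != "insert") != length(seq_a) ||
      sum(al$type != "delete") != length(seq_b)) {
    stop("alignment_to_gapped: sequence lengths do not match the alignment")
  }
  ga <- ifelse(is.na(al$index_a), "-", seq_a[al$index_a])
  gb <- ifelse(is.na(al$index_b), "-", seq_b[al$index_b])
  c(paste(ga, collapse = ""), paste(gb, collapse = ""))
}

#' Read / write a pair alignment as a TSV of column records
#'
#' Columns `type` (match/delete/insert), `index_a`, `index_b`, one row per
#' alignment column; `NA` where a column does not touch a protein.
#'
#' @param al a `"pair_alignment"`.
#' @param path file path.
#' @return `read_alignment_tsv`: the restored `"pair_alignment"`.
#' @export
write_alignment_tsv <- function(al, path) {
  utils::write.table(as.data.frame(al), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_alignment_tsv
#' @export
read_alignment_tsv <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, na.strings = "NA")
  pair_alignment(d$type, d$index_a, d$index_b)
}

#' @rdname alignment_to_gapped
#' @param gapped_a,gapped_b equal-length gapped strings.
#' @return `gapped_to_alignment`: a `"pair_alignment"`.
#' @export
gapped_to_alignment <- function(gapped_a, gapped_b) {
  ca <- strsplit(gapped_a, "")[[1]]
  cb <- strsplit(gapped_b, "")[[1]]
  if (length(ca) != length(cb)) stop("gapped rows must have equal length")
  ga <- ca == "-"; gb <- cb == "-"
  if (any(ga & gb)) stop("column with gaps on both sides")
  type <- ifelse(!ga & !gb, "match", ifelse(gb, "delete", "insert"))
  pair_alignment(type,
                 index_a = ifelse(ga, NA_integer_, cumsum(!ga)),
                 index_b = ifelse(gb, NA_integer_, cumsum(!gb)))
}
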