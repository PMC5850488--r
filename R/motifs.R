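#' Detect jump-event evolutionary motif sites
#'
#' Two-stage criterion for aligned sites showing evidence of a site-class
#' jump. Stage one conditions on both amino-acid sequences and both
#' dihedral-angle tracks and requires the joint posterior
#' `p(H_i = k, r_a != r_b | A_a, A_b, X_a, X_b)` to exceed
#' `primary_threshold` for a single hidden state k. Stage two drops one
#' angle track at a time and requires the same joint posterior (same
#' state k) to exceed `secondary_threshold` under at least one
#' single-structure condition, ensuring the motif is identifiable when
#' only one structure is available. Thresholds are strict inequalities.
#'
#' @param o an `"obs_pairs"` data.frame with amino acids and both angle
#'   tracks present.
#' @param m an `"evo_model"`.
#' @param t evolutionary time.
#' @param primary_threshold stage-one posterior threshold (default 0.90).
#' @param secondary_threshold stage-two posterior threshold (default 0.50).
#' @return data.frame with one row per detected site: `site`, `state`,
#'   `posterior_full`, `posterior_a_only`, `posterior_b_only`.
#' @export
detect_jump_sites <- function(o, m, t, primary_threshold = 0.90,
                              secondary_threshold = 0.50) {
  o <- validate_obs_pairs(o)
  hom <- o$homologous
  if (!any(!is.na(o$aa_a) & hom) || !any(!is.na(o$aa_b) & hom) ||
      !any(!is.na(o$phi_a) & hom) || !any(!is.na(o$phi_b) & hom)) {
    stop("detect_jump_sites: both sequences and both angle tracks required")
  }
  empty <- data.frame(site = integer(0), state = integer(0),
                      posterior_full = numeric(0),
                      posterior_a_only = numeric(0),
                      posterior_b_only = numeric(0))
  if (t == 0) return(empty)  # the jump prior carries no mass at t = 0
  o_full <- obs_mask(o, c("aa_a", "aa_b", "x_a", "x_b"))
  j_full <- posterior_jump(o_full, m, t)
  j_a <- posterior_jump(obs_mask(o, c("aa_a", "aa_b", "x_a")), m, t)
  j_b <- posterior_jump(obs_mask(o, c("aa_a", "aa_b", "x_b")), m, t)
  best_k <- max.col(j_full, ties.method = "first")
  idx <- cbind(seq_len(nrow(o)), best_k)
  p_full <- j_full[idx]; p_a <- j_a[idx]; p_b <- j_b[idx]
  hit <- hom & p_full > primary_threshold &
    (p_a > secondary_threshold | p_b > secondary_threshold)
  data.frame(site = which(hit), state = best_k[hit],
             posterior_full = p_full[hit],
             posterior_a_only = p_a[hit], posterior_b_only = p_b[hit])
}

# Observation-track combinations of the prediction benchmark: which fields
# are conditioned on when predicting the dihedral angles of protein b.
.benchmark_combos <- list(
  `1` = character(0),
  `2` = c("aa_b"),
  `3` = c("aa_a", "aa_b"),
  `4` = c("aa_a", "aa_b", "ss_a"),
  `5` = c("aa_a", "aa_b", "x_a"),
  `6` = c("aa_a", "aa_b", "x_a"))

#' Predictive accuracy benchmark for missing dihedral angles
#'
#' Treats the dihedral angles of protein b as missing, imputes them under
#' the model conditioned on one of six standard observation combinations,
#' and returns the mean angular distance between imputed and true angles.
#' Combinations: (1) nothing, (2) the target's own sequence, (3) both
#' sequences, (4) both sequences and the homolog's secondary structure,
#' (5) both sequences and the homolog's dihedral angles, (6) as (5) with
#' the alignment treated as known a priori. For combinations 1-5 the
#' alignment is marginalized: alignments are sampled from their posterior
#' given the conditioned tracks under the TKF92 prior, then missing fields
#' are imputed per sampled alignment.
#'
#' @param track_a,track_b `"protein_track"` objects; `track_b$angles` is
#'   the held-out truth.
#' @param m an `"evo_model"`.
#' @param combination integer 1-6.
#' @param t evolutionary time used for the imputation.
#' @param tkf a `"tkf92_params"` (needed for combinations 1-5).
#' @param alignment the reference `"pair_alignment"` (needed for
#'   combination 6).
#' @param n_samples number of imputation samples.
#' @param seed optional integer seed.
#' @return list with `mean_distance` (mean over sites and samples),
#'   `per_site` (mean per residue of b), and `n_sites`.
#' @export
predict_benchmark <- function(track_a, track_b, m, combination, t,
                              tkf = NULL, alignment = NULL,
                              n_samples = 10L, seed = NULL) {
  stopifnot(combination %in% 1:6)
  if (is.null(track_b$angles) || any(is.na(track_b$angles))) {
    stop("predict_benchmark: track_b must carry complete true angles")
  }
  keep <- .benchmark_combos[[as.character(combination)]]
  if (("ss_a" %in% keep) && is.null(track_a$ss)) {
    stop("predict_benchmark: combination requires a secondary-structure track")
  }
  if (("x_a" %in% keep) && is.null(track_a$angles)) {
    stop("predict_benchmark: combination requires the homolog's angles")
  }
  truth <- track_b$angles
  nb <- track_b$length
  .with_seed(seed, {
    if (combination == 6L) {
      if (is.null(alignment)) {
        stop("predict_benchmark: combination 6 needs a fixed alignment")
      }
      als <- rep(list(alignment), n_samples)
    } else {
      if (is.null(tkf)) {
        stop("predict_benchmark: combinations 1-5 need TKF92 parameters")
      }
      mask_track <- function(tr, aa_keep, ang_keep, ss_keep) {
        protein_track(tr$id, tr$sequence,
                      angles = if (ang_keep) tr$angles,
                      ss = if (ss_keep) tr$ss)
      }
      ta <- mask_track(track_a, TRUE, "x_a" %in% keep, "ss_a" %in% keep)
      tb <- mask_track(track_b, TRUE, FALSE, FALSE)
      # sequence content only enters through the kept tracks
      if (!("aa_a" %in% keep)) ta$sequence[] <- NA_character_
      if (!("aa_b" %in% keep)) tb$sequence[] <- NA_character_
      als <- sample_alignments(ta, tb, m, tkf, t, n = n_samples)
    }
    errs <- matrix(NA_real_, n_samples, nb)
    for (s in seq_len(n_samples)) {
      al <- als[[s]]
      o <- align_tracks(track_a, track_b, al)
      o <- obs_mask(o, keep)
      imp <- sample_missing(o, m, t, n_samples = 1L)[[1]]
      # recover imputed angles of b per residue
      rows <- which(!is.na(al$index_b))
      ord <- al$index_b[rows]
      xb <- cbind(imp$phi_b[rows], imp$psi_b[rows])[order(ord), , drop = FALSE]
      errs[s, ] <- angular_distance(xb, truth)
    }
    list(mean_distance = mean(errs), per_site = colMeans(errs),
         n_sites = nb)
  })
}
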