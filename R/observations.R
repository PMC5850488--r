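#' Observation pairs at aligned sites
#'
#' Builds the per-site observation table for an aligned pair of homologous
#' proteins. Each row is one alignment column carrying up to three
#' observation pairs: amino acids (`aa_a`, `aa_b`), dihedral angles
#' (`phi_a`, `psi_a`, `phi_b`, `psi_b`, radians, wrapped) and secondary
#' structure classes (`ss_a`, `ss_b`). Any field may be `NA` (missing).
#' `homologous` is `FALSE` for insertion/deletion columns, where exactly
#' one side carries data.
#'
#' @param aa_a,aa_b character vectors of amino-acid one-letter codes or NA.
#' @param x_a,x_b n x 2 matrices of (phi, psi) pairs, or NULL; NA rows mark
#'   missing angles.
#' @param ss_a,ss_b character vectors in `{H, S, C}` or NA.
#' @param homologous logical vector; defaults to all TRUE.
#' @param n number of sites (inferred from the longest argument if omitted).
#' @return data.frame of class `"obs_pairs"`.
#' @export
obs_pairs <- function(aa_a = NULL, aa_b = NULL, x_a = NULL, x_b = NULL,
                      ss_a = NULL, ss_b = NULL, homologous = NULL, n = NULL) {
  lens <- c(length(aa_a), length(aa_b), NROW(x_a), NROW(x_b),
            length(ss_a), length(ss_b), length(homologous), n %||% 0L)
  m <- max(lens)
  if (m == 0L) stop("obs_pairs: no sites")
  fill_chr <- function(v) if (is.null(v)) rep(NA_character_, m) else {
    stopifnot(length(v) == m); as.character(v)
  }
  fill_ang <- function(v) if (is.null(v)) matrix(NA_real_, m, 2) else {
    stopifnot(NROW(v) == m, NCOL(v) == 2)
    v <- as.matrix(v)
    ok <- !is.na(v[, 1])
    v[ok, ] <- wrap_angle(v[ok, , drop = FALSE])
    v
  }
  xa <- fill_ang(x_a); xb <- fill_ang(x_b)
  out <- data.frame(
    aa_a = fill_chr(aa_a), aa_b = fill_chr(aa_b),
    phi_a = xa[, 1], psi_a = xa[, 2], phi_b = xb[, 1], psi_b = xb[, 2],
    ss_a = fill_chr(ss_a), ss_b = fill_chr(ss_b),
    homologous = if (is.null(homologous)) rep(TRUE, m) else as.logical(homologous),
    stringsAsFactors = FALSE)
  validate_obs_pairs(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname obs_pairs
#' @param o a candidate `"obs_pairs"` data.frame.
#' @export
validate_obs_pairs <- function(o) {
  req <- c("aa_a", "aa_b", "phi_a", "psi_a", "phi_b", "psi_b",
           "ss_a", "ss_b", "homologous")
  if (!all(req %in% names(o))) stop("obs_pairs: missing columns")
  chk_aa <- c(o$aa_a, o$aa_b)
  if (any(!is.na(chk_aa) & !chk_aa %in% AA_ALPHABET)) {
    stop("obs_pairs: unknown amino-acid code")
  }
  chk_ss <- c(o$ss_a, o$ss_b)
  if (any(!is.na(chk_ss) & !chk_ss %in% SS_ALPHABET)) {
    stop("obs_pairs: unknown secondary-structure class")
  }
  if (any(is.na(o$phi_a) != is.na(o$psi_a)) ||
      any(is.na(o$phi_b) != is.na(o$psi_b))) {
    stop("obs_pairs: phi and psi must be jointly present or jointly missing")
  }
  has_a <- !is.na(o$aa_a) | !is.na(o$phi_a) | !is.na(o$ss_a)
  has_b <- !is.na(o$aa_b) | !is.na(o$phi_b) | !is.na(o$ss_b)
  bad <- !o$homologous & has_a & has_b
  if (any(bad)) {
    stop("obs_pairs: non-homologous columns must carry data on one side only")
  }
  class(o) <- unique(c("obs_pairs", class(o)))
  o
}

#' Swap the a/b sides of every observation field
#'
#' By time-reversibility either protein may be chosen as the ancestor;
#' swapping the sides never changes any likelihood in the package.
#'
#' @param o an `"obs_pairs"` data.frame.
#' @return the swapped `"obs_pairs"`.
#' @export
obs_swap <- function(o) {
  sw <- o
  sw$aa_a <- o$aa_b;  sw$aa_b <- o$aa_a
  sw$phi_a <- o$phi_b; sw$psi_a <- o$psi_b
  sw$phi_b <- o$phi_a; sw$psi_b <- o$psi_a
  sw$ss_a <- o$ss_b;  sw$ss_b <- o$ss_a
  sw
}

#' Mask observation tracks
#'
#' Keeps only the named fields, setting all others to missing; used to
#' condition inference on subsets of the data (e.g. sequences only).
#'
#' @param o an `"obs_pairs"` data.frame.
#' @param keep character subset of
#'   `c("aa_a", "aa_b", "x_a", "x_b", "ss_a", "ss_b")`.
#' @return the masked `"obs_pairs"`.
#' @export
obs_mask <- function(o, keep) {
  all_fields <- c("aa_a", "aa_b", "x_a", "x_b", "ss_a", "ss_b")
  stopifnot(all(keep %in% all_fields))
  drop <- setdiff(all_fields, keep)
  if ("aa_a" %in% drop) o$aa_a <- NA_character_
  if ("aa_b" %in% drop) o$aa_b <- NA_character_
  if ("x_a" %in% drop) { o$phi_a <- NA_real_; o$psi_a <- NA_real_ }
  if ("x_b" %in% drop) { o$phi_b <- NA_real_; o$psi_b <- NA_real_ }
  if ("ss_a" %in% drop) o$ss_a <- NA_character_
  if ("ss_b" %in% drop) o$ss_b <- NA_character_
  o
}

#' Single-protein observation track
#'
#' Per-residue observations for one protein: sequence, optional dihedral
#' angles and optional secondary structure.
#'
#' @param id protein identifier.
#' @param sequence character vector of one-letter residues (or a single
#'   string, which is split).
#' @param angles optional n x 2 matrix of (phi, psi), radians; NA rows for
#'   missing (e.g. chain termini).
#' @param ss optional character vector in `{H, S, C}`.
#' @return object of class `"protein_track"` (a list).
#' @export
protein_track <- function(id, sequence, angles = NULL, ss = NULL) {
  if (length(sequence) == 1L && nchar(sequence) > 1L) {
    sequence <- strsplit(sequence, "")[[1]]
  }
  sequence <- toupper(sequence)
  n <- length(sequence)
  if (any(!sequence %in% c(AA_ALPHABET, NA))) {
    stop("protein_track: non-canonical residue in sequence")
  }
  if (!is.null(angles)) {
    stopifnot(NROW(angles) == n, NCOL(angles) == 2)
    angles <- as.matrix(angles)
    ok <- !is.na(angles[, 1])
    angles[ok, ] <- wrap_angle(angles[ok, , drop = FALSE])
  }
  if (!is.null(ss)) {
    stopifnot(length(ss) == n)
    if (any(!is.na(ss) & !ss %in% SS_ALPHABET)) {
      stop("protein_track: unknown secondary-structure class")
    }
  }
  structure(list(id = id, sequence = sequence, angles = angles, ss = ss,
                 length = n),
            class = "protein_track")
}

# Assemble an obs_pairs table from two tracks and a pair alignment.
#' Build aligned observation pairs from two protein tracks
#'
#' @param track_a,track_b `"protein_track"` objects.
#' @param alignment a `"pair_alignment"` (see [pair_alignment()]); defaults
#'   to the all-homologous diagonal alignment (requires equal lengths).
#' @return an `"obs_pairs"` data.frame with one row per alignment column.
#' @export
align_tracks <- function(track_a, track_b, alignment = NULL) {
  if (is.null(alignment)) {
    if (track_a$length != track_b$length) {
      stop("align_tracks: unequal lengths require an explicit alignment")
    }
    alignment <- pair_alignment(type = rep("match", track_a$length),
                                index_a = seq_len(track_a$length),
                                index_b = seq_len(track_b$length))
  }
  m <- nrow(alignment)
  pick <- function(tr, idx, what) {
    out <- switch(what,
      aa = rep(NA_character_, m),
      ang = matrix(NA_real_, m, 2),
      ss = rep(NA_character_, m))
    ok <- !is.na(idx)
    if (what == "aa") out[ok] <- tr$sequence[idx[ok]]
    if (what == "ang" && !is.null(tr$angles)) out[ok, ] <- tr$angles[idx[ok], ]
    if (what == "ss" && !is.null(tr$ss)) out[ok] <- tr$ss[idx[ok]]
    out
  }
  obs_pairs(aa_a = pick(track_a, alignment$index_a, "aa"),
            aa_b = pick(track_b, alignment$index_b, "aa"),
            x_a = pick(track_a, alignment$index_a, "ang"),
            x_b = pick(track_b, alignment$index_b, "ang"),
            ss_a = pick(track_a, alignment$index_a, "ss"),
            ss_b = pick(track_b, alignment$index_b, "ss"),
            homologous = alignment$type == "match")
}
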