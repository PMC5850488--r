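#' Read and write protein sequences as FASTA
#'
#' Sequences are uppercased on input. Non-canonical residue codes either
#' raise an error (default) or are treated as missing, per
#' `non_canonical`. Gapped two-row FASTA files are supported for
#' alignments via [read_alignment_fasta()].
#'
#' @param path file path.
#' @param non_canonical `"error"` or `"missing"`.
#' @return list of `"protein_track"` objects (sequences only).
#' @export
read_fasta <- function(path, non_canonical = c("error", "missing")) {
  non_canonical <- match.arg(non_canonical)
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = FALSE,
                             forceDNAtolower = FALSE)
  lapply(seq_along(recs), function(i) {
    s <- toupper(as.character(recs[[i]]))
    bad <- !s %in% AA_ALPHABET
    if (any(bad)) {
      if (non_canonical == "error") {
        stop(sprintf("read_fasta: non-canonical residue '%s' in %s",
                     s[which(bad)[1]], names(recs)[i]))
      }
      s[bad] <- NA_character_
    }
    protein_track(names(recs)[i], s)
  })
}

#' @rdname read_fasta
#' @param tracks list of `"protein_track"` objects.
#' @export
write_fasta <- function(tracks, path) {
  seqs <- lapply(tracks, function(tr) ifelse(is.na(tr$sequence), "X", tr$sequence))
  seqinr::write.fasta(seqs, names = vapply(tracks, `[[`, character(1), "id"),
                      file.out = path)
  invisible(path)
}

#' Read / write a pairwise alignment as gapped two-row FASTA
#'
#' @param path file path.
#' @return `read_alignment_fasta`: list with the `"pair_alignment"` and the
#'   two ungapped sequences.
#' @export
read_alignment_fasta <- function(path) {
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  if (length(recs) != 2L) stop("alignment FASTA must contain exactly 2 records")
  g1 <- toupper(as.character(recs[[1]])); g2 <- toupper(as.character(recs[[2]]))
  al <- gapped_to_alignment(g1, g2)
  list(alignment = al,
       seq_a = gsub("-", "", g1), seq_b = gsub("-", "", g2),
       ids = names(recs))
}

#' @rdname read_alignment_fasta
#' @param al a `"pair_alignment"`.
#' @param seq_a,seq_b ungapped sequences (strings or character vectors).
#' @param ids identifiers for the two rows.
#' @export
write_alignment_fasta <- function(al, seq_a, seq_b, path,
                                  ids = c("protein_a", "protein_b")) {
  g <- alignment_to_gapped(al, seq_a, seq_b)
  seqinr::write.fasta(as.list(g), names = ids, file.out = path)
  invisible(path)
}

#' Read / write per-residue observation tracks as TSV
#'
#' The package's native observation format: tab-separated columns
#' `index` (1-based), `residue` (one-letter code), `phi`, `psi` (radians)
#' and `ss` (H/S/C), with `NA` for missing values. Eight-class secondary
#' structure labels are reduced to three classes (H,G,I to H; E,B to S;
#' everything else to C).
#'
#' @param path file path.
#' @param id protein identifier (defaults to the file name).
#' @return a `"protein_track"`.
#' @export
read_track_tsv <- function(path, id = NULL) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, na.strings = "NA",
                         colClasses = c("integer", "character", "numeric",
                                        "numeric", "character"))
  if (!identical(names(d), c("index", "residue", "phi", "psi", "ss"))) {
    stop("track TSV must have columns index, residue, phi, psi, ss")
  }
  if (!identical(d$index, seq_len(nrow(d)))) {
    stop("track TSV indices must run 1..n")
  }
  ss <- reduce_ss_classes(d$ss)
  protein_track(id %||% basename(path), toupper(d$residue),
                angles = cbind(d$phi, d$psi), ss = ss)
}

#' @rdname read_track_tsv
#' @param track a `"protein_track"`.
#' @export
write_track_tsv <- function(track, path) {
  ang <- track$angles %||% matrix(NA_real_, track$length, 2)
  d <- data.frame(index = seq_len(track$length), residue = track$sequence,
                  phi = ang[, 1], psi = ang[, 2],
                  ss = track$ss %||% rep(NA_character_, track$length))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Reduce 8-class secondary structure labels to 3 classes
#'
#' H, G, I map to helix (H); E, B map to sheet (S); all other labels map
#' to coil (C). Labels already in `{H, S, C}` are preserved; NA stays NA.
#'
#' @param ss character vector of labels.
#' @return character vector in `{H, S, C, NA}`.
#' @export
reduce_ss_classes <- function(ss) {
  out <- ifelse(is.na(ss), NA_character_,
         ifelse(ss %in% c("H", "G", "I"), "H",
         ifelse(ss %in% c("E", "B", "S"), "S", "C")))
  out
}

# ---- PDB dihedral extraction --------------------------------------------

# Torsion angle of four points (rows of a 4 x 3 matrix), radians in
# [-pi, pi), IUPAC sign convention.
.dihedral4 <- function(P) {
  b1 <- P[2, ] - P[1, ]
  b2 <- P[3, ] - P[2, ]
  b3 <- P[4, ] - P[3, ]
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  # sign follows the biopolymer convention (clockwise positive looking
  # down the central bond), matching standard torsion tools
  wrap_angle(-atan2(sum(m1 * n2), sum(n1 * n2)))
}

#' Extract backbone dihedral angles from a PDB file
#'
#' Reads the coordinates with `bio3d` and computes the (phi, psi) dihedral
#' angles from the backbone N, CA, C atoms: `phi_i` from
#' `(C_{i-1}, N_i, CA_i, C_i)` and `psi_i` from `(N_i, CA_i, C_i,
#' N_{i+1})`. Chain termini and residues adjacent to missing backbone
#' atoms or chain breaks get missing angles rather than failing.
#'
#' @param pdb_path path to a PDB file.
#' @param chain chain identifier (default the first chain present).
#' @return a `"protein_track"` with sequence and angles (no secondary
#'   structure).
#' @export
extract_dihedrals <- function(pdb_path, chain = NULL) {
  pdb <- bio3d::read.pdb(pdb_path)
  at <- pdb$atom[pdb$atom$type == "ATOM", ]
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[at$chain == chain, ]
  if (nrow(at) == 0L) stop(sprintf("chain '%s' not found", chain))
  resnos <- unique(at$resno)
  n <- length(resnos)
  if (n < 2L) stop("chain must contain at least 2 residues")
  getxyz <- function(resno, elety) {
    r <- at[at$resno == resno & at$elety == elety, c("x", "y", "z")]
    if (nrow(r) == 0L) return(NULL)
    as.numeric(r[1, ])
  }
  aa3to1 <- stats::setNames(bio3d::aa321(bio3d::aa.table$aa3),
                            bio3d::aa.table$aa3)
  seqv <- vapply(resnos, function(rn) {
    r3 <- at$resid[at$resno == rn][1]
    s <- unname(aa3to1[r3])
    if (is.na(s) || !s %in% AA_ALPHABET) NA_character_ else s
  }, character(1))
  ang <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    Ni <- getxyz(resnos[i], "N"); CAi <- getxyz(resnos[i], "CA")
    Ci <- getxyz(resnos[i], "C")
    if (is.null(Ni) || is.null(CAi) || is.null(Ci)) next
    if (i > 1L && resnos[i - 1L] == resnos[i] - 1L) {
      Cp <- getxyz(resnos[i - 1L], "C")
      if (!is.null(Cp)) ang[i, 1] <- .dihedral4(rbind(Cp, Ni, CAi, Ci))
    }
    if (i < n && resnos[i + 1L] == resnos[i] + 1L) {
      Nn <- getxyz(resnos[i + 1L], "N")
      if (!is.null(Nn)) ang[i, 2] <- .dihedral4(rbind(Ni, CAi, Ci, Nn))
    }
  }
  # a track requires phi and psi jointly present; termini keep both missing
  half <- xor(is.na(ang[, 1]), is.na(ang[, 2]))
  ang[half, ] <- NA_real_
  protein_track(paste0(basename(pdb_path), "_", chain), seqv, angles = ang)
}

# ---- Model serialization -------------------------------------------------

MODEL_SCHEMA_VERSION <- "1.0"

#' Serialize / deserialize a model as JSON
#'
#' Round-trips every parameter at full precision; the schema is versioned
#' and all type invariants are re-validated on load.
#'
#' @param m an `"evo_model"`.
#' @param path file path.
#' @return `read_model`: the restored `"evo_model"`.
#' @export
write_model <- function(m, path) {
  ser_class <- function(sc) list(
    aa_equilibrium = unname(sc$aa_equilibrium), aa_scale = sc$aa_scale,
    ss_equilibrium = unname(sc$ss_equilibrium),
    wn = list(mu = sc$wn$mu, alpha1 = sc$wn$alpha1, alpha2 = sc$wn$alpha2,
              alpha3 = sc$wn$alpha3, sigma1 = sc$wn$sigma1,
              sigma2 = sc$wn$sigma2))
  obj <- list(
    schema_version = MODEL_SCHEMA_VERSION,
    aa_alphabet = AA_ALPHABET, ss_alphabet = SS_ALPHABET,
    K = m$K,
    S = m$S, V = m$V, transition = m$transition,
    states = lapply(m$states, function(st) list(
      class_equilibrium = st$class_equilibrium, jump_rate = st$jump_rate,
      class1 = ser_class(st$classes[[1]]), class2 = ser_class(st$classes[[2]]))))
  # 17 significant digits: doubles round-trip bit-exactly
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (!identical(obj$schema_version, MODEL_SCHEMA_VERSION)) {
    stop(sprintf("model schema version mismatch: got '%s', expected '%s'",
                 obj$schema_version, MODEL_SCHEMA_VERSION))
  }
  des_class <- function(sc) {
    site_class(sc$aa_equilibrium, sc$aa_scale, sc$ss_equilibrium,
               wn_params(sc$wn$mu, sc$wn$alpha1, sc$wn$alpha2, sc$wn$alpha3,
                         sc$wn$sigma1, sc$wn$sigma2))
  }
  sts <- obj$states
  mk_state <- function(i) {
    if (is.data.frame(sts)) {
      stop("model JSON states malformed")  # guards simplification surprises
    }
    st <- sts[[i]]
    hidden_state(des_class(st$class1), des_class(st$class2),
                 st$class_equilibrium, st$jump_rate)
  }
  states <- lapply(seq_along(sts), mk_state)
  evo_model(states, as.matrix(obj$transition), as.matrix(obj$S),
            as.matrix(obj$V), K = obj$K)
}

# ---- Synthetic fixture generation ---------------------------------------

#' Generate an on-disk synthetic dataset
#'
#' Simulates homologous pairs from a model across a grid of evolutionary
#' times, optionally introducing indel columns via the TKF92 prior, and
#' writes per-protein FASTA and track TSV files, true alignments (gapped
#' FASTA), the true model (JSON) and a manifest. Deterministic under the
#' seed.
#'
#' @param dir output directory (created if needed).
#' @param m generating `"evo_model"` (default [example_model()]).
#' @param lengths integer vector of pair lengths (homologous sites).
#' @param t_values numeric vector of evolutionary times, recycled across
#'   pairs.
#' @param indel_prob per-boundary probability of opening an indel run in
#'   the simulated alignment (0 for indel-free pairs).
#' @param seed integer seed.
#' @return invisibly, the manifest data.frame.
#' @export
generate_fixtures <- function(dir, m = example_model(), lengths = rep(100L, 5L),
                              t_values = c(0.1, 0.3, 0.5, 0.8, 1.2),
                              indel_prob = 0.03, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  t_values <- rep_len(t_values, length(lengths))
  write_model(m, file.path(dir, "true_model.json"))
  rows <- list()
  for (i in seq_along(lengths)) {
    pr <- .with_seed(seed + i, {
      sim <- simulate_pair(m, lengths[i], t_values[i])
      obs <- sim$obs
      if (indel_prob > 0) {
        obs <- .sprinkle_indels(obs, m, indel_prob)
      }
      obs
    })
    trks <- obs_to_tracks(pr, ids = paste0("pair", i, c("_a", "_b")))
    base <- file.path(dir, sprintf("pair%02d", i))
    write_track_tsv(trks$a, paste0(base, "_a.tsv"))
    write_track_tsv(trks$b, paste0(base, "_b.tsv"))
    write_fasta(list(trks$a, trks$b), paste0(base, ".fasta"))
    al <- .obs_to_alignment(pr)
    write_alignment_fasta(al, trks$a$sequence, trks$b$sequence,
                          paste0(base, "_alignment.fasta"),
                          ids = c(trks$a$id, trks$b$id))
    rows[[i]] <- data.frame(pair = i, length = nrow(pr), t = t_values[i],
                            n_indels = sum(!pr$homologous))
  }
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

# Insert single-sided columns between homologous sites (ambient RNG):
# geometric runs, content drawn from a random state's class-1 stationary.
.sprinkle_indels <- function(obs, m, indel_prob) {
  out <- list()
  for (i in seq_len(nrow(obs))) {
    out[[length(out) + 1L]] <- obs[i, ]
    while (stats::runif(1) < indel_prob) {
      k <- sample.int(n_states(m), 1L)
      cl <- m$states[[k]]$classes[[1L]]
      side_a <- stats::runif(1) < 0.5
      x <- wn_sample_stationary(cl$wn, 1L)
      aa <- sample(AA_ALPHABET, 1L, prob = cl$aa_equilibrium)
      ss <- sample(SS_ALPHABET, 1L, prob = cl$ss_equilibrium)
      row <- obs_pairs(n = 1L)
      if (side_a) {
        row$aa_a <- aa; row$phi_a <- x[1]; row$psi_a <- x[2]; row$ss_a <- ss
      } else {
        row$aa_b <- aa; row$phi_b <- x[1]; row$psi_b <- x[2]; row$ss_b <- ss
      }
      row$homologous <- FALSE
      out[[length(out) + 1L]] <- row
    }
  }
  validate_obs_pairs(do.call(rbind, out))
}

# Derive the pair_alignment implied by an obs table's column structure.
.obs_to_alignment <- function(o) {
  has_a <- !is.na(o$aa_a) | !is.na(o$phi_a) | !is.na(o$ss_a)
  type <- ifelse(o$homologous, "match", ifelse(has_a, "delete", "insert"))
  ia <- rep(NA_integer_, nrow(o)); ib <- ia
  sel_a <- type != "insert"; sel_b <- type != "delete"
  ia[sel_a] <- seq_len(sum(sel_a)); ib[sel_b] <- seq_len(sum(sel_b))
  pair_alignment(type, ia, ib)
}
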