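# Synthetic inputs for the pipeline: (a) class-structured Bernoulli
# fingerprint datasets with planted common / subfamily-specific contacts and
# (b) toy two-chain 3-D complexes whose residue geometry triggers each
# contact criterion. Fingerprint frames are temporally i.i.d. (no
# autocorrelation) - persistence and discriminant statistics depend only on
# marginal occupancies.

#' Specification of a planted fingerprint dataset
#'
#' Three G protein classes (Gs, Gi, Gq), each with a set of systems and
#' i.i.d. Bernoulli contact occupancies per pair: common pairs are occupied
#' with \code{p_common} in every system, class-specific pairs with
#' \code{p_specific_own} in their own class and \code{p_specific_other}
#' elsewhere, background pairs with \code{p_background} everywhere.
#'
#' @param systems_per_class systems per G protein class
#' @param n_frames frames per system
#' @param n_background_pairs,n_common_pairs number of background / common
#'   pairs
#' @param n_specific_pairs class-specific pairs per class
#' @param p_common,p_specific_own,p_specific_other,p_background Bernoulli
#'   occupancies
#' @param seed RNG seed
#' @return list of class \code{st_planted_spec}
#' @export
planted_spec <- function(systems_per_class = 2L, n_frames = 500L,
                         n_background_pairs = 40L, n_common_pairs = 6L,
                         n_specific_pairs = 3L, p_common = 0.6,
                         p_specific_own = 0.6, p_specific_other = 0.02,
                         p_background = 0.05, seed = 1L) {
  probs <- c(p_common, p_specific_own, p_specific_other, p_background)
  if (any(probs < 0 | probs > 1)) {
    stop("occupancy probabilities must lie in [0, 1]", call. = FALSE)
  }
  counts <- c(systems_per_class, n_background_pairs, n_common_pairs,
              n_specific_pairs)
  if (any(counts < 0) || systems_per_class < 1L) {
    stop("counts must be non-negative, with >= 1 system per class",
         call. = FALSE)
  }
  if (n_frames < 1L) stop("n_frames must be >= 1", call. = FALSE)
  if (n_background_pairs + n_common_pairs + 3L * n_specific_pairs < 1L) {
    stop("at least one pair required", call. = FALSE)
  }
  structure(list(systems_per_class = as.integer(systems_per_class),
                 n_frames = as.integer(n_frames),
                 n_background_pairs = as.integer(n_background_pairs),
                 n_common_pairs = as.integer(n_common_pairs),
                 n_specific_pairs = as.integer(n_specific_pairs),
                 p_common = p_common, p_specific_own = p_specific_own,
                 p_specific_other = p_specific_other,
                 p_background = p_background, seed = as.integer(seed)),
            class = "st_planted_spec")
}

# deterministic generic-style pair keys: receptor side "TMxYY"-style GPCRdb
# strings, Galpha side CGN helix-5 style strings
synthetic_pair_keys <- function(n) {
  helix <- rep(1:7, length.out = n)
  pos <- 40L + ((seq_len(n) - 1L) %/% 7L)
  gpcr <- sprintf("%dx%02d", helix, pos)
  gprot <- sprintf("G.H5.%02d", 1L + (seq_len(n) - 1L) %% 26L)
  pair_key(gpcr, gprot)
}

#' Generate a planted synthetic fingerprint dataset
#'
#' Draws every fingerprint entry independently Bernoulli with the pair's
#' class-dependent occupancy and returns the dataset together with the
#' ground-truth pair roles and system classes.
#'
#' @param spec an \code{st_planted_spec}
#' @return list(fingerprints = \code{st_fingerprints}, system_class = named
#'   vector, truth = data.frame(pair, role, class))
#' @export
generate_fingerprints <- function(spec = planted_spec()) {
  stopifnot(inherits(spec, "st_planted_spec"))
  set.seed(spec$seed)
  n_pairs <- spec$n_background_pairs + spec$n_common_pairs +
    3L * spec$n_specific_pairs
  keys <- synthetic_pair_keys(n_pairs)
  role <- c(rep("common", spec$n_common_pairs),
            rep("specific", 3L * spec$n_specific_pairs),
            rep("background", spec$n_background_pairs))
  role_class <- c(rep(NA_character_, spec$n_common_pairs),
                  rep(GP_CLASSES, each = spec$n_specific_pairs),
                  rep(NA_character_, spec$n_background_pairs))
  truth <- data.frame(pair = keys, role = role, class = role_class,
                      stringsAsFactors = FALSE)

  occupancy <- function(cls) {
    p <- rep(spec$p_background, n_pairs)
    p[role == "common"] <- spec$p_common
    p[role == "specific"] <- ifelse(role_class[role == "specific"] == cls,
                                    spec$p_specific_own,
                                    spec$p_specific_other)
    p
  }
  blocks <- list(); system_class <- character(0)
  for (cls in GP_CLASSES) {
    p <- occupancy(cls)
    for (s in seq_len(spec$systems_per_class)) {
      sid <- paste0(cls, "_sys", s)
      m <- matrix(stats::rbinom(spec$n_frames * n_pairs, 1L,
                                rep(p, each = spec$n_frames)),
                  nrow = spec$n_frames, dimnames = list(NULL, keys))
      blocks[[sid]] <- m
      system_class[sid] <- cls
    }
  }
  list(fingerprints = fingerprint_set(blocks, system_class),
       system_class = system_class, truth = truth)
}

# ---- toy 3-D complexes ------------------------------------------------------

# idealized residue templates: heavy atoms (plus optional polar hydrogens),
# local coordinates in Angstrom with the functional "anchor" atom at the
# origin. Geometry is idealized (literature-ish bond lengths, planar rings),
# not rotamer-library derived.
residue_template <- function(resname) {
  hexagon <- function(r = 1.39) {
    ang <- seq(0, 300, by = 60) * pi / 180
    cbind(r * cos(ang), r * sin(ang), 0)
  }
  tmpl <- switch(resname,
    ALA = list(anchor = "CB", atoms = rbind(
      CB = c(0, 0, 0), CA = c(1.53, 0, 0), N = c(2.1, 1.3, 0.2),
      C = c(2.1, -1.0, -0.9), O = c(3.3, -1.0, -1.2))),
    GLY = list(anchor = "CA", atoms = rbind(
      CA = c(0, 0, 0), N = c(1.2, 0.8, 0), C = c(-0.9, -1.2, 0),
      O = c(-2.1, -1.0, 0))),
    ASP = list(anchor = "OD1", atoms = rbind(
      OD1 = c(0, 0, 0), CG = c(0, 0, -1.25), OD2 = c(1.08, 0, -1.88),
      CB = c(-1.32, 0, -2.02), CA = c(-1.32, 0, -3.55),
      N = c(-2.2, 1.2, -3.95), C = c(-2.2, -1.2, -3.95),
      O = c(-3.35, -1.2, -4.45))),
    GLU = list(anchor = "OE1", atoms = rbind(
      OE1 = c(0, 0, 0), CD = c(0, 0, -1.25), OE2 = c(1.08, 0, -1.88),
      CG = c(-1.32, 0, -2.02), CB = c(-1.32, 0, -3.55),
      CA = c(-2.6, 0, -4.3), N = c(-3.5, 1.2, -4.6),
      C = c(-3.5, -1.2, -4.6), O = c(-4.65, -1.2, -5.1))),
    LYS = list(anchor = "NZ", atoms = rbind(
      NZ = c(0, 0, 0), CE = c(0, 0, -1.49), CD = c(-1.27, 0, -2.32),
      CG = c(-1.27, 0, -3.85), CB = c(-2.54, 0, -4.68),
      CA = c(-2.54, 0, -6.21), N = c(-3.45, 1.2, -6.6),
      C = c(-3.45, -1.2, -6.6), O = c(-4.6, -1.2, -7.1)),
      hydrogens = rbind(HZ1 = c(0.9, 0.35, 0.3), HZ2 = c(-0.9, 0.35, 0.3),
                        HZ3 = c(0, -0.95, 0.3))),
    ARG = list(anchor = "NH1", atoms = rbind(
      NH1 = c(0, 0, 0), CZ = c(0, 0, -1.33), NH2 = c(1.15, 0, -2.0),
      NE = c(-1.15, 0, -2.0), CD = c(-1.2, 0, -3.5),
      CG = c(-2.5, 0, -4.3), CB = c(-2.5, 0, -5.83),
      CA = c(-3.8, 0, -6.6), N = c(-4.7, 1.2, -6.9),
      C = c(-4.7, -1.2, -6.9), O = c(-5.85, -1.2, -7.4))),
    SER = list(anchor = "OG", atoms = rbind(
      OG = c(0, 0, 0), CB = c(0, 0, -1.42), CA = c(-1.3, 0, -2.2),
      N = c(-2.2, 1.2, -2.5), C = c(-2.2, -1.2, -2.5),
      O = c(-3.35, -1.2, -3.0)),
      hydrogens = rbind(HG = c(0, 0.77, 0.58))),
    PHE = {
      ring <- hexagon()
      rownames(ring) <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
      list(anchor = "__centroid__", atoms = rbind(
        ring, CB = c(2.9, 0, 0), CA = c(3.6, 1.35, 0),
        N = c(4.6, 1.4, 1.1), C = c(4.3, 1.5, -1.35),
        O = c(5.5, 1.5, -1.6)))
    },
    TYR = {
      ring <- hexagon()
      rownames(ring) <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
      list(anchor = "__centroid__", atoms = rbind(
        ring, OH = c(-2.76, 0, 0), CB = c(2.9, 0, 0),
        CA = c(3.6, 1.35, 0), N = c(4.6, 1.4, 1.1),
        C = c(4.3, 1.5, -1.35), O = c(5.5, 1.5, -1.6)))
    },
    HIS = {
      ang <- (90 + 72 * 0:4) * pi / 180
      ring <- cbind(1.17 * cos(ang), 1.17 * sin(ang), 0)
      rownames(ring) <- c("CG", "ND1", "CE1", "NE2", "CD2")
      list(anchor = "__centroid__", atoms = rbind(
        ring, CB = c(0.75, 2.3, 0), CA = c(1.6, 3.2, 0.7),
        N = c(2.6, 3.9, 0.1), C = c(2.2, 2.8, 2.0),
        O = c(3.4, 2.8, 2.3)))
    },
    LEU = list(anchor = "CD1", atoms = rbind(
      CD1 = c(0, 0, 0), CG = c(0, 0, -1.53), CD2 = c(1.3, 0, -2.3),
      CB = c(-1.3, 0, -2.3), CA = c(-1.3, 0, -3.83),
      N = c(-2.2, 1.2, -4.2), C = c(-2.2, -1.2, -4.2),
      O = c(-3.35, -1.2, -4.7))),
    stop("no toy template for residue ", resname, call. = FALSE))
  tmpl
}

#' Axis-aligned rotation matrix
#' @param axis "x", "y" or "z"
#' @param degrees rotation angle, degrees
#' @return 3x3 rotation matrix (apply to row-vector coordinates as
#'   \code{xyz \%*\% t(R)})
#' @export
rotation_matrix <- function(axis = c("x", "y", "z"), degrees) {
  axis <- match.arg(axis)
  t <- degrees * pi / 180
  c_ <- cos(t); s <- sin(t)
  switch(axis,
         x = matrix(c(1, 0, 0, 0, c_, -s, 0, s, c_), 3, byrow = TRUE),
         y = matrix(c(c_, 0, s, 0, 1, 0, -s, 0, c_), 3, byrow = TRUE),
         z = matrix(c(c_, -s, 0, s, c_, 0, 0, 0, 1), 3, byrow = TRUE))
}

#' A residue placement for a toy complex
#'
#' @param resname residue type with a toy template (ALA, GLY, ASP, GLU, LYS,
#'   ARG, SER, PHE, TYR, HIS, LEU)
#' @param chain chain identifier
#' @param resnum residue number
#' @param anchor 3-vector: position of the template's functional anchor atom
#'   (charged atom, hydroxyl oxygen, or ring centroid)
#' @param rotation optional 3x3 rotation applied about the anchor before
#'   translation (see \code{\link{rotation_matrix}})
#' @return placement list
#' @export
toy_residue <- function(resname, chain, resnum, anchor = c(0, 0, 0),
                        rotation = NULL) {
  list(resname = resname, chain = chain, resnum = as.integer(resnum),
       anchor = as.numeric(anchor), rotation = rotation)
}

#' Specification of a toy two-chain complex trajectory
#'
#' @param placements list of \code{\link{toy_residue}}
#' @param n_frames frames to generate
#' @param jitter standard deviation (Angstrom) of i.i.d. Gaussian coordinate
#'   noise applied per frame (frame 1 of a jittered trajectory is also
#'   jittered)
#' @param seed RNG seed
#' @param include_hydrogens include template polar hydrogens
#' @return list of class \code{st_toy_spec}
#' @export
toy_complex_spec <- function(placements, n_frames = 1L, jitter = 0,
                             seed = 1L, include_hydrogens = FALSE) {
  stopifnot(length(placements) >= 1L, jitter >= 0, n_frames >= 1L)
  structure(list(placements = placements, n_frames = as.integer(n_frames),
                 jitter = jitter, seed = as.integer(seed),
                 include_hydrogens = include_hydrogens),
            class = "st_toy_spec")
}

#' Generate a toy complex topology and trajectory
#'
#' Builds the reference structure from idealized residue templates, applies
#' per-frame Gaussian jitter, and (optionally) writes the frames as a
#' multi-model PDB. Atom pairs closer than 1 Angstrom in the reference
#' structure abort generation.
#'
#' @param spec an \code{st_toy_spec}
#' @param path optional output path for a multi-model PDB of the frames
#' @param chain_gpcr,chain_gprot chains assigned to the receptor / Galpha
#'   selections
#' @param system_id trajectory label
#' @return list(topology = \code{st_topology}, trajectory =
#'   \code{st_trajectory}, path)
#' @export
generate_toy_complex <- function(spec, path = NULL, chain_gpcr = "R",
                                 chain_gprot = "A", system_id = "toy") {
  stopifnot(inherits(spec, "st_toy_spec"))
  rows <- list()
  for (pl in spec$placements) {
    tmpl <- residue_template(pl$resname)
    atoms <- tmpl$atoms
    if (spec$include_hydrogens && !is.null(tmpl$hydrogens)) {
      atoms <- rbind(atoms, tmpl$hydrogens)
    }
    if (identical(tmpl$anchor, "__centroid__")) {
      ring <- AROMATIC_RINGS[[pl$resname]]
      cen <- colMeans(atoms[ring, , drop = FALSE])
      atoms <- sweep(atoms, 2L, cen)
    } else {
      atoms <- sweep(atoms, 2L, atoms[tmpl$anchor, ])
    }
    if (!is.null(pl$rotation)) atoms <- atoms %*% t(pl$rotation)
    atoms <- sweep(atoms, 2L, -pl$anchor)
    nm <- rownames(atoms)
    rows[[length(rows) + 1L]] <- data.frame(
      atom_name = nm,
      element = ifelse(grepl("^H", nm), "H",
                       substr(sub("^[0-9]+", "", nm), 1L, 1L)),
      chain = pl$chain, resnum = pl$resnum, resname = pl$resname,
      x = atoms[, 1], y = atoms[, 2], z = atoms[, 3],
      stringsAsFactors = FALSE)
  }
  at <- do.call(rbind, rows)
  rownames(at) <- NULL
  at$residue <- residue_key(at$chain, at$resnum)
  at$is_sidechain <- !(at$atom_name %in% BACKBONE_ATOMS)
  at <- at[, c("atom_name", "element", "chain", "resnum", "resname",
               "residue", "is_sidechain", "x", "y", "z")]
  ref <- as.matrix(at[, c("x", "y", "z")])
  if (min(stats::dist(ref)) < 1) {
    stop("overlapping atoms (< 1 Angstrom) in toy complex", call. = FALSE)
  }
  selections <- list(gpcr = unique(at$residue[at$chain %in% chain_gpcr]),
                     galpha = unique(at$residue[at$chain %in% chain_gprot]))
  topology <- new_topology(at, selections)

  set.seed(spec$seed)
  coords <- array(NA_real_, dim = c(nrow(at), 3L, spec$n_frames))
  for (f in seq_len(spec$n_frames)) {
    noise <- if (spec$jitter > 0)
      matrix(stats::rnorm(length(ref), sd = spec$jitter), ncol = 3L)
    else 0
    coords[, , f] <- ref + noise
  }
  trajectory <- structure(
    list(topology = topology, coords = coords,
         frame_ids = seq_len(spec$n_frames) - 1L, system_id = system_id),
    class = "st_trajectory")
  if (!is.null(path)) write_multimodel_pdb(topology, coords, path)
  list(topology = topology, trajectory = trajectory, path = path)
}

#' Default numbering map for a toy complex
#'
#' Assigns deterministic GPCRdb-style generics (receptor chain) and CGN
#' helix-5 generics (Galpha chain) to every residue of a toy topology, with
#' simple SSE labels (TM3 / H5).
#'
#' @param topology an \code{st_topology}
#' @return an \code{st_numbering_map}
#' @export
toy_numbering_map <- function(topology) {
  res <- unique(topology$atoms[, c("chain", "resnum", "residue")])
  gpcr <- res$residue %in% topology$selections$gpcr
  df <- data.frame(chain = res$chain, resnum = res$resnum,
                   generic = NA_character_, sse = NA_character_,
                   side = ifelse(gpcr, "GPCR", "GPROT"),
                   stringsAsFactors = FALSE)
  df$generic[gpcr] <- sprintf("3x%02d", 44L + seq_len(sum(gpcr)))
  df$sse[gpcr] <- "TM3"
  df$generic[!gpcr] <- sprintf("G.H5.%02d", seq_len(sum(!gpcr)))
  df$sse[!gpcr] <- "H5"
  as_numbering_map(df[, c("chain", "resnum", "generic", "sse", "side")])
}
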