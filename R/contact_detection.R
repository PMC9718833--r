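# Geometric detection of sidechain-sidechain intermolecular contacts.
# Five criteria with strict ("<") cutoffs: salt bridge (SB), hydrogen bond
# (HB), van der Waals (VDW), pi-stacking (PS), cation-pi (PC).

# Atom-level chemistry tables. These are the explicit donor/acceptor/ion/ring
# definitions used by the predicates; they follow common contact-analysis
# practice for standard amino-acid sidechains.
ANION_ATOMS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
CATION_ATOMS <- list(LYS = "NZ", ARG = c("NH1", "NH2", "NE"))
CATION_ATOMS_HIS <- list(HIS = c("ND1", "NE2"))
HB_DONORS <- list(
  SER = "OG", THR = "OG1", TYR = "OH", CYS = "SG", TRP = "NE1",
  ASN = "ND2", GLN = "NE2", LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
  HIS = c("ND1", "NE2")
)
HB_ACCEPTORS <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2"),
  MET = "SD", CYS = "SG"
)
AROMATIC_RINGS <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2")
)
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)
CONTACT_TYPES <- c("SB", "HB", "VDW", "PS", "PC")

#' Geometric contact criteria
#'
#' Thresholds of the five contact criteria. All distance comparisons are
#' strict (\code{<}); angles are in degrees and plane-normal angles are
#' folded into [0, 90] (normals are unsigned axes). The van der Waals test
#' uses \code{distance < r_i + r_j + vdw_slack} with an element radius table.
#'
#' @param salt_bridge_cutoff anion-cation distance cutoff, Angstrom
#' @param hbond_da_cutoff donor-acceptor heavy-atom distance cutoff, Angstrom
#' @param hbond_angle_max max angle between D-H and D-A vectors, degrees
#' @param vdw_slack slack added to the radius sum, Angstrom
#' @param vdw_radii named element -> van der Waals radius table, Angstrom
#' @param pistack_centroid_cutoff ring centroid distance cutoff, Angstrom
#' @param pistack_angle_max max angle between ring normals, degrees
#' @param catpi_cutoff cation to ring-centroid distance cutoff, Angstrom
#' @param catpi_angle_max max angle between ring normal and centroid-cation
#'   vector, degrees
#' @param his_cation treat HIS ND1/NE2 as cations (protonated His)
#' @return list of class \code{st_criteria}
#' @export
contact_criteria <- function(salt_bridge_cutoff = 4.0,
                             hbond_da_cutoff = 3.5,
                             hbond_angle_max = 70,
                             vdw_slack = 0.5,
                             vdw_radii = VDW_RADII,
                             pistack_centroid_cutoff = 7.0,
                             pistack_angle_max = 30,
                             catpi_cutoff = 6.0,
                             catpi_angle_max = 60,
                             his_cation = FALSE) {
  cuts <- c(salt_bridge_cutoff, hbond_da_cutoff, vdw_slack,
            pistack_centroid_cutoff, catpi_cutoff)
  if (any(cuts <= 0)) stop("distance cutoffs must be > 0", call. = FALSE)
  angs <- c(hbond_angle_max, pistack_angle_max, catpi_angle_max)
  if (any(angs <= 0 | angs > 90)) {
    stop("angle maxima must lie in (0, 90]", call. = FALSE)
  }
  structure(list(salt_bridge_cutoff = salt_bridge_cutoff,
                 hbond_da_cutoff = hbond_da_cutoff,
                 hbond_angle_max = hbond_angle_max,
                 vdw_slack = vdw_slack, vdw_radii = vdw_radii,
                 pistack_centroid_cutoff = pistack_centroid_cutoff,
                 pistack_angle_max = pistack_angle_max,
                 catpi_cutoff = catpi_cutoff,
                 catpi_angle_max = catpi_angle_max,
                 his_cation = his_cation),
            class = "st_criteria")
}

cation_table <- function(criteria) {
  if (isTRUE(criteria$his_cation)) c(CATION_ATOMS, CATION_ATOMS_HIS)
  else CATION_ATOMS
}

vnorm <- function(v) sqrt(sum(v * v))

# angle in degrees between two vectors; fold = TRUE treats them as unsigned
# axes (angle folded into [0, 90])
vec_angle <- function(u, v, fold = FALSE) {
  cosang <- sum(u * v) / (vnorm(u) * vnorm(v))
  cosang <- min(1, max(-1, cosang))
  ang <- acos(cosang) * 180 / pi
  if (fold && ang > 90) ang <- 180 - ang
  ang
}

ring_centroid <- function(ring_xyz) colMeans(ring_xyz)

# best-fit plane normal of the ring atoms (least-squares via SVD)
ring_normal <- function(ring_xyz) {
  centered <- sweep(ring_xyz, 2, colMeans(ring_xyz))
  svd(centered)$v[, 3]
}

#' Salt-bridge test
#'
#' TRUE iff the anion-cation distance is strictly below the cutoff
#' (default 4.0 Angstrom).
#'
#' @param anion_xyz,cation_xyz 3-vectors, Angstrom
#' @param criteria an \code{st_criteria}
#' @return logical
#' @export
is_salt_bridge <- function(anion_xyz, cation_xyz,
                           criteria = contact_criteria()) {
  vnorm(anion_xyz - cation_xyz) < criteria$salt_bridge_cutoff
}

#' Hydrogen-bond test
#'
#' TRUE iff the donor-acceptor heavy-atom distance is strictly below the
#' cutoff (default 3.5 Angstrom) and, when a donor hydrogen is supplied, the
#' angle between the donor-to-hydrogen and donor-to-acceptor vectors is
#' strictly below the angle maximum (default 70 degrees). With
#' \code{donor_h_xyz = NULL} the distance criterion alone applies
#' (heavy-atom mode).
#'
#' @param donor_xyz,acceptor_xyz donor/acceptor heavy-atom 3-vectors
#' @param donor_h_xyz donor hydrogen 3-vector or NULL
#' @param criteria an \code{st_criteria}
#' @return logical
#' @export
is_hbond <- function(donor_xyz, donor_h_xyz = NULL, acceptor_xyz,
                     criteria = contact_criteria()) {
  if (vnorm(donor_xyz - acceptor_xyz) >= criteria$hbond_da_cutoff) {
    return(FALSE)
  }
  if (is.null(donor_h_xyz)) return(TRUE)
  vec_angle(donor_h_xyz - donor_xyz, acceptor_xyz - donor_xyz) <
    criteria$hbond_angle_max
}

#' Van der Waals contact test
#'
#' TRUE iff the interatomic distance is strictly below the sum of the two
#' element van der Waals radii plus the slack (default 0.5 Angstrom).
#'
#' @param xyz_i,xyz_j heavy-atom 3-vectors
#' @param element_i,element_j element symbols, looked up in the radius table
#' @param criteria an \code{st_criteria}
#' @return logical
#' @export
is_vdw <- function(xyz_i, element_i, xyz_j, element_j,
                   criteria = contact_criteria()) {
  ri <- criteria$vdw_radii[toupper(element_i)]
  rj <- criteria$vdw_radii[toupper(element_j)]
  if (is.na(ri) || is.na(rj)) {
    stop("no van der Waals radius for element ",
         paste(unique(c(element_i, element_j)), collapse = "/"),
         call. = FALSE)
  }
  vnorm(xyz_i - xyz_j) < unname(ri + rj + criteria$vdw_slack)
}

#' Pi-stacking test
#'
#' TRUE iff ring centroids are strictly closer than the cutoff (default 7.0
#' Angstrom) and the angle between the two ring-plane normals (folded into
#' [0, 90]) is strictly below the maximum (default 30 degrees).
#'
#' @param ring_i_xyz,ring_j_xyz matrices (>= 5 rows x 3) of ring-atom
#'   coordinates
#' @param criteria an \code{st_criteria}
#' @return logical
#' @export
is_pistack <- function(ring_i_xyz, ring_j_xyz,
                       criteria = contact_criteria()) {
  if (nrow(ring_i_xyz) < 5L || nrow(ring_j_xyz) < 5L) return(FALSE)
  ci <- ring_centroid(ring_i_xyz); cj <- ring_centroid(ring_j_xyz)
  if (vnorm(ci - cj) >= criteria$pistack_centroid_cutoff) return(FALSE)
  vec_angle(ring_normal(ring_i_xyz), ring_normal(ring_j_xyz), fold = TRUE) <
    criteria$pistack_angle_max
}

#' Cation-pi test
#'
#' TRUE iff the cation is strictly closer than the cutoff (default 6.0
#' Angstrom) to the ring centroid and the angle between the ring normal and
#' the centroid-to-cation vector (folded into [0, 90]) is strictly below the
#' maximum (default 60 degrees).
#'
#' @param cation_xyz cation 3-vector
#' @param ring_xyz matrix (>= 5 rows x 3) of ring-atom coordinates
#' @param criteria an \code{st_criteria}
#' @return logical
#' @export
is_cationpi <- function(cation_xyz, ring_xyz,
                        criteria = contact_criteria()) {
  if (nrow(ring_xyz) < 5L) return(FALSE)
  cen <- ring_centroid(ring_xyz)
  if (vnorm(cation_xyz - cen) >= criteria$catpi_cutoff) return(FALSE)
  vec_angle(ring_normal(ring_xyz), cation_xyz - cen, fold = TRUE) <
    criteria$catpi_angle_max
}

# ---- residue-level machinery -----------------------------------------------

# index sidechain atoms of one selection into per-residue structures
index_selection <- function(topology, residues) {
  at <- topology$atoms
  keep <- at$residue %in% residues & at$is_sidechain
  idx <- which(keep)
  split(idx, at$residue[idx])
}

named_atoms <- function(at, idx, names_wanted) {
  idx[at$atom_name[idx] %in% names_wanted]
}

# donor hydrogen lookup: hydrogens within 1.25 A of the donor heavy atom in
# the same residue
donor_hydrogens <- function(at, xyz, res_idx, donor_i) {
  h <- res_idx[at$element[res_idx] %in% c("H", "D")]
  if (length(h) == 0L) return(integer(0))
  d <- sqrt(colSums((t(xyz[h, , drop = FALSE]) - xyz[donor_i, ])^2))
  h[d < 1.25]
}

# per-residue feature cache (anion/cation/donor/acceptor/ring atom indices)
residue_features <- function(topology, res_groups, criteria) {
  at <- topology$atoms
  cations <- cation_table(criteria)
  lapply(res_groups, function(idx) {
    rn <- at$resname[idx[1]]
    heavy <- idx[!(at$element[idx] %in% c("H", "D"))]
    ring_names <- AROMATIC_RINGS[[rn]]
    ring <- if (is.null(ring_names)) integer(0) else
      named_atoms(at, idx, ring_names)
    if (length(ring) < 5L) ring <- integer(0)
    list(resname = rn, all = idx, heavy = heavy,
         anion = named_atoms(at, idx, ANION_ATOMS[[rn]] %||% character(0)),
         cation = named_atoms(at, idx, cations[[rn]] %||% character(0)),
         donor = named_atoms(at, idx, HB_DONORS[[rn]] %||% character(0)),
         acceptor = named_atoms(at, idx, HB_ACCEPTORS[[rn]] %||% character(0)),
         ring = ring)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate all five criteria for one residue pair in one frame; returns a
# character vector of contact types satisfied
pair_contact_types <- function(at, xyz, fi, fj, criteria, hydrogens) {
  types <- character(0)
  coords <- function(i) xyz[i, , drop = TRUE]

  # SB: anion of one residue vs cation of the other, both directions
  sb_hit <- function(an, ca) {
    for (a in an) for (c in ca) {
      if (is_salt_bridge(coords(a), coords(c), criteria)) return(TRUE)
    }
    FALSE
  }
  if ((length(fi$anion) && length(fj$cation) &&
       sb_hit(fi$anion, fj$cation)) ||
      (length(fj$anion) && length(fi$cation) &&
       sb_hit(fj$anion, fi$cation))) {
    types <- c(types, "SB")
  }

  # HB: donor on either side
  hb_hit <- function(don_f, acc_f) {
    for (d in don_f$donor) {
      hs <- if (hydrogens) donor_hydrogens(at, xyz, don_f$all, d) else
        integer(0)
      for (a in acc_f$acceptor) {
        if (length(hs) == 0L) {
          if (is_hbond(coords(d), NULL, coords(a), criteria)) return(TRUE)
        } else {
          for (h in hs) {
            if (is_hbond(coords(d), coords(h), coords(a), criteria)) {
              return(TRUE)
            }
          }
        }
      }
    }
    FALSE
  }
  if ((length(fi$donor) && length(fj$acceptor) && hb_hit(fi, fj)) ||
      (length(fj$donor) && length(fi$acceptor) && hb_hit(fj, fi))) {
    types <- c(types, "HB")
  }

  # VDW: any heavy-atom pair
  vdw_hit <- FALSE
  for (i in fi$heavy) {
    for (j in fj$heavy) {
      if (is_vdw(coords(i), at$element[i], coords(j), at$element[j],
                 criteria)) { vdw_hit <- TRUE; break }
    }
    if (vdw_hit) break
  }
  if (vdw_hit) types <- c(types, "VDW")

  # PS: aromatic ring on both sides
  if (length(fi$ring) && length(fj$ring) &&
      is_pistack(xyz[fi$ring, , drop = FALSE],
                 xyz[fj$ring, , drop = FALSE], criteria)) {
    types <- c(types, "PS")
  }

  # PC: cation vs ring, both directions
  pc_hit <- function(cat_f, ring_f) {
    for (c in cat_f$cation) {
      if (is_cationpi(coords(c), xyz[ring_f$ring, , drop = FALSE],
                      criteria)) return(TRUE)
    }
    FALSE
  }
  if ((length(fi$cation) && length(fj$ring) && pc_hit(fi, fj)) ||
      (length(fj$cation) && length(fi$ring) && pc_hit(fj, fi))) {
    types <- c(types, "PC")
  }

  types
}

#' Detect per-frame intermolecular sidechain contacts
#'
#' Evaluates the five geometric criteria over all receptor-Galpha sidechain
#' residue pairs in every frame. A 12 Angstrom sidechain-centroid prefilter
#' skips residue pairs that cannot satisfy any criterion (lossless given the
#' default cutoffs and ring extents; disable with \code{prefilter = Inf}).
#' Residues without a generic-number entry are excluded and tallied in the
#' result's metadata. Hydrogen-aware hydrogen bonding is auto-selected when
#' hydrogens are present in the topology.
#'
#' @param trajectory an \code{st_trajectory}
#' @param numbering_map an \code{st_numbering_map}, or NULL to key events by
#'   plain residue keys
#' @param criteria an \code{st_criteria}
#' @param prefilter centroid-distance prefilter in Angstrom (Inf disables)
#' @return an \code{st_timeline}: data.frame (frame_id, gpcr_residue,
#'   gprot_residue, gpcr_generic, gprot_generic, contact_type) with
#'   attributes system_id, n_frames, hbond_mode, n_unmapped
#' @export
detect_contacts <- function(trajectory, numbering_map = NULL,
                            criteria = contact_criteria(),
                            prefilter = 12) {
  topology <- trajectory$topology
  at <- topology$atoms
  g_res <- index_selection(topology, topology$selections$gpcr)
  a_res <- index_selection(topology, topology$selections$galpha)
  if (length(g_res) == 0L || length(a_res) == 0L) {
    stop("a selection has no sidechain atoms", call. = FALSE)
  }
  n_unmapped <- 0L
  generic_of <- function(res_names) {
    if (is.null(numbering_map)) return(res_names)
    map_lookup(numbering_map, res_names)$generic
  }
  g_gen <- generic_of(names(g_res)); a_gen <- generic_of(names(a_res))
  keep_g <- !is.na(g_gen); keep_a <- !is.na(a_gen)
  n_unmapped <- sum(!keep_g) + sum(!keep_a)
  g_res <- g_res[keep_g]; g_gen <- g_gen[keep_g]
  a_res <- a_res[keep_a]; a_gen <- a_gen[keep_a]
  if (length(g_res) == 0L || length(a_res) == 0L) {
    stop("no mapped residues left in a selection", call. = FALSE)
  }

  hydrogens <- any(at$element %in% c("H", "D"))
  gf <- residue_features(topology, g_res, criteria)
  af <- residue_features(topology, a_res, criteria)

  rows <- list()
  for (f in seq_len(n_frames(trajectory))) {
    xyz <- frame_coords(trajectory, f)
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3L)
    gc <- t(vapply(gf, function(r) colMeans(xyz[r$all, , drop = FALSE]),
                   numeric(3)))
    ac <- t(vapply(af, function(r) colMeans(xyz[r$all, , drop = FALSE]),
                   numeric(3)))
    for (i in seq_along(gf)) {
      d2 <- colSums((t(ac) - gc[i, ])^2)
      near <- which(d2 < prefilter^2)
      for (j in near) {
        types <- pair_contact_types(at, xyz, gf[[i]], af[[j]], criteria,
                                    hydrogens)
        if (length(types)) {
          rows[[length(rows) + 1L]] <- data.frame(
            frame_id = trajectory$frame_ids[f],
            gpcr_residue = names(g_res)[i],
            gprot_residue = names(a_res)[j],
            gpcr_generic = g_gen[i], gprot_generic = a_gen[j],
            contact_type = types, stringsAsFactors = FALSE)
        }
      }
    }
  }
  events <- if (length(rows)) do.call(rbind, rows) else
    data.frame(frame_id = integer(0), gpcr_residue = character(0),
               gprot_residue = character(0), gpcr_generic = character(0),
               gprot_generic = character(0), contact_type = character(0),
               stringsAsFactors = FALSE)
  events <- unique(events)
  new_timeline(events, system_id = trajectory$system_id,
               n_frames = n_frames(trajectory),
               hbond_mode = if (hydrogens) "hydrogen" else "heavy-atom",
               n_unmapped = n_unmapped)
}

new_timeline <- function(events, system_id, n_frames,
                         hbond_mode = "heavy-atom", n_unmapped = 0L) {
  stopifnot(all(events$contact_type %in% CONTACT_TYPES))
  if (nrow(events) && any(events$frame_id >= n_frames)) {
    stop("event frame_id beyond n_frames", call. = FALSE)
  }
  structure(events, class = c("st_timeline", "data.frame"),
            system_id = system_id, n_frames = n_frames,
            hbond_mode = hbond_mode, n_unmapped = n_unmapped)
}

#' Write a contact timeline to TSV
#' @param timeline an \code{st_timeline}
#' @param path output TSV path
#' @export
write_timeline <- function(timeline, path) {
  utils::write.table(as.data.frame(timeline), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a contact timeline from TSV
#' @param path TSV path
#' @param system_id system label
#' @param n_frames total frame count of the source ensemble
#' @return an \code{st_timeline}
#' @export
read_timeline <- function(path, system_id, n_frames) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  new_timeline(df, system_id = system_id, n_frames = n_frames)
}
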