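# Independent brute-force contact oracle: plain all-pairs loops with its own
# vector math and chemistry tables, no prefilter, no shared code with the
# package's detector beyond the criteria thresholds.

oracle_tables <- list(
  anion = list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2")),
  cation = list(LYS = "NZ", ARG = c("NH1", "NH2", "NE")),
  donor = list(SER = "OG", THR = "OG1", TYR = "OH", CYS = "SG",
               TRP = "NE1", ASN = "ND2", GLN = "NE2", LYS = "NZ",
               ARG = c("NE", "NH1", "NH2"), HIS = c("ND1", "NE2")),
  acceptor = list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
                  ASN = "OD1", GLN = "OE1", SER = "OG", THR = "OG1",
                  TYR = "OH", HIS = c("ND1", "NE2"), MET = "SD",
                  CYS = "SG"),
  ring = list(PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
              TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
              TRP = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
              HIS = c("CG", "ND1", "CD2", "CE1", "NE2")),
  radii = c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)
)

oracle_dist <- function(a, b) sqrt(sum((a - b)^2))

oracle_angle <- function(u, v, fold = FALSE) {
  ca <- sum(u * v) / sqrt(sum(u * u) * sum(v * v))
  ang <- acos(max(-1, min(1, ca))) * 180 / pi
  if (fold && ang > 90) 180 - ang else ang
}

# best-fit plane normal (the ring-normal definition of the contact
# contract): eigenvector of the smallest eigenvalue of the coordinate
# covariance — an independent route to the same least-squares plane
oracle_plane_normal <- function(m) {
  c0 <- sweep(m, 2, colMeans(m))
  ev <- eigen(crossprod(c0), symmetric = TRUE)
  n <- ev$vectors[, 3]
  n / sqrt(sum(n * n))
}

# full O(n^2) evaluation over one frame; returns data.frame
# (gpcr_residue, gprot_residue, contact_type)
oracle_frame_contacts <- function(atoms, xyz, gpcr_res, gprot_res,
                                  criteria = contact_criteria()) {
  tb <- oracle_tables
  backbone <- c("N", "CA", "C", "O", "OXT",
                "H", "H1", "H2", "H3", "HA", "HA2", "HA3", "HN")
  sc <- !(atoms$atom_name %in% backbone)
  hydrogens_present <- any(atoms$element == "H")
  out <- list()
  emit <- function(g, a, type) {
    out[[length(out) + 1]] <<- data.frame(
      gpcr_residue = g, gprot_residue = a, contact_type = type,
      stringsAsFactors = FALSE)
  }
  res_atoms <- function(res) which(atoms$residue == res & sc)
  pick <- function(idx, names) idx[atoms$atom_name[idx] %in% names]

  for (g in gpcr_res) {
    gi <- res_atoms(g)
    if (!length(gi)) next
    grn <- atoms$resname[gi[1]]
    for (a in gprot_res) {
      ai <- res_atoms(a)
      if (!length(ai)) next
      arn <- atoms$resname[ai[1]]

      # SB
      hit <- FALSE
      for (dir in 1:2) {
        an <- if (dir == 1) pick(gi, tb$anion[[grn]]) else
          pick(ai, tb$anion[[arn]])
        ca <- if (dir == 1) pick(ai, tb$cation[[arn]]) else
          pick(gi, tb$cation[[grn]])
        for (x in an) for (y in ca) {
          if (oracle_dist(xyz[x, ], xyz[y, ]) <
              criteria$salt_bridge_cutoff) hit <- TRUE
        }
      }
      if (hit) emit(g, a, "SB")

      # HB
      hit <- FALSE
      for (dir in 1:2) {
        don_res <- if (dir == 1) gi else ai
        acc_res <- if (dir == 1) ai else gi
        dn <- pick(don_res,
                   tb$donor[[atoms$resname[don_res[1]]]])
        ac <- pick(acc_res,
                   tb$acceptor[[atoms$resname[acc_res[1]]]])
        for (d in dn) for (x in ac) {
          if (oracle_dist(xyz[d, ], xyz[x, ]) >=
              criteria$hbond_da_cutoff) next
          if (!hydrogens_present) { hit <- TRUE; next }
          hs <- don_res[atoms$element[don_res] == "H"]
          hs <- hs[vapply(hs, function(h)
            oracle_dist(xyz[h, ], xyz[d, ]) < 1.25, TRUE)]
          if (!length(hs)) next
          for (h in hs) {
            if (oracle_angle(xyz[h, ] - xyz[d, ], xyz[x, ] - xyz[d, ]) <
                criteria$hbond_angle_max) hit <- TRUE
          }
        }
      }
      if (hit) emit(g, a, "HB")

      # VDW (heavy atoms only)
      hit <- FALSE
      for (x in gi[atoms$element[gi] != "H"]) {
        for (y in ai[atoms$element[ai] != "H"]) {
          thr <- tb$radii[atoms$element[x]] + tb$radii[atoms$element[y]] +
            criteria$vdw_slack
          if (oracle_dist(xyz[x, ], xyz[y, ]) < thr) hit <- TRUE
        }
      }
      if (hit) emit(g, a, "VDW")

      # PS
      ri <- pick(gi, tb$ring[[grn]]); rj <- pick(ai, tb$ring[[arn]])
      if (length(ri) >= 5 && length(rj) >= 5) {
        mi <- xyz[ri, , drop = FALSE]; mj <- xyz[rj, , drop = FALSE]
        if (oracle_dist(colMeans(mi), colMeans(mj)) <
            criteria$pistack_centroid_cutoff &&
            oracle_angle(oracle_plane_normal(mi), oracle_plane_normal(mj),
                         fold = TRUE) < criteria$pistack_angle_max) {
          emit(g, a, "PS")
        }
      }

      # PC
      hit <- FALSE
      for (dir in 1:2) {
        cat_i <- if (dir == 1) pick(gi, tb$cation[[grn]]) else
          pick(ai, tb$cation[[arn]])
        ring_i <- if (dir == 1) pick(ai, tb$ring[[arn]]) else
          pick(gi, tb$ring[[grn]])
        if (!length(cat_i) || length(ring_i) < 5) next
        m <- xyz[ring_i, , drop = FALSE]
        cen <- colMeans(m)
        for (c in cat_i) {
          if (oracle_dist(xyz[c, ], cen) < criteria$catpi_cutoff &&
              oracle_angle(oracle_plane_normal(m), xyz[c, ] - cen,
                           fold = TRUE) < criteria$catpi_angle_max) {
            hit <- TRUE
          }
        }
      }
      if (hit) emit(g, a, "PC")
    }
  }
  if (!length(out)) {
    return(data.frame(gpcr_residue = character(0),
                      gprot_residue = character(0),
                      contact_type = character(0)))
  }
  res <- unique(do.call(rbind, out))
  res[order(res$gpcr_residue, res$gprot_residue, res$contact_type), ]
}

# run the oracle over every frame of a trajectory
oracle_timeline <- function(trajectory, criteria = contact_criteria()) {
  topo <- trajectory$topology
  out <- list()
  for (f in seq_along(trajectory$frame_ids)) {
    xyz <- trajectory$coords[, , f]
    fc <- oracle_frame_contacts(topo$atoms, xyz, topo$selections$gpcr,
                                topo$selections$galpha, criteria)
    if (nrow(fc)) {
      fc$frame_id <- trajectory$frame_ids[f]
      out[[length(out) + 1]] <- fc
    }
  }
  if (!length(out)) {
    return(data.frame(frame_id = integer(0), gpcr_residue = character(0),
                      gprot_residue = character(0),
                      contact_type = character(0)))
  }
  do.call(rbind, out)
}

# canonical sorted event-set string for comparison
event_set <- function(df) {
  sort(paste(df$frame_id, df$gpcr_residue, df$gprot_residue,
             df$contact_type, sep = "|"))
}

# a random toy frame generator: residues of random types placed on two
# facing grids with random perturbations, some pairs within contact range
random_toy_trajectory <- function(seed, n_frames = 1, n_pairs = 4,
                                  jitter = 0.4) {
  set.seed(seed)
  types <- c("ASP", "GLU", "LYS", "ARG", "SER", "PHE", "TYR", "HIS",
             "ALA", "LEU")
  placements <- list()
  for (i in seq_len(n_pairs)) {
    sep <- runif(1, 2.5, 9)          # anchor separation, contact-ish range
    base <- c((i - 1) * 14, 0, 0)    # keep pairs apart from each other
    placements[[2 * i - 1]] <- toy_residue(
      sample(types, 1), "R", i, anchor = base)
    placements[[2 * i]] <- toy_residue(
      sample(types, 1), "A", 100 + i,
      anchor = base + c(runif(1, -1, 1), runif(1, -1, 1), sep),
      rotation = rotation_matrix(sample(c("x", "y", "z"), 1),
                                 runif(1, 0, 180)))
  }
  spec <- toy_complex_spec(placements, n_frames = n_frames,
                           jitter = jitter, seed = seed)
  generate_toy_complex(spec)$trajectory
}

# deterministic retry: some random layouts place atoms < 1 A apart, which
# generate_toy_complex rejects; step the seed until a valid layout appears
random_toy_trajectory_safe <- function(seed, ...) {
  for (s in seed + 1000L * (0:20)) {
    tr <- tryCatch(random_toy_trajectory(s, ...), error = function(e) NULL)
    if (!is.null(tr)) return(tr)
  }
  stop("no valid random toy layout found")
}
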