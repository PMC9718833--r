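# Readers/writers and shared conventions: coordinates in Angstrom, 0-based
# frame indices, half-open frame windows, residue identity = (chain, resnum).

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT",
                    "H", "H1", "H2", "H3", "HA", "HA2", "HA3", "HN")

GPROT_SUBFAMILIES <- c("Gs", "Gi", "Gq", "G12/13")
COUPLING_CATEGORIES <- c("primary", "secondary", "none")
COUPLING_DATASETS <- c("AVET", "GTP", "INOUE")

#' Residue key strings
#'
#' Residues are identified by chain and residue number throughout; insertion
#' codes are not supported. Keys render as \code{"chain:resnum"}.
#'
#' @param chain character vector of chain identifiers
#' @param resnum integer vector of residue numbers
#' @return character vector of keys
#' @export
residue_key <- function(chain, resnum) {
  paste0(chain, ":", as.integer(resnum))
}

#' Read a PDB topology
#'
#' Parses a (single- or multi-model) PDB file into an atom table and two named
#' residue selections, \code{"gpcr"} and \code{"galpha"}, assigned by chain
#' identifier. Sidechain status is assigned by atom name: backbone names
#' (N, CA, C, O, OXT and the standard backbone hydrogens) are backbone,
#' everything else sidechain. All heavy atoms are retained; hydrogens are
#' retained when present.
#'
#' @param path PDB file path
#' @param chain_gpcr chain id(s) forming the receptor selection
#' @param chain_gprot chain id(s) forming the Galpha selection
#' @return an object of class \code{st_topology}: list with \code{atoms}
#'   (data.frame: atom_name, element, chain, resnum, resname, residue,
#'   is_sidechain, x, y, z) and \code{selections} (named list of residue-key
#'   character vectors)
#' @export
read_topology <- function(path, chain_gpcr = "R", chain_gprot = "A") {
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e) stop("cannot parse PDB file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  if (any(nzchar(at$insert) & !is.na(at$insert))) {
    stop("insertion codes are not supported", call. = FALSE)
  }
  element <- trimws(at$elesy)
  missing_el <- is.na(element) | !nzchar(element)
  if (any(missing_el)) {
    # fall back on the leading letter of the atom name
    element[missing_el] <- sub("^[0-9]*([A-Za-z]).*$", "\\1",
                               trimws(at$elety[missing_el]))
  }
  atoms <- data.frame(
    atom_name    = trimws(at$elety),
    element      = element,
    chain        = at$chain,
    resnum       = as.integer(at$resno),
    resname      = trimws(at$resid),
    stringsAsFactors = FALSE
  )
  atoms$residue <- residue_key(atoms$chain, atoms$resnum)
  atoms$is_sidechain <- !(atoms$atom_name %in% BACKBONE_ATOMS)
  atoms$x <- at$x
  atoms$y <- at$y
  atoms$z <- at$z
  sel_res <- function(chains) unique(atoms$residue[atoms$chain %in% chains])
  selections <- list(gpcr = sel_res(chain_gpcr), galpha = sel_res(chain_gprot))
  if (length(selections$gpcr) == 0L || length(selections$galpha) == 0L) {
    stop("empty chain selection (gpcr chains: ",
         paste(chain_gpcr, collapse = ","), "; galpha chains: ",
         paste(chain_gprot, collapse = ","), ")", call. = FALSE)
  }
  new_topology(atoms, selections)
}

new_topology <- function(atoms, selections) {
  if (anyDuplicated(unique(atoms[, c("chain", "resnum")])) > 0) {
    stop("duplicate residue keys in topology", call. = FALSE)
  }
  if (length(intersect(selections$gpcr, selections$galpha)) > 0L) {
    stop("gpcr and galpha selections overlap", call. = FALSE)
  }
  structure(list(atoms = atoms, selections = selections),
            class = "st_topology")
}

#' @export
print.st_topology <- function(x, ...) {
  cat("st_topology:", nrow(x$atoms), "atoms,",
      length(unique(x$atoms$residue)), "residues;",
      length(x$selections$gpcr), "gpcr /",
      length(x$selections$galpha), "galpha residues\n")
  invisible(x)
}

n_atoms <- function(topology) nrow(topology$atoms)

#' Read trajectory frames
#'
#' Reads one or more coordinate files (multi-model PDB, or DCD) against a
#' topology and returns the concatenated frame ensemble. The half-open window
#' \code{frame_range = c(start, end)} (0-based) is applied per file before
#' concatenation, mirroring the practice of keeping only the terminal window
#' of each replicate; replicate order is preserved and frames are renumbered
#' 0..n-1 across the ensemble.
#'
#' @param paths character vector of coordinate file paths (replicates)
#' @param topology an \code{st_topology}
#' @param frame_range integer length-2 half-open window \code{[start, end)}
#'   applied within each file, or NULL for all frames
#' @param system_id label carried through to downstream tables
#' @return an \code{st_trajectory}: list(topology, coords (n_atoms x 3 x
#'   n_frames array, Angstrom), frame_ids, system_id)
#' @export
read_trajectory <- function(paths, topology, frame_range = NULL,
                            system_id = "system") {
  stopifnot(inherits(topology, "st_topology"))
  blocks <- lapply(paths, function(p) {
    xyz <- read_frames_file(p)
    if (ncol(xyz) != 3L * n_atoms(topology)) {
      stop("atom count mismatch: file '", p, "' has ", ncol(xyz) / 3,
           " atoms, topology has ", n_atoms(topology), call. = FALSE)
    }
    window_frames(xyz, frame_range)
  })
  xyz <- do.call(rbind, blocks)
  if (nrow(xyz) < 1L) stop("no frames after windowing", call. = FALSE)
  new_trajectory(topology, xyz, system_id)
}

read_frames_file <- function(path) {
  if (grepl("\\.dcd$", path, ignore.case = TRUE)) {
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
  } else {
    pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE,
                                            verbose = FALSE))
    xyz <- pdb$xyz
  }
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  xyz
}

window_frames <- function(xyz, frame_range) {
  if (is.null(frame_range)) return(xyz)
  start <- as.integer(frame_range[1]); end <- as.integer(frame_range[2])
  if (end <= start) {
    stop("empty frame window [", start, ",", end, ")", call. = FALSE)
  }
  if (start < 0L || end > nrow(xyz)) {
    stop("frame window [", start, ",", end, ") outside 0..", nrow(xyz),
         call. = FALSE)
  }
  xyz[(start + 1L):end, , drop = FALSE]
}

new_trajectory <- function(topology, xyz, system_id) {
  n_fr <- nrow(xyz)
  coords <- aperm(array(t(xyz), dim = c(3L, n_atoms(topology), n_fr)),
                  c(2L, 1L, 3L))
  structure(list(topology = topology, coords = coords,
                 frame_ids = seq_len(n_fr) - 1L, system_id = system_id),
            class = "st_trajectory")
}

#' @export
print.st_trajectory <- function(x, ...) {
  cat("st_trajectory '", x$system_id, "': ", length(x$frame_ids),
      " frames x ", dim(x$coords)[1], " atoms\n", sep = "")
  invisible(x)
}

n_frames <- function(trajectory) length(trajectory$frame_ids)

frame_coords <- function(trajectory, i) {
  # i is 1-based internal index
  trajectory$coords[, , i, drop = TRUE]
}

#' Read a generic-numbering map
#'
#' TSV with columns chain, resnum, generic, sse, side; one row per residue.
#' GPCR generics use GPCRdb notation ("3x53", "34x51"); Galpha generics use
#' common G protein numbering ("G.H5.16"). Residues absent from the map are
#' treated as unmapped downstream and excluded from fingerprinting.
#'
#' @param path TSV path
#' @return data.frame with a \code{residue} key column, class
#'   \code{st_numbering_map}
#' @export
read_numbering_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  needed <- c("chain", "resnum", "generic", "sse", "side")
  miss <- setdiff(needed, names(df))
  if (length(miss) > 0L) {
    stop("numbering map missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  as_numbering_map(df)
}

as_numbering_map <- function(df) {
  df$resnum <- as.integer(df$resnum)
  df$residue <- residue_key(df$chain, df$resnum)
  if (anyDuplicated(df$residue) > 0L) {
    stop("duplicate residue key(s) in numbering map: ",
         paste(unique(df$residue[duplicated(df$residue)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(df$generic))) stop("empty generic number", call. = FALSE)
  if (!all(df$side %in% c("GPCR", "GPROT"))) {
    stop("side must be GPCR or GPROT", call. = FALSE)
  }
  for (sd in unique(df$side)) {
    g <- df$generic[df$side == sd]
    if (anyDuplicated(g) > 0L) {
      stop("duplicate generic number within side ", sd, call. = FALSE)
    }
  }
  class(df) <- c("st_numbering_map", "data.frame")
  df
}

#' Write a generic-numbering map to TSV
#' @param map an \code{st_numbering_map}
#' @param path output TSV path
#' @export
write_numbering_map <- function(map, path) {
  utils::write.table(map[, c("chain", "resnum", "generic", "sse", "side")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

map_lookup <- function(map, residues) {
  idx <- match(residues, map$residue)
  list(generic = map$generic[idx], sse = map$sse[idx])
}

#' Read a G protein coupling table
#'
#' Accepts either categorical tables (value in primary/secondary/none, e.g.
#' GPCRdb / Guide-to-Pharmacology style) or numeric double-normalised Emax
#' tables (Avet et al. style). Columns: receptor, subfamily, value.
#'
#' @param path CSV or TSV path (delimiter sniffed from extension)
#' @param dataset_id one of "AVET", "GTP", "INOUE"
#' @return data.frame (receptor, subfamily, category, emax, dataset_id) of
#'   class \code{st_coupling_table}
#' @export
read_coupling_table <- function(path, dataset_id) {
  dataset_id <- match.arg(dataset_id, COUPLING_DATASETS)
  readf <- if (grepl("\\.tsv$", path, ignore.case = TRUE))
    utils::read.delim else utils::read.csv
  df <- readf(path, stringsAsFactors = FALSE)
  needed <- c("receptor", "subfamily", "value")
  miss <- setdiff(needed, names(df))
  if (length(miss) > 0L) {
    stop("coupling table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(df$subfamily), GPROT_SUBFAMILIES)
  if (length(bad) > 0L) {
    stop("unknown G protein subfamily label(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df[, c("receptor", "subfamily")]) > 0L) {
    stop("duplicate (receptor, subfamily) rows", call. = FALSE)
  }
  val <- df$value
  num <- suppressWarnings(as.numeric(val))
  is_num <- !is.na(num)
  is_cat <- val %in% COUPLING_CATEGORIES
  if (!all(is_num | is_cat)) {
    stop("coupling values must be numeric Emax or one of ",
         paste(COUPLING_CATEGORIES, collapse = "/"), call. = FALSE)
  }
  out <- data.frame(receptor = df$receptor, subfamily = df$subfamily,
                    category = NA_character_, emax = NA_real_,
                    dataset_id = dataset_id, stringsAsFactors = FALSE)
  out$category[is_cat] <- val[is_cat]
  out$emax[is_num & !is_cat] <- num[is_num & !is_cat]
  if (any(!is.na(out$emax) & !is.finite(out$emax))) {
    stop("non-finite Emax value", call. = FALSE)
  }
  class(out) <- c("st_coupling_table", "data.frame")
  out
}

#' Write a multi-model PDB file
#'
#' Emits one MODEL/ENDMDL block per frame with standard ATOM records
#' (element symbol in columns 77-78), suitable for re-reading with
#' \code{\link{read_topology}} / \code{\link{read_trajectory}}.
#'
#' @param topology an \code{st_topology}
#' @param coords n_atoms x 3 x n_frames array (Angstrom); defaults to the
#'   topology's reference coordinates as a single model
#' @param path output path
#' @export
write_multimodel_pdb <- function(topology, coords = NULL, path) {
  at <- topology$atoms
  if (is.null(coords)) {
    coords <- array(as.matrix(at[, c("x", "y", "z")]),
                    dim = c(nrow(at), 3L, 1L))
  }
  con <- file(path, "w")
  on.exit(close(con))
  nfr <- dim(coords)[3]
  for (f in seq_len(nfr)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- coords[, , f, drop = TRUE]
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3L)
    name4 <- ifelse(nchar(at$atom_name) < 4L,
                    sprintf(" %-3s", at$atom_name),
                    sprintf("%-4s", at$atom_name))
    lines <- sprintf(
      "ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nrow(at)), name4, at$resname, at$chain, at$resnum,
      xyz[, 1], xyz[, 2], xyz[, 3], at$element)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
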