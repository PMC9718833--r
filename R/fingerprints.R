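# Binary contact fingerprints, per-system contact frequencies, persistence
# taxonomy (subfamily specific vs common contacts) and SSE composition.

GP_CLASSES <- c("Gs", "Gi", "Gq")

pair_key <- function(gpcr_generic, gprot_generic) {
  paste0(gpcr_generic, ":", gprot_generic)
}

split_pair_key <- function(keys) {
  parts <- strsplit(keys, ":", fixed = TRUE)
  data.frame(gpcr_generic = vapply(parts, `[`, "", 1L),
             gprot_generic = vapply(parts, `[`, "", 2L),
             stringsAsFactors = FALSE)
}

#' Build the contact-pair universe
#'
#' Union of all contact pairs observed across timelines, keyed
#' \code{"<gpcr generic>:<gprot generic>"}, in deterministic lexicographic
#' order. When \code{resolved_regions} is given (a named per-system list of
#' resolved GPCR generic positions), pairs whose receptor-side position is
#' unresolved in any system are excluded, so that only regions represented in
#' every complex enter the analysis.
#'
#' @param timelines list of \code{st_timeline}
#' @param resolved_regions named list (system_id -> character vector of GPCR
#'   generic positions), or NULL for no region filter
#' @return character vector of pair keys
#' @export
build_pair_universe <- function(timelines, resolved_regions = NULL) {
  stopifnot(length(timelines) >= 1L)
  keys <- unique(unlist(lapply(timelines, function(tl) {
    if (nrow(tl) == 0L) return(character(0))
    unique(pair_key(tl$gpcr_generic, tl$gprot_generic))
  })))
  if (!is.null(resolved_regions)) {
    common <- Reduce(intersect, resolved_regions)
    keys <- keys[split_pair_key(keys)$gpcr_generic %in% common]
  }
  if (length(keys) == 0L) stop("empty pair universe", call. = FALSE)
  sort(keys, method = "radix")
}

#' One-hot encode a timeline into a fingerprint block
#'
#' Entry (frame, pair) is 1 iff any contact type links the pair in that
#' frame; the five contact types collapse to a single binary event per pair.
#' Pairs outside the universe are dropped.
#'
#' @param timeline an \code{st_timeline}
#' @param pair_universe character vector from
#'   \code{\link{build_pair_universe}}
#' @return binary integer matrix, n_frames x length(pair_universe), with
#'   column names = pair keys
#' @export
encode_fingerprints <- function(timeline, pair_universe) {
  nf <- attr(timeline, "n_frames")
  stopifnot(nf >= 1L)
  m <- matrix(0L, nrow = nf, ncol = length(pair_universe),
              dimnames = list(NULL, pair_universe))
  if (nrow(timeline) > 0L) {
    keys <- pair_key(timeline$gpcr_generic, timeline$gprot_generic)
    col <- match(keys, pair_universe)
    keep <- !is.na(col)
    m[cbind(timeline$frame_id[keep] + 1L, col[keep])] <- 1L
  }
  m
}

#' Assemble a multi-system fingerprint set
#'
#' @param blocks named list (system_id -> binary matrix from
#'   \code{\link{encode_fingerprints}}), all sharing one pair universe
#' @param system_class named character vector mapping system_id to G protein
#'   class ("Gs", "Gi", "Gq", or other labels)
#' @return an \code{st_fingerprints}: list(X = stacked binary matrix,
#'   frames = data.frame(system_id, class), universe)
#' @export
fingerprint_set <- function(blocks, system_class) {
  stopifnot(length(blocks) >= 1L, !is.null(names(blocks)))
  uni <- colnames(blocks[[1]])
  for (b in blocks) stopifnot(identical(colnames(b), uni))
  miss <- setdiff(names(blocks), names(system_class))
  if (length(miss)) {
    stop("no class for system(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  X <- do.call(rbind, blocks)
  frames <- data.frame(
    system_id = rep(names(blocks), vapply(blocks, nrow, 0L)),
    stringsAsFactors = FALSE)
  frames$class <- unname(system_class[frames$system_id])
  structure(list(X = X, frames = frames, universe = uni),
            class = "st_fingerprints")
}

#' @export
print.st_fingerprints <- function(x, ...) {
  cat("st_fingerprints:", nrow(x$X), "frames x", ncol(x$X), "pairs;",
      length(unique(x$frames$system_id)), "systems\n")
  invisible(x)
}

#' Per-system contact frequencies
#'
#' The frequency of a pair in a system is the fraction of that system's
#' frames in which the contact is present, i.e. the column mean of the
#' system's fingerprint block.
#'
#' @param fp an \code{st_fingerprints}
#' @return data.frame (system_id, pair, frequency) of class
#'   \code{st_frequency_table}
#' @export
contact_frequencies <- function(fp) {
  sys <- unique(fp$frames$system_id)
  out <- do.call(rbind, lapply(sys, function(s) {
    block <- fp$X[fp$frames$system_id == s, , drop = FALSE]
    data.frame(system_id = s, pair = fp$universe,
               frequency = unname(colMeans(block)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("st_frequency_table", "data.frame")
  out
}

#' Write/read a frequency table (TSV: pair, system_id, frequency)
#' @param freq an \code{st_frequency_table}
#' @param path TSV path
#' @export
write_frequency_table <- function(freq, path) {
  utils::write.table(freq[, c("pair", "system_id", "frequency")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_frequency_table
#' @export
read_frequency_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df <- df[, c("system_id", "pair", "frequency")]
  class(df) <- c("st_frequency_table", "data.frame")
  df
}

#' Classify contact persistence
#'
#' A pair is persistent in a G protein class when its frequency exceeds the
#' threshold (strictly, default > 0.20) in at least one of that class's
#' systems. Pairs persistent in exactly one class are subfamily specific
#' ("specific-Gs"/"specific-Gi"/"specific-Gq"); pairs persistent in all three
#' classes are "common"; everything else is "other" (sub-labelled
#' "two-family" or "never-persistent").
#'
#' @param freq an \code{st_frequency_table}
#' @param system_class named character vector system_id -> class; classes
#'   must cover Gs, Gi and Gq with at least one system each
#' @param threshold persistence frequency threshold (strict)
#' @return data.frame (pair, label, sublabel, persistent_in) of class
#'   \code{st_persistence}; \code{persistent_in} is a comma-joined class list
#' @export
classify_persistence <- function(freq, system_class, threshold = 0.20) {
  cls <- unname(system_class[freq$system_id])
  if (any(is.na(cls))) {
    stop("system(s) without class assignment: ",
         paste(unique(freq$system_id[is.na(cls)]), collapse = ", "),
         call. = FALSE)
  }
  for (g in GP_CLASSES) {
    if (!any(system_class == g)) {
      stop("no system for class ", g, call. = FALSE)
    }
  }
  pairs <- sort(unique(freq$pair), method = "radix")
  pers <- sapply(GP_CLASSES, function(g) {
    sub <- freq[cls == g, ]
    hit <- tapply(sub$frequency > threshold, sub$pair, any)
    as.logical(hit[pairs])
  })
  if (is.null(dim(pers))) pers <- matrix(pers, nrow = 1L,
                                         dimnames = list(NULL, GP_CLASSES))
  n_in <- rowSums(pers)
  first_in <- apply(pers, 1L, function(r) which(r)[1])
  label <- ifelse(n_in == 3L, "common",
           ifelse(n_in == 1L,
                  paste0("specific-", GP_CLASSES[first_in]),
                  "other"))
  sublabel <- ifelse(n_in == 2L, "two-family",
              ifelse(n_in == 0L, "never-persistent", label))
  out <- data.frame(
    pair = pairs, label = label, sublabel = sublabel,
    persistent_in = apply(pers, 1L, function(r)
      paste(GP_CLASSES[r], collapse = ",")),
    stringsAsFactors = FALSE)
  class(out) <- c("st_persistence", "data.frame")
  out
}

round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Secondary-structure composition of a contact-pair set
#'
#' Tallies pairs by the secondary structural element (SSE) of their receptor-
#' or Galpha-side position and reports percentages (one decimal, half-up)
#' summing to 100.
#'
#' @param pairs character vector of pair keys
#' @param numbering_map an \code{st_numbering_map} with generic -> sse rows
#' @param side "GPCR" or "GPROT"
#' @return data.frame (sse, n, percent), descending percent
#' @export
sse_composition <- function(pairs, numbering_map, side = c("GPCR", "GPROT")) {
  side <- match.arg(side)
  comp <- split_pair_key(pairs)
  gen <- if (side == "GPCR") comp$gpcr_generic else comp$gprot_generic
  sub <- numbering_map[numbering_map$side == side, ]
  sse <- sub$sse[match(gen, sub$generic)]
  if (any(is.na(sse))) {
    stop("position(s) without SSE annotation: ",
         paste(unique(gen[is.na(sse)]), collapse = ", "), call. = FALSE)
  }
  tab <- sort(table(sse), decreasing = TRUE)
  data.frame(sse = names(tab), n = as.integer(tab),
             percent = round_half_up(100 * as.integer(tab) / length(pairs)),
             stringsAsFactors = FALSE)
}

#' Mean contact frequency over a pair subset
#'
#' Arithmetic mean of one system's frequencies over the subset members that
#' exist in the frequency table (e.g. mean sampling of the common-contact
#' subset by a given complex).
#'
#' @param freq an \code{st_frequency_table}
#' @param system_id system to average
#' @param subset character vector of pair keys
#' @return numeric scalar
#' @export
mean_frequency_over_subset <- function(freq, system_id, subset) {
  sub <- freq[freq$system_id == system_id & freq$pair %in% subset, ]
  if (nrow(sub) == 0L) {
    stop("subset has no members in the frequency table for system ",
         system_id, call. = FALSE)
  }
  mean(sub$frequency)
}

#' Write/read a fingerprint matrix (TSV: frame_id + one column per pair)
#' @param block binary matrix from \code{\link{encode_fingerprints}}
#' @param path TSV path
#' @export
write_fingerprints <- function(block, path) {
  df <- data.frame(frame_id = seq_len(nrow(block)) - 1L, block,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fingerprints
#' @export
read_fingerprints <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, setdiff(names(df), "frame_id"), drop = FALSE])
  storage.mode(m) <- "integer"
  m
}
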