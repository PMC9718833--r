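# Weighted promiscuity index over multi-dataset G protein coupling tables.
# Categories map to numeric scores (primary = 1, secondary = 0.5, none = 0);
# per-dataset indices are the mean over the four Galpha subfamilies and are
# weighted by how directly each dataset measured coupling
# (AVET BRET = 4, Guide-to-Pharmacology curation = 2, chimeric-Gq assay = 1).

DATASET_WEIGHTS <- c(AVET = 4, GTP = 2, INOUE = 1)
CATEGORY_SCORES <- c(primary = 1, secondary = 0.5, none = 0)

#' Categorize a double-normalized Emax value
#'
#' Emax > 0.8 is "primary" coupling, 0.2 < Emax < 0.8 "secondary",
#' anything else "none". Boundaries fall to the lower category (strict
#' inequalities). Negative values are treated as "none" with a warning.
#'
#' @param emax numeric vector of double-normalized Emax values
#' @return character vector of categories
#' @export
categorize_emax <- function(emax) {
  if (any(!is.finite(emax))) stop("Emax must be finite", call. = FALSE)
  if (any(emax < 0)) {
    warning("negative Emax value(s) treated as 'none'")
  }
  # boundaries fall to the lower category: 0.8 -> secondary, 0.2 -> none
  ifelse(emax > 0.8, "primary", ifelse(emax > 0.2, "secondary", "none"))
}

coupling_scores <- function(tab) {
  cat <- tab$category
  needs <- is.na(cat)
  cat[needs] <- categorize_emax(tab$emax[needs])
  data.frame(receptor = tab$receptor, dataset_id = tab$dataset_id,
             subfamily = tab$subfamily, category = cat,
             numeric = unname(CATEGORY_SCORES[cat]),
             stringsAsFactors = FALSE)
}

#' Per-dataset coupling index for one receptor
#'
#' Arithmetic mean of the numeric category scores over the four Galpha
#' subfamilies (Gs, Gi, Gq, G12/13); subfamilies not measured by the dataset
#' count as 0 in the mean (they are part of the four-subfamily framing).
#'
#' @param scores data.frame with subfamily and numeric columns for one
#'   receptor in one dataset
#' @return numeric scalar in [0, 1]
#' @export
dataset_index <- function(scores) {
  v <- rep(0, length(GPROT_SUBFAMILIES))
  names(v) <- GPROT_SUBFAMILIES
  idx <- match(scores$subfamily, GPROT_SUBFAMILIES)
  if (any(is.na(idx))) stop("unknown subfamily", call. = FALSE)
  if (anyDuplicated(idx)) stop("duplicate subfamily rows", call. = FALSE)
  v[idx] <- scores$numeric
  mean(v)
}

#' Weighted promiscuity index across coupling datasets
#'
#' For each receptor, the per-dataset index (mean categorical score over the
#' four subfamilies) is multiplied by the dataset weight (AVET 4, GTP 2,
#' INOUE 1) and the composite is the mean of the weighted indices. By
#' default a dataset that does not cover a receptor is excluded from that
#' receptor's mean; with \code{missing_as_zero = TRUE} it enters as 0.
#'
#' @param tables list of \code{st_coupling_table} (any subset of the three
#'   datasets)
#' @param missing_as_zero include absent datasets as 0 in the mean
#' @return data.frame (receptor, idx_avet, idx_gtp, idx_inoue, composite,
#'   n_datasets), sorted by descending composite
#' @export
promiscuity_index <- function(tables, missing_as_zero = FALSE) {
  scored <- do.call(rbind, lapply(tables, coupling_scores))
  receptors <- sort(unique(scored$receptor), method = "radix")
  per <- expand.grid(receptor = receptors, dataset_id = COUPLING_DATASETS,
                     stringsAsFactors = FALSE)
  per$index <- mapply(function(r, d) {
    sub <- scored[scored$receptor == r & scored$dataset_id == d, ]
    if (nrow(sub) == 0L) NA_real_ else dataset_index(sub)
  }, per$receptor, per$dataset_id)

  out <- do.call(rbind, lapply(receptors, function(r) {
    idx <- per$index[match(paste(r, COUPLING_DATASETS),
                           paste(per$receptor, per$dataset_id))]
    names(idx) <- COUPLING_DATASETS
    weighted <- DATASET_WEIGHTS * idx
    present <- !is.na(idx)
    composite <- if (missing_as_zero) {
      sum(weighted[present]) / length(weighted)
    } else {
      mean(weighted[present])
    }
    data.frame(receptor = r, idx_avet = idx[["AVET"]],
               idx_gtp = idx[["GTP"]], idx_inoue = idx[["INOUE"]],
               composite = composite, n_datasets = sum(present),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$composite, out$receptor), ]
  rownames(out) <- NULL
  out
}
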