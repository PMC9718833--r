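# Linear discriminant model over binary contact fingerprints, composite
# weight x frequency scoring, and extraction of the top-k spatiotemporal
# code per G protein class.
#
# The discriminant subspace is fitted with MASS::lda (SVD-based, common
# within-class covariance). On top of the MASS fit we compute per-class
# linear weight vectors in the centered class-mean convention
#   w_X = S S' (mu_X - xbar),   b_X = -0.5 ||S'(mu_X - xbar)||^2 + log pi_X
# where S is the (whitening) scaling matrix, mu_X the class mean, xbar the
# prior-weighted grand mean and pi_X the class prior. argmax_X w_X.x + b_X
# reproduces the Gaussian LDA decision rule restricted to the discriminant
# subspace; w_X is the per-class coefficient vector used for feature
# ranking.

#' Fit the linear discriminant model on contact fingerprints
#'
#' Fits a 3-class (or generally g-class) LDA on a binary frames x pairs
#' matrix. Zero-variance and within-class-constant columns cannot enter the
#' MASS fit; they are dropped from the fit and their weights reported as 0.
#' Scalings carry a deterministic sign convention (first nonzero loading of
#' each component positive) so projections are reproducible.
#'
#' @param X binary matrix, frames x pairs (column names = pair keys)
#' @param labels class label per row
#' @param prior class priors; default empirical frequencies
#' @return an \code{st_lda}: list(classes, universe, scalings (pairs x
#'   (g-1)), weights (pairs x g), intercepts, class_means, xbar,
#'   explained_variance_ratio, prior, dropped (constant columns), solver)
#' @export
fit_lda <- function(X, labels, prior = NULL) {
  labels <- as.character(labels)
  stopifnot(nrow(X) == length(labels))
  classes <- sort(unique(labels))
  if (length(classes) < 2L) {
    stop("need at least two classes to fit a discriminant model",
         call. = FALSE)
  }
  if (any(table(labels) < 2L)) {
    stop("every class needs at least two frames", call. = FALSE)
  }
  uni <- colnames(X)
  # drop columns constant within every class: they carry no discriminant
  # information and break the within-class covariance estimate
  keep <- vapply(seq_len(ncol(X)), function(j) {
    any(vapply(classes, function(g)
      stats::var(X[labels == g, j]) > 0, TRUE))
  }, TRUE)
  if (!any(keep)) stop("all features are constant within classes",
                       call. = FALSE)
  Xf <- X[, keep, drop = FALSE]
  if (is.null(prior)) prior <- as.numeric(table(factor(labels, classes))) /
      length(labels)
  fit <- suppressWarnings(
    MASS::lda(Xf, grouping = factor(labels, levels = classes),
              prior = prior))
  S <- fit$scaling
  # deterministic sign: first nonzero loading of each component positive
  for (k in seq_len(ncol(S))) {
    nz <- which(abs(S[, k]) > 1e-12)[1]
    if (!is.na(nz) && S[nz, k] < 0) S[, k] <- -S[, k]
  }
  evr <- fit$svd^2 / sum(fit$svd^2)
  mu <- fit$means                       # g x p_kept
  xbar <- drop(prior %*% mu)            # prior-weighted grand mean
  centered <- sweep(mu, 2L, xbar)       # g x p_kept
  W_kept <- S %*% t(centered %*% S)     # p_kept x g
  proj <- centered %*% S                # g x (g-1)
  intercepts <- -0.5 * rowSums(proj^2) + log(prior)

  expand <- function(m) {
    out <- matrix(0, nrow = length(uni), ncol = ncol(m),
                  dimnames = list(uni, colnames(m)))
    out[keep, ] <- m
    out
  }
  scalings <- expand(S)
  colnames(scalings) <- paste0("LD", seq_len(ncol(S)))
  weights <- expand(W_kept)
  colnames(weights) <- classes
  means_full <- matrix(0, nrow = length(classes), ncol = length(uni),
                       dimnames = list(classes, uni))
  means_full[, keep] <- mu
  xbar_full <- numeric(length(uni)); names(xbar_full) <- uni
  xbar_full[keep] <- xbar

  structure(list(classes = classes, universe = uni, scalings = scalings,
                 weights = weights, intercepts = unname(intercepts),
                 class_means = means_full, xbar = xbar_full,
                 explained_variance_ratio = unname(evr), prior = prior,
                 dropped = uni[!keep], solver = "svd (MASS::lda)"),
            class = "st_lda")
}

#' @export
print.st_lda <- function(x, ...) {
  cat("st_lda:", length(x$classes), "classes (",
      paste(x$classes, collapse = ", "), "),",
      length(x$universe), "contact pairs;",
      "explained variance:",
      paste(sprintf("%.2f%%", 100 * x$explained_variance_ratio),
            collapse = " / "), "\n")
  invisible(x)
}

# align an external fingerprint matrix onto the model universe:
# missing pairs imputed 0, novel pairs dropped; tallies returned
align_universe <- function(X, universe) {
  out <- matrix(0L, nrow = nrow(X), ncol = length(universe),
                dimnames = list(NULL, universe))
  shared <- intersect(colnames(X), universe)
  out[, shared] <- X[, shared]
  attr(out, "n_missing") <- length(setdiff(universe, colnames(X)))
  attr(out, "n_dropped") <- length(setdiff(colnames(X), universe))
  out
}

#' Project fingerprints into the discriminant space and classify
#'
#' Maps frames to discriminant coordinates \code{(x - xbar) S} and assigns
#' each frame the class maximising the linear decision score. Fingerprints
#' from outside the training universe are aligned first: missing pairs are
#' imputed as 0, novel pairs are dropped (both tallied in attributes).
#'
#' @param model an \code{st_lda}
#' @param X binary matrix with pair-key column names
#' @param target_class optional class name; when given, the result carries
#'   \code{accuracy} = fraction of frames predicted as that class
#' @return data.frame (component1, component2, ..., predicted) with
#'   attributes \code{accuracy}, \code{n_missing}, \code{n_dropped}
#' @export
project_and_classify <- function(model, X, target_class = NULL) {
  if (nrow(X) == 0L) stop("empty fingerprint matrix", call. = FALSE)
  A <- align_universe(X, model$universe)
  Ac <- sweep(A, 2L, model$xbar)
  Z <- Ac %*% model$scalings
  scores <- Ac %*% model$weights +
    matrix(model$intercepts, nrow(A), length(model$classes), byrow = TRUE)
  pred <- model$classes[max.col(scores, ties.method = "first")]
  out <- as.data.frame(Z)
  names(out) <- paste0("component", seq_len(ncol(Z)))
  out$predicted <- pred
  attr(out, "n_missing") <- attr(A, "n_missing")
  attr(out, "n_dropped") <- attr(A, "n_dropped")
  if (!is.null(target_class)) {
    stopifnot(target_class %in% model$classes)
    attr(out, "accuracy") <- mean(pred == target_class)
  }
  out
}

#' Stratified holdout accuracy of the discriminant classifier
#'
#' Random stratified train/test split (default 80:20), fit on the training
#' frames, accuracy on the held-out frames. Stratification is by system when
#' system ids are given, otherwise by class.
#'
#' @param X binary matrix, frames x pairs
#' @param labels class label per row
#' @param split training fraction
#' @param seed RNG seed for the split
#' @param systems optional system id per row for stratification
#' @return held-out accuracy (scalar) with attribute \code{model}
#' @export
holdout_accuracy <- function(X, labels, split = 0.8, seed = 1L,
                             systems = NULL) {
  labels <- as.character(labels)
  strata <- if (is.null(systems)) labels else as.character(systems)
  set.seed(seed)
  train <- logical(length(labels))
  for (s in unique(strata)) {
    idx <- which(strata == s)
    n_tr <- max(1L, round(split * length(idx)))
    train[sample(idx, n_tr)] <- TRUE
  }
  if (!all(unique(labels) %in% unique(labels[train]))) {
    stop("a class is absent from the training split", call. = FALSE)
  }
  model <- fit_lda(X[train, , drop = FALSE], labels[train])
  pred <- project_and_classify(model, X[!train, , drop = FALSE])$predicted
  acc <- mean(pred == labels[!train])
  attr(acc, "model") <- model
  acc
}

#' Composite weight-frequency scores (wGx)
#'
#' For each class X and pair p: cGx = mean frequency of p over X's systems
#' (mean of per-system frequencies), wGx = w_X(p) * cGx(p). Ranks are
#' assigned per class by descending wGx, ties broken by larger |w_X| then
#' lexicographic pair key.
#'
#' @param model an \code{st_lda}
#' @param freq an \code{st_frequency_table} over the model universe
#' @param system_class named character vector system_id -> class
#' @return data.frame (class, pair, weight, cGx, wGx, rank) of class
#'   \code{st_scores}
#' @export
composite_scores <- function(model, freq, system_class) {
  if (!all(freq$pair %in% model$universe)) {
    stop("frequency table contains pairs outside the model universe",
         call. = FALSE)
  }
  cls_of <- unname(system_class[freq$system_id])
  out <- do.call(rbind, lapply(model$classes, function(g) {
    sub <- freq[cls_of == g, ]
    if (nrow(sub) == 0L) stop("no systems for class ", g, call. = FALSE)
    cgx_by_pair <- tapply(sub$frequency, sub$pair, mean)
    cgx <- as.numeric(cgx_by_pair[model$universe])
    cgx[is.na(cgx)] <- 0
    w <- model$weights[, g]
    df <- data.frame(class = g, pair = model$universe, weight = unname(w),
                     cGx = cgx, wGx = unname(w) * cgx,
                     stringsAsFactors = FALSE)
    ord <- order(-df$wGx, -abs(df$weight), df$pair, method = "radix")
    df$rank <- NA_integer_
    df$rank[ord] <- seq_len(nrow(df))
    df
  }))
  rownames(out) <- NULL
  class(out) <- c("st_scores", "data.frame")
  out
}

#' Extract the spatiotemporal code
#'
#' The top-k (default 10) contact pairs per class by composite wGx score,
#' annotated with the persistence label and, when supplied, whether the pair
#' is present in the starting structure of any system of that class.
#'
#' @param scores an \code{st_scores} from \code{\link{composite_scores}}
#' @param k pairs per class
#' @param persistence optional \code{st_persistence} for label annotation
#' @param in_structure optional named list (class -> character vector of
#'   pair keys seen in the starting structures)
#' @return data.frame (class, rank, pair, wGx, cGx, persistence_label,
#'   in_structure) of class \code{st_code}
#' @export
extract_code <- function(scores, k = 10, persistence = NULL,
                         in_structure = NULL) {
  n_per_class <- table(scores$class)
  if (any(n_per_class < k)) {
    stop("k = ", k, " exceeds the universe size for some class",
         call. = FALSE)
  }
  top <- scores[scores$rank <= k, ]
  top <- top[order(top$class, top$rank), ]
  out <- data.frame(class = top$class, rank = top$rank, pair = top$pair,
                    wGx = top$wGx, cGx = top$cGx,
                    persistence_label = NA_character_,
                    in_structure = NA, stringsAsFactors = FALSE)
  if (!is.null(persistence)) {
    out$persistence_label <-
      persistence$label[match(out$pair, persistence$pair)]
  }
  if (!is.null(in_structure)) {
    out$in_structure <- mapply(function(g, p)
      p %in% (in_structure[[g]] %||% character(0)),
      out$class, out$pair)
  }
  rownames(out) <- NULL
  class(out) <- c("st_code", "data.frame")
  out
}

#' Compare mean values over a position subset and its complement
#'
#' Generic position-subset mean comparison (e.g. population missense-variant
#' frequency at code positions versus all remaining positions).
#'
#' @param values named numeric vector, position -> value
#' @param subset character vector of positions (must be covered by values)
#' @return list(mean_subset, mean_complement (NA when the complement is
#'   empty), n_subset, n_complement)
#' @export
compare_position_subsets <- function(values, subset) {
  if (length(subset) == 0L) stop("empty position subset", call. = FALSE)
  if (!all(subset %in% names(values))) {
    stop("subset position(s) missing from values: ",
         paste(setdiff(subset, names(values)), collapse = ", "),
         call. = FALSE)
  }
  comp <- setdiff(names(values), subset)
  list(mean_subset = mean(values[subset]),
       mean_complement = if (length(comp)) mean(values[comp]) else NA_real_,
       n_subset = length(subset), n_complement = length(comp))
}

#' Serialize / restore a fitted discriminant model as JSON
#' @param model an \code{st_lda}
#' @param path JSON path
#' @export
write_lda_model <- function(model, path) {
  payload <- list(
    classes = model$classes, universe = model$universe,
    scalings = unname(apply(model$scalings, 2L, identity, simplify = FALSE)),
    weights = unname(apply(model$weights, 2L, identity, simplify = FALSE)),
    intercepts = model$intercepts,
    class_means = unname(apply(model$class_means, 1L, identity,
                               simplify = FALSE)),
    xbar = unname(model$xbar),
    explained_variance_ratio = model$explained_variance_ratio,
    prior = model$prior, dropped = model$dropped, solver = model$solver)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_lda_model
#' @export
read_lda_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  uni <- p$universe
  # columns/rows were serialized as lists of vectors; jsonlite simplifies
  # equal-length lists to row-major matrices
  as_cols <- function(x, n_col) {
    if (is.matrix(x)) t(x) else matrix(unlist(x), ncol = n_col)
  }
  scalings <- as_cols(p$scalings, length(p$scalings))
  dimnames(scalings) <- list(uni, paste0("LD", seq_len(ncol(scalings))))
  weights <- as_cols(p$weights, length(p$classes))
  dimnames(weights) <- list(uni, p$classes)
  means <- if (is.matrix(p$class_means)) p$class_means else
    matrix(unlist(p$class_means), ncol = length(uni), byrow = TRUE)
  dimnames(means) <- list(p$classes, uni)
  xbar <- p$xbar; names(xbar) <- uni
  structure(list(classes = p$classes, universe = uni, scalings = scalings,
                 weights = weights, intercepts = p$intercepts,
                 class_means = means, xbar = xbar,
                 explained_variance_ratio = p$explained_variance_ratio,
                 prior = p$prior, dropped = p$dropped, solver = p$solver),
            class = "st_lda")
}
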