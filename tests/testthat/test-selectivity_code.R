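# Discriminant model, composite wGx scoring, code extraction, projection.

# separable variant: class-specific contacts deterministically present in
# their own class, so frame-level class membership is unambiguous
sep_sim <- function(seed = 1, n_frames = 300) {
  generate_fingerprints(planted_spec(n_frames = n_frames, seed = seed,
                                     p_specific_own = 1.0))
}

test_that("a perfectly separating feature gets the largest class weight", {
  set.seed(1)
  n <- 120
  labels <- rep(c("Gs", "Gi", "Gq"), each = n)
  X <- cbind(
    fs = as.integer(labels == "Gs"),
    fi = as.integer(labels == "Gi"),
    fq = as.integer(labels == "Gq"),
    noise1 = rbinom(3 * n, 1, 0.5),
    noise2 = rbinom(3 * n, 1, 0.5))
  # flip a few entries so no feature is constant within a class
  flip <- sample(3 * n, 6)
  X[flip, 1:3] <- 1L - X[flip, 1:3]
  model <- fit_lda(X, labels)
  for (g in c("Gs", "Gi", "Gq")) {
    feat <- c(Gs = "fs", Gi = "fi", Gq = "fq")[[g]]
    w <- model$weights[, g]
    expect_equal(names(which.max(w)), feat)          # own feature dominates
  }
})

test_that("identical classes under different labels separate near zero", {
  set.seed(2)
  n <- 400; p <- 12
  X <- matrix(rbinom(2 * n * p, 1, 0.4), ncol = p,
              dimnames = list(NULL, paste0("f", 1:p)))
  labels <- rep(c("A", "B"), each = n)       # same distribution, two labels
  model <- fit_lda(X, labels)
  # between-class separation: distance of class means in discriminant space
  mu <- model$class_means %*% model$scalings
  sep_null <- abs(mu[1, 1] - mu[2, 1])
  # compare with a genuinely separated dataset of the same size
  X2 <- X; X2[labels == "B", 1] <- rbinom(n, 1, 0.95)
  model2 <- fit_lda(X2, labels)
  mu2 <- model2$class_means %*% model2$scalings
  expect_lt(sep_null, 0.2 * abs(mu2[1, 1] - mu2[2, 1]))
})

test_that("explained variance ratios are a 2-vector summing to 1", {
  sim <- sep_sim(seed = 21, n_frames = 150)
  model <- fit_lda(sim$fingerprints$X, sim$fingerprints$frames$class)
  expect_length(model$explained_variance_ratio, 2L)
  expect_true(all(model$explained_variance_ratio >= 0))
  expect_equal(sum(model$explained_variance_ratio), 1, tolerance = 1e-12)
  expect_equal(ncol(model$scalings), 2L)
})

test_that("components are orthogonal in the within-class-whitened metric", {
  sim <- sep_sim(seed = 22, n_frames = 200)
  X <- sim$fingerprints$X
  labels <- sim$fingerprints$frames$class
  model <- fit_lda(X, labels)
  kept <- setdiff(model$universe, model$dropped)
  S <- model$scalings[kept, ]
  # MASS scalings whiten the within-class covariance: S' W S = I
  Xk <- X[, kept]
  W <- matrix(0, length(kept), length(kept))
  for (g in unique(labels)) {
    xg <- Xk[labels == g, , drop = FALSE]
    W <- W + crossprod(sweep(xg, 2, colMeans(xg)))
  }
  W <- W / (nrow(Xk) - length(unique(labels)))
  gram <- t(S) %*% W %*% S
  expect_equal(gram, diag(2), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("scalings are deterministically signed and duplication-stable", {
  sim <- sep_sim(seed = 23, n_frames = 100)
  X <- sim$fingerprints$X
  labels <- sim$fingerprints$frames$class
  m1 <- fit_lda(X, labels)
  m2 <- fit_lda(X, labels)
  expect_identical(m1$scalings, m2$scalings)
  # first nonzero loading of each component is positive
  for (k in 1:2) {
    col <- m1$scalings[, k]
    expect_gt(col[which(abs(col) > 1e-12)[1]], 0)
  }
  # duplicating every frame leaves the discriminant directions unchanged
  # up to sign (the n - g normalization rescales lengths marginally)
  m3 <- fit_lda(rbind(X, X), c(labels, labels))
  for (k in 1:2) {
    a <- m1$scalings[, k]; b <- m3$scalings[, k]
    cosang <- abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
    expect_equal(cosang, 1, tolerance = 1e-8)
  }
  # and the induced classification is identical
  expect_identical(project_and_classify(m1, X)$predicted,
                   project_and_classify(m3, X)$predicted)
})

test_that("decision rule matches the reference LDA predictions", {
  sim <- sep_sim(seed = 24, n_frames = 150)
  X <- sim$fingerprints$X
  labels <- sim$fingerprints$frames$class
  model <- fit_lda(X, labels)
  ours <- project_and_classify(model, X)$predicted
  kept <- setdiff(model$universe, model$dropped)
  ref <- MASS::lda(X[, kept], grouping = factor(labels))
  theirs <- as.character(predict(ref, X[, kept])$class)
  expect_equal(mean(ours == theirs), 1)
})

test_that("holdout accuracy is perfect on separable planted data", {
  sim <- sep_sim(seed = 31, n_frames = 250)
  acc <- holdout_accuracy(sim$fingerprints$X, sim$fingerprints$frames$class,
                          split = 0.8, seed = 7,
                          systems = sim$fingerprints$frames$system_id)
  expect_equal(as.numeric(acc), 1.0)
  # nearest-class-mean oracle agrees on this well-separated geometry
  X <- sim$fingerprints$X
  labels <- sim$fingerprints$frames$class
  mu <- do.call(rbind, lapply(unique(labels), function(g)
    colMeans(X[labels == g, , drop = FALSE])))
  rownames(mu) <- unique(labels)
  d2 <- sapply(rownames(mu), function(g)
    rowSums(sweep(X, 2, mu[g, ])^2))
  ncm <- rownames(mu)[max.col(-d2, ties.method = "first")]
  expect_equal(mean(ncm == labels), 1.0)
})

test_that("label permutation drops holdout accuracy to chance", {
  sim <- generate_fingerprints(planted_spec(n_frames = 500, seed = 32))
  X <- sim$fingerprints$X                      # 3000 frames
  set.seed(99)
  perm <- sample(sim$fingerprints$frames$class)
  acc <- holdout_accuracy(X, perm, split = 0.8, seed = 5)
  expect_equal(as.numeric(acc), 1 / 3, tolerance = 0.15)
  expect_lt(abs(as.numeric(acc) - 1 / 3), 0.05)
})

test_that("composite scores are weight x mean class frequency", {
  sim <- sep_sim(seed = 41, n_frames = 200)
  fp <- sim$fingerprints
  model <- fit_lda(fp$X, fp$frames$class)
  freq <- contact_frequencies(fp)
  scores <- composite_scores(model, freq, sim$system_class)
  # independent recomputation for a sample of (class, pair) entries
  set.seed(1)
  take <- scores[sample(nrow(scores), 25), ]
  for (i in seq_len(nrow(take))) {
    g <- take$class[i]; p <- take$pair[i]
    systems <- names(sim$system_class)[sim$system_class == g]
    cgx <- mean(freq$frequency[freq$pair == p &
                                 freq$system_id %in% systems])
    expect_equal(take$cGx[i], cgx)
    expect_equal(take$wGx[i], model$weights[p, g] * cgx)
  }
  # zero frequency forces zero composite score
  expect_true(all(scores$wGx[scores$cGx == 0] == 0))
  # ranking equals an oracle sort of recomputed products
  gs <- scores[scores$class == "Gs", ]
  ord <- order(-gs$wGx, -abs(gs$weight), gs$pair)
  expect_equal(gs$rank[ord], seq_len(nrow(gs)))
})

test_that("the code recovers planted specific pairs in the right class", {
  sim <- sep_sim(seed = 51, n_frames = 400)
  fp <- sim$fingerprints
  model <- fit_lda(fp$X, fp$frames$class)
  freq <- contact_frequencies(fp)
  scores <- composite_scores(model, freq, sim$system_class)
  pers <- classify_persistence(freq, sim$system_class)
  code <- extract_code(scores, k = 10, persistence = pers)
  expect_equal(as.integer(table(code$class)), rep(10L, 3L))
  for (g in c("Gs", "Gi", "Gq")) {
    planted <- sim$truth$pair[sim$truth$role == "specific" &
                                sim$truth$class == g]
    expect_true(all(planted %in% code$pair[code$class == g]))
  }
  expect_error(extract_code(scores, k = 10000), "exceeds the universe")
})

test_that("projection maps all-zero fingerprints to a single point", {
  sim <- sep_sim(seed = 61, n_frames = 100)
  model <- fit_lda(sim$fingerprints$X, sim$fingerprints$frames$class)
  Z <- matrix(0L, nrow = 5, ncol = length(model$universe),
              dimnames = list(NULL, model$universe))
  proj <- project_and_classify(model, Z, target_class = "Gs")
  expect_equal(length(unique(proj$component1)), 1L)
  expect_equal(length(unique(proj$component2)), 1L)
  expect_true(attr(proj, "accuracy") %in% c(0, 1))
  # training frames of class Gs projected with target Gs are all correct
  gs_rows <- sim$fingerprints$frames$class == "Gs"
  pr <- project_and_classify(model, sim$fingerprints$X[gs_rows, ],
                             target_class = "Gs")
  expect_equal(attr(pr, "accuracy"), 1.0)
})

test_that("universe alignment imputes missing pairs and drops novel ones", {
  sim <- sep_sim(seed = 62, n_frames = 100)
  model <- fit_lda(sim$fingerprints$X, sim$fingerprints$frames$class)
  X <- sim$fingerprints$X[1:10, ]
  Xext <- cbind(X[, -(1:3)], novel1 = 1L, novel2 = 0L)
  proj <- project_and_classify(model, Xext)
  expect_equal(attr(proj, "n_missing"), 3L)
  expect_equal(attr(proj, "n_dropped"), 2L)
})

test_that("model JSON round-trips exactly", {
  sim <- sep_sim(seed = 63, n_frames = 80)
  model <- fit_lda(sim$fingerprints$X, sim$fingerprints$frames$class)
  path <- tempfile(fileext = ".json")
  write_lda_model(model, path)
  back <- read_lda_model(path)
  expect_equal(back$scalings, model$scalings)
  expect_equal(back$weights, model$weights)
  expect_equal(back$explained_variance_ratio,
               model$explained_variance_ratio)
  p1 <- project_and_classify(model, sim$fingerprints$X[1:5, ])
  p2 <- project_and_classify(back, sim$fingerprints$X[1:5, ])
  expect_equal(p1$predicted, p2$predicted)
  expect_equal(p1$component1, p2$component1)
})

test_that("degenerate inputs raise model errors", {
  X <- matrix(rbinom(100, 1, 0.5), ncol = 5,
              dimnames = list(NULL, paste0("f", 1:5)))
  expect_error(fit_lda(X, rep("Gs", 20)), "at least two classes")
  Xc <- matrix(1L, nrow = 20, ncol = 3,
               dimnames = list(NULL, paste0("f", 1:3)))
  expect_error(fit_lda(Xc, rep(c("Gs", "Gi"), each = 10)),
               "constant within classes")
})

test_that("position-subset means match direct computation", {
  vals <- c(a = 1, b = 3)
  res <- compare_position_subsets(vals, "a")
  expect_equal(res$mean_subset, 1)
  expect_equal(res$mean_complement, 3)
  res_all <- compare_position_subsets(vals, c("a", "b"))
  expect_true(is.na(res_all$mean_complement))
  set.seed(8)
  vals2 <- stats::setNames(runif(100), paste0("p", 1:100))
  sub <- paste0("p", sample(100, 17))
  res2 <- compare_position_subsets(vals2, sub)
  expect_equal(res2$mean_subset, mean(vals2[sub]))
  expect_equal(res2$mean_complement,
               mean(vals2[setdiff(names(vals2), sub)]))
  expect_error(compare_position_subsets(vals2, character(0)), "empty")
})
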