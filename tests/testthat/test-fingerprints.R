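# Fingerprint encoding, frequencies, persistence taxonomy, SSE composition.

make_timeline <- function(events, system_id, n_frames) {
  df <- data.frame(frame_id = events$frame_id,
                   gpcr_residue = paste0("R:", 1),
                   gprot_residue = paste0("A:", 1),
                   gpcr_generic = events$gpcr,
                   gprot_generic = events$gprot,
                   contact_type = events$type %||% "SB",
                   stringsAsFactors = FALSE)
  stcontacts:::new_timeline(df, system_id = system_id, n_frames = n_frames)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("pair universe is the resolved-region-filtered sorted union", {
  t1 <- make_timeline(data.frame(frame_id = 0L,
                                 gpcr = c("3x50", "3x51"),
                                 gprot = "G.H5.16"), "s1", 2L)
  t2 <- make_timeline(data.frame(frame_id = 0L,
                                 gpcr = c("3x51", "34x57"),
                                 gprot = "G.H5.16"), "s2", 2L)
  uni <- build_pair_universe(list(t1, t2))
  expect_equal(uni, sort(c("3x50:G.H5.16", "3x51:G.H5.16",
                           "34x57:G.H5.16")))
  # 34x57 unresolved in s1 -> its pair is excluded
  uni2 <- build_pair_universe(list(t1, t2), resolved_regions = list(
    s1 = c("3x50", "3x51"), s2 = c("3x50", "3x51", "34x57")))
  expect_equal(uni2, c("3x50:G.H5.16", "3x51:G.H5.16"))
})

test_that("encoding collapses contact types to pair-level binaries", {
  tl <- make_timeline(data.frame(frame_id = c(0L, 0L, 2L),
                                 gpcr = "3x50", gprot = "G.H5.16",
                                 type = c("SB", "VDW", "HB")), "s1", 4L)
  uni <- c("3x50:G.H5.16", "3x50:G.H5.17")
  m <- encode_fingerprints(tl, uni)
  expect_equal(unname(m[, 1]), c(1L, 0L, 1L, 0L))   # types collapsed
  expect_equal(unname(m[, 2]), rep(0L, 4))

  empty <- stcontacts:::new_timeline(
    as.data.frame(tl)[0, ], system_id = "s0", n_frames = 5L)
  expect_equal(dim(encode_fingerprints(empty, uni)), c(5L, 2L))
  expect_true(all(encode_fingerprints(empty, uni) == 0L))
})

test_that("frequencies are exact per-system column means", {
  tl <- make_timeline(data.frame(frame_id = c(0L, 2L), gpcr = "3x50",
                                 gprot = "G.H5.16"), "s1", 4L)
  uni <- "3x50:G.H5.16"
  fp <- fingerprint_set(list(s1 = encode_fingerprints(tl, uni)),
                        c(s1 = "Gs"))
  expect_equal(contact_frequencies(fp)$frequency, 0.5)

  # randomized block equals a brute-force per-frame recount
  sim <- generate_fingerprints(planted_spec(n_frames = 60, seed = 3))
  freq <- contact_frequencies(sim$fingerprints)
  s <- "Gi_sys1"
  block <- sim$fingerprints$X[sim$fingerprints$frames$system_id == s, ]
  manual <- vapply(seq_len(ncol(block)),
                   function(j) sum(block[, j] == 1L) / nrow(block), 0)
  expect_equal(freq$frequency[freq$system_id == s], manual)
})

persist_fixture <- function(freqs) {
  # freqs: named list system -> named numeric of pair frequencies
  do.call(rbind, lapply(names(freqs), function(s)
    data.frame(system_id = s, pair = names(freqs[[s]]),
               frequency = unname(freqs[[s]]), stringsAsFactors = FALSE)))
}

test_that("persistence labels follow the >20 percent one-or-more rule", {
  sys_cls <- c(gs1 = "Gs", gs2 = "Gs", gi1 = "Gi", gq1 = "Gq")
  base <- c(p1 = 0.10, p2 = 0.25)
  freq <- persist_fixture(list(
    gs1 = c(p1 = 0.30, p2 = 0.25), gs2 = c(p1 = 0.05, p2 = 0.10),
    gi1 = c(p1 = 0.20, p2 = 0.25), gq1 = c(p1 = 0.10, p2 = 0.25)))
  lab <- classify_persistence(freq, sys_cls)
  # 0.30 in one Gs system, <= 0.20 elsewhere -> specific-Gs (0.20 is not > 0.20)
  expect_equal(lab$label[lab$pair == "p1"], "specific-Gs")
  # > 0.20 in at least one system of every class -> common
  expect_equal(lab$label[lab$pair == "p2"], "common")
})

test_that("persistence labels partition the universe", {
  sim <- generate_fingerprints(planted_spec(n_frames = 120, seed = 5))
  freq <- contact_frequencies(sim$fingerprints)
  lab <- classify_persistence(freq, sim$system_class)
  expect_setequal(lab$pair, sim$truth$pair)
  expect_equal(anyDuplicated(lab$pair), 0L)
  expect_true(all(lab$label %in% c("common", "other",
                                   paste0("specific-", c("Gs", "Gi", "Gq")))))
  # label consistency with persistent_in
  n_in <- lengths(strsplit(lab$persistent_in, ","))
  n_in[lab$persistent_in == ""] <- 0L
  expect_true(all((lab$label == "common") == (n_in == 3L)))
  expect_true(all(grepl("^specific", lab$label) == (n_in == 1L)))
})

test_that("raising the threshold never grows a persistent-in set", {
  sim <- generate_fingerprints(planted_spec(n_frames = 150, seed = 9))
  freq <- contact_frequencies(sim$fingerprints)
  lab_lo <- classify_persistence(freq, sim$system_class, threshold = 0.2)
  lab_hi <- classify_persistence(freq, sim$system_class, threshold = 0.4)
  in_lo <- strsplit(lab_lo$persistent_in, ",")
  in_hi <- strsplit(lab_hi$persistent_in, ",")
  expect_true(all(mapply(function(h, l) all(h %in% l), in_hi, in_lo)))
})

test_that("planted persistence labels are recovered at defaults", {
  sim <- generate_fingerprints(planted_spec(seed = 42))  # 500 frames/system
  freq <- contact_frequencies(sim$fingerprints)
  lab <- classify_persistence(freq, sim$system_class)
  truth <- sim$truth
  expected <- ifelse(truth$role == "common", "common",
              ifelse(truth$role == "specific",
                     paste0("specific-", truth$class), "other"))
  got <- lab$label[match(truth$pair, lab$pair)]
  expect_equal(got, expected)
})

test_that("SSE composition percentages sum to 100 and round half-up", {
  map <- stcontacts:::as_numbering_map(data.frame(
    chain = "R", resnum = 1:3, generic = c("5x61", "5x62", "34x51"),
    sse = c("TM5", "TM5", "ICL2"), side = "GPCR",
    stringsAsFactors = FALSE))
  pairs <- c("5x61:G.H5.16", "5x62:G.H5.16", "5x61:G.H5.17",
             "5x62:G.H5.17")
  comp <- sse_composition(pairs, map, side = "GPCR")
  expect_equal(comp$percent[comp$sse == "TM5"], 100)

  pairs2 <- c("5x61:G.H5.16", "5x62:G.H5.16", "34x51:G.H5.16")
  comp2 <- sse_composition(pairs2, map, side = "GPCR")
  expect_equal(sum(comp2$percent), 100, tolerance = 0.1)
  expect_equal(comp2$percent[comp2$sse == "TM5"], 66.7)  # half-up 1 decimal
  expect_error(sse_composition("9x99:G.H5.16", map, "GPCR"),
               "without SSE annotation")
})

test_that("subset mean frequency equals the plain arithmetic mean", {
  freq <- persist_fixture(list(s1 = c(a = 0.4, b = 0.6, c = 0.9)))
  expect_equal(mean_frequency_over_subset(freq, "s1", c("a", "b")), 0.5)
  expect_equal(mean_frequency_over_subset(freq, "s1", "c"), 0.9)
  expect_error(mean_frequency_over_subset(freq, "s1", "zz"),
               "no members")
  # randomized check against an independent mean
  sim <- generate_fingerprints(planted_spec(n_frames = 80, seed = 13))
  freq2 <- contact_frequencies(sim$fingerprints)
  subset <- sim$truth$pair[sim$truth$role == "common"]
  s <- "Gq_sys2"
  manual <- mean(freq2$frequency[freq2$system_id == s &
                                   freq2$pair %in% subset])
  expect_equal(mean_frequency_over_subset(freq2, s, subset), manual)
})
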