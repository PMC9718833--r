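# End-to-end orchestration: detect -> fingerprint -> frequencies ->
# persistence -> discriminant model -> spatiotemporal code, from a single
# config (R list or YAML file), with a manifest recording seeds, criteria
# and counts at each stage.

#' Run the contact-analysis pipeline
#'
#' The config lists the systems (each with a system_id, G protein class,
#' topology path, trajectory path(s), optional half-open frame window and
#' numbering-map path) plus analysis parameters. All stage outputs are
#' written under \code{out_dir} as plain-text files and a manifest is
#' returned (and written as JSON).
#'
#' Config fields: \code{systems} (list of lists: system_id, class, topology,
#' trajectory (vector of paths), window (optional c(start, end)), map,
#' chain_gpcr, chain_gprot), \code{threshold} (persistence, default 0.2),
#' \code{k} (code size, default 10), \code{split} (holdout fraction, default
#' 0.8), \code{seed}, \code{out_dir}, and optional \code{criteria} overrides
#' (named list passed to \code{\link{contact_criteria}}).
#'
#' @param config R list or path to a YAML file with the fields above
#' @return the run manifest (list), invisibly written to
#'   \code{out_dir/manifest.json}
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- validate_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  criteria <- do.call(contact_criteria, cfg$criteria %||% list())
  log_msg <- function(...) message("[stcontacts] ", ...)

  timelines <- list(); system_class <- character(0); maps <- list()
  for (sys in cfg$systems) {
    log_msg("detecting contacts: ", sys$system_id)
    topo <- read_topology(sys$topology,
                          chain_gpcr = sys$chain_gpcr %||% "R",
                          chain_gprot = sys$chain_gprot %||% "A")
    traj <- read_trajectory(unlist(sys$trajectory), topo,
                            frame_range = sys$window,
                            system_id = sys$system_id)
    map <- read_numbering_map(sys$map)
    tl <- detect_contacts(traj, map, criteria)
    write_timeline(tl, file.path(cfg$out_dir,
                                 paste0("timeline_", sys$system_id, ".tsv")))
    timelines[[sys$system_id]] <- tl
    system_class[sys$system_id] <- sys$class
    maps[[sys$system_id]] <- map
  }

  universe <- build_pair_universe(timelines)
  blocks <- lapply(timelines, encode_fingerprints, pair_universe = universe)
  fp <- fingerprint_set(blocks, system_class)
  for (sid in names(blocks)) {
    write_fingerprints(blocks[[sid]],
                       file.path(cfg$out_dir,
                                 paste0("fingerprints_", sid, ".tsv")))
  }
  freq <- contact_frequencies(fp)
  write_frequency_table(freq, file.path(cfg$out_dir, "frequencies.tsv"))

  persistence <- classify_persistence(freq, system_class,
                                      threshold = cfg$threshold)
  utils::write.table(persistence, file.path(cfg$out_dir, "persistence.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  log_msg("fitting discriminant model on ", nrow(fp$X), " frames x ",
          ncol(fp$X), " pairs")
  model <- fit_lda(fp$X, fp$frames$class)
  write_lda_model(model, file.path(cfg$out_dir, "model.json"))
  acc <- holdout_accuracy(fp$X, fp$frames$class, split = cfg$split,
                          seed = cfg$seed, systems = fp$frames$system_id)

  scores <- composite_scores(model, freq, system_class)
  utils::write.table(scores, file.path(cfg$out_dir, "scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  k <- min(cfg$k, length(universe))
  code <- extract_code(scores, k = k, persistence = persistence)
  utils::write.table(code, file.path(cfg$out_dir, "code.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("stcontacts")),
    seed = cfg$seed, threshold = cfg$threshold, k = k, split = cfg$split,
    criteria = unclass(criteria)[setdiff(names(criteria), "vdw_radii")],
    systems = lapply(cfg$systems, function(s)
      list(system_id = s$system_id, class = s$class,
           n_frames = attr(timelines[[s$system_id]], "n_frames"),
           n_events = nrow(timelines[[s$system_id]]),
           n_unmapped_residues = attr(timelines[[s$system_id]],
                                      "n_unmapped"),
           hbond_mode = attr(timelines[[s$system_id]], "hbond_mode"))),
    n_pairs_universe = length(universe),
    n_frames_total = nrow(fp$X),
    persistence_counts = as.list(table(persistence$label)),
    explained_variance_ratio = model$explained_variance_ratio,
    holdout_accuracy = as.numeric(acc),
    artifacts = c("timelines per system", "fingerprints per system",
                  "frequencies.tsv", "persistence.tsv", "model.json",
                  "scores.tsv", "code.tsv"))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

validate_config <- function(config) {
  if (is.null(config$systems) || length(config$systems) < 1L) {
    stop("config must list at least one system", call. = FALSE)
  }
  classes <- unique(vapply(config$systems, function(s)
    s$class %||% stop("system without class", call. = FALSE), ""))
  if (length(classes) < 2L) {
    stop("code derivation needs systems from at least two G protein classes",
         call. = FALSE)
  }
  for (sys in config$systems) {
    for (fld in c("system_id", "topology", "trajectory", "map")) {
      if (is.null(sys[[fld]])) {
        stop("system missing field '", fld, "'", call. = FALSE)
      }
    }
    for (p in c(sys$topology, unlist(sys$trajectory), sys$map)) {
      if (!file.exists(p)) stop("missing input file: ", p, call. = FALSE)
    }
  }
  config$threshold <- config$threshold %||% 0.2
  config$k <- config$k %||% 10L
  config$split <- config$split %||% 0.8
  config$seed <- config$seed %||% 1L
  config$out_dir <- config$out_dir %||% "stcontacts_run"
  config
}
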