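# Configuration-driven orchestration: simulate -> preprocess -> analyze ->
# report, with a machine-readable manifest and per-stage substream seeds.

default_config <- function() {
  list(
    paradigm = "exp1", day = 3L, n_neurons = 30L, n_blocks = 6L,
    class_probs = list(identity = 0.35, valence = 0.25, vigor = 0.15,
                       silent = 0.25),
    amp_scale = 0.3, noise_sd = 0.1, learning_rate = 0.05,
    n_shuffles = 100L, n_clusters = 6L, pr_k = 15L, pr_resamples = 100L,
    seed = 1L,
    stages = c("simulate", "preprocess", "analyze", "report")
  )
}

#' Validate a pipeline configuration
#'
#' Checks a configuration list (or YAML file) against the pipeline schema
#' before any computation: known field names, correct types, and value
#' ranges. Unknown fields and out-of-range values abort with a named
#' error.
#'
#' @param config A named list or path to a YAML file.
#' @return The validated, default-filled configuration list.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  def <- default_config()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown)) {
    abort(sprintf("unknown config field(s): %s", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(def, config)
  if (!cfg$paradigm %in% c("exp1", "exp2")) abort("config: paradigm must be exp1 or exp2")
  if (cfg$n_neurons < 1) abort("config: n_neurons must be >= 1")
  if (cfg$n_blocks < 1) abort("config: n_blocks must be >= 1")
  if (cfg$n_shuffles < 0) abort("config: n_shuffles must be >= 0")
  bad <- setdiff(cfg$stages, c("simulate", "preprocess", "analyze", "report"))
  if (length(bad)) abort(sprintf("config: unknown stage(s): %s", paste(bad, collapse = ", ")))
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

require_stage_output <- function(path, stage, needed_by) {
  if (!file.exists(path)) {
    abort(sprintf("stage '%s' requires output of stage '%s' (missing: %s)",
                  needed_by, stage, path))
  }
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages into an output directory:
#'
#' * `simulate` -- generate a synthetic session and write its container,
#' * `preprocess` -- moving-baseline dF/F, written as `dff.csv`,
#' * `analyze` -- responsiveness, single-neuron auROC + quadrants,
#'   population decoding and generalization, distance trajectories,
#'   participation ratio, response-profile clusters, behavior metrics and
#'   decoupling regressions, all as CSV,
#' * `report` -- summary tables mirroring the analysis panels.
#'
#' Later stages fail fast with a named dependency error when an earlier
#' stage's outputs are absent, which makes partial runs resumable
#' stage-by-stage. A `manifest.json` records the configuration, derived
#' seeds, package version, and the MD5 hash of every output file; the same
#' configuration and seed reproduce identical manifests.
#'
#' @param config Configuration list or YAML path (see [validate_config()]).
#' @param out_dir Output directory.
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  cfg <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
  session_dir <- file.path(out_dir, "session")
  dff_path <- file.path(out_dir, "dff.csv")
  analysis_dir <- file.path(out_dir, "analysis")
  report_dir <- file.path(out_dir, "report")

  if ("simulate" %in% cfg$stages) {
    session <- simulate_session(
      n_neurons = cfg$n_neurons, paradigm = cfg$paradigm, day = cfg$day,
      n_blocks = cfg$n_blocks, seed = cfg$seed,
      class_probs = unlist(cfg$class_probs), amp_scale = cfg$amp_scale,
      noise_sd = cfg$noise_sd, learning_rate = cfg$learning_rate
    )
    write_session(session, session_dir, overwrite = TRUE)
  }

  if ("preprocess" %in% cfg$stages) {
    require_stage_output(file.path(session_dir, "session.json"),
                         "simulate", "preprocess")
    session <- read_session(session_dir)
    dff <- session_dff(session)
    write.csv(as.data.frame(dff), dff_path, row.names = FALSE)
  }

  if ("analyze" %in% cfg$stages) {
    require_stage_output(dff_path, "preprocess", "analyze")
    require_stage_output(file.path(session_dir, "session.json"),
                         "simulate", "analyze")
    session <- read_session(session_dir)
    dff <- as.matrix(read.csv(dff_path))
    dimnames(dff) <- NULL
    attr(dff, "frame_times") <- session$frame_times
    dir.create(analysis_dir, showWarnings = FALSE)
    run_analysis(dff, session, cfg, analysis_dir)
  }

  if ("report" %in% cfg$stages) {
    require_stage_output(file.path(analysis_dir, "quadrants.csv"),
                         "analyze", "report")
    dir.create(report_dir, showWarnings = FALSE)
    write_report(analysis_dir, report_dir)
  }

  manifest <- build_manifest(out_dir, cfg)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

run_analysis <- function(dff, session, cfg, analysis_dir) {
  trials <- session$trials
  scheme <- session$scheme
  tensor <- align_trials(dff, trials, pre_s = 2, post_s = 8)
  seed_an <- derive_seed(cfg$seed, "analyze")
  role <- setNames(scheme$role, scheme$odor)

  resp <- responsiveness_table(tensor)
  write.csv(resp, file.path(analysis_dir, "responsiveness.csv"), row.names = FALSE)

  aur <- auroc_table(tensor, n_shuffles = cfg$n_shuffles, seed = seed_an)
  write.csv(aur, file.path(analysis_dir, "auroc.csv"), row.names = FALSE)

  # quadrant categorization from the paradigm's inter/intra-valence pairs
  v <- odor_value(scheme)
  hi <- names(v)[v == max(v)]
  lo <- names(v)[v == min(v)]
  inter_pair <- c(hi[1], lo[1])
  intra_pair <- c(hi[1], hi[2])
  pick <- function(p) {
    aur |>
      dplyr::filter((.data$odor_1 == p[1] & .data$odor_2 == p[2]) |
                    (.data$odor_1 == p[2] & .data$odor_2 == p[1])) |>
      dplyr::arrange(.data$neuron) |>
      dplyr::pull(.data$auroc)
  }
  quad <- quadrant_classify(pick(inter_pair), pick(intra_pair))
  quad$neuron <- sort(unique(aur$neuron))
  write.csv(quad, file.path(analysis_dir, "quadrants.csv"), row.names = FALSE)

  dist_tr <- distance_trajectories(tensor)
  write.csv(dist_tr, file.path(analysis_dir, "distance.csv"), row.names = FALSE)

  gen <- generalization_matrix(tensor, seed = seed_an)
  write.csv(gen, file.path(analysis_dir, "generalization.csv"), row.names = FALSE)

  k <- min(cfg$pr_k, nrow(dff))
  pr <- subsampled_pr(tensor_samples(tensor), k = k,
                      n_resamples = cfg$pr_resamples, seed = seed_an)
  write.csv(glance(pr), file.path(analysis_dir, "pr.csv"), row.names = FALSE)

  post_s <- 3
  feats <- build_cluster_features(align_trials(dff, trials, 2, post_s))
  ncl <- min(cfg$n_clusters, nrow(feats) - 1)
  cl <- cluster_profiles(feats, n_clusters = ncl)
  write.csv(cl, file.path(analysis_dir, "clusters.csv"), row.names = FALSE)

  lw <- if (cfg$paradigm == "exp1") c(0, 2) else c(1.5, 2.5)
  lm_out <- lick_metrics(session$behavior, trials, window = lw)
  write.csv(lm_out$per_trial, file.path(analysis_dir, "behavior.csv"),
            row.names = FALSE)

  amp <- window_features(tensor, c(1, 2)) -
    window_features(tensor, c(-2, 0))
  licks <- anticipatory_licks(session$behavior, trials, lw)$licks
  ps <- odor_value(scheme)[trials$odor]
  if (var(ps) > 0 && var(licks) > 0) {
    dec <- delta_r2_decoupling(amp, ps, licks)
    write.csv(dec, file.path(analysis_dir, "decoupling.csv"), row.names = FALSE)
  }
  invisible(NULL)
}

#' Write summary report tables from a completed analysis
#'
#' Regenerates the report purely from the analysis CSVs (no hidden state),
#' so rebuilding a report from the same bundle is byte-identical.
#'
#' @param analysis_dir Directory written by the `analyze` stage.
#' @param report_dir Output directory for the summary tables.
#' @return `report_dir`, invisibly.
#' @export
write_report <- function(analysis_dir, report_dir) {
  need <- c("responsiveness.csv", "quadrants.csv", "generalization.csv", "pr.csv")
  for (f in need) {
    require_stage_output(file.path(analysis_dir, f), "analyze", "report")
  }
  dir.create(report_dir, showWarnings = FALSE, recursive = TRUE)

  resp <- read.csv(file.path(analysis_dir, "responsiveness.csv"))
  pct <- resp |>
    dplyr::group_by(.data$odor) |>
    dplyr::summarise(
      pct_responsive = 100 * mean(.data$responsive),
      pct_excited = 100 * mean(.data$responsive & .data$direction == "excited"),
      pct_inhibited = 100 * mean(.data$responsive & .data$direction == "inhibited"),
      .groups = "drop"
    )
  write.csv(pct, file.path(report_dir, "percent_responsive.csv"), row.names = FALSE)

  quad <- read.csv(file.path(analysis_dir, "quadrants.csv"))
  qf <- quad |>
    dplyr::count(.data$category, name = "n") |>
    dplyr::mutate(fraction = .data$n / sum(.data$n))
  write.csv(qf, file.path(report_dir, "quadrant_fractions.csv"), row.names = FALSE)

  gen <- read.csv(file.path(analysis_dir, "generalization.csv"))
  write.csv(gen, file.path(report_dir, "generalization_15x15.csv"), row.names = FALSE)

  file.copy(file.path(analysis_dir, "pr.csv"),
            file.path(report_dir, "pr.csv"), overwrite = TRUE)
  if (file.exists(file.path(analysis_dir, "decoupling.csv"))) {
    file.copy(file.path(analysis_dir, "decoupling.csv"),
              file.path(report_dir, "decoupling_scatter.csv"), overwrite = TRUE)
  }
  invisible(report_dir)
}

build_manifest <- function(out_dir, cfg) {
  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[!basename(files) %in% "manifest.json"]
  rel <- sub(paste0("^", out_dir, "/?"), "", files)
  hashes <- unname(tools::md5sum(files))
  list(
    package = "odorvalence",
    version = as.character(utils::packageVersion("odorvalence")),
    config = cfg,
    derived_seeds = list(
      trials = derive_seed(cfg$seed, "trials"),
      behavior = derive_seed(cfg$seed, "behavior"),
      truth = derive_seed(cfg$seed, "truth"),
      population = derive_seed(cfg$seed, "population"),
      calcium = derive_seed(cfg$seed, "calcium"),
      analyze = derive_seed(cfg$seed, "analyze")
    ),
    files = purrr::map2(rel, hashes, function(f, h) list(file = f, md5 = h))
  )
}
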