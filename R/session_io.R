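# Plain-text session container.
#
# A session is persisted as one directory with a fixed group layout:
#   fluorescence.csv        neurons x frames raw fluorescence
#   behavior_frames.csv     per-frame behavior channels
#   behavior_licks.csv      lick event timestamps
#   trials.csv              trial metadata table
#   truth.csv               ground-truth encoding parameters (if present)
#   session.json            scalars: frame_rate, seed, paradigm, day

#' Write a simulated session to a plain-text container directory
#'
#' @param session A [simulate_session()] object.
#' @param path Directory to create (must not already contain a session
#'   unless `overwrite = TRUE`).
#' @param overwrite Replace an existing container.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path, overwrite = FALSE) {
  stopifnot(inherits(session, "simulated_session"))
  if (dir.exists(path) && file.exists(file.path(path, "session.json")) && !overwrite) {
    abort(sprintf("session container already exists at '%s'", path))
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write.csv(as.data.frame(session$fluorescence),
            file.path(path, "fluorescence.csv"), row.names = FALSE)
  b <- session$behavior
  frames <- data.frame(
    time = b$frame_times, lick_count = b$lick_count, lick_state = b$lick_state,
    locomotion = b$locomotion, eye_area = b$eye_area, spout_in = b$spout_in,
    tongue_conf = b$face_features[, 1], mouth_conf = b$face_features[, 2],
    lip_dist = b$face_features[, 3]
  )
  write.csv(frames, file.path(path, "behavior_frames.csv"), row.names = FALSE)
  write.csv(data.frame(time = b$lick_times),
            file.path(path, "behavior_licks.csv"), row.names = FALSE)
  write.csv(as.data.frame(session$trials), file.path(path, "trials.csv"),
            row.names = FALSE)
  tr <- as.data.frame(session$truth)
  wid <- do.call(rbind, tr$w_identity)
  colnames(wid) <- paste0("w_identity_", session$scheme$odor)
  tr$w_identity <- NULL
  write.csv(cbind(tr, wid), file.path(path, "truth.csv"), row.names = FALSE)
  meta <- list(
    frame_rate = session$frame_rate, seed = session$seed,
    paradigm = attr(session$trials, "paradigm"),
    day = attr(session$scheme, "day"),
    n_neurons = nrow(session$fluorescence),
    n_trials = nrow(session$trials)
  )
  jsonlite::write_json(meta, file.path(path, "session.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a session container written by [write_session()]
#'
#' @param path Container directory.
#' @return A `simulated_session`-like list (without the amplitude matrix,
#'   which is a simulator intermediate).
#' @export
read_session <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "session.json"))
  fluo <- as.matrix(read.csv(file.path(path, "fluorescence.csv")))
  dimnames(fluo) <- NULL
  frames <- read.csv(file.path(path, "behavior_frames.csv"))
  licks <- read.csv(file.path(path, "behavior_licks.csv"))
  scheme <- make_odor_scheme(meta$paradigm, day = meta$day)
  trials <- as_tibble(read.csv(file.path(path, "trials.csv")))
  trials <- structure(trials, class = c("trial_table", class(trials)),
                      paradigm = meta$paradigm, scheme = scheme)
  truth_df <- read.csv(file.path(path, "truth.csv"))
  wid_cols <- grep("^w_identity_", names(truth_df))
  truth <- as_tibble(truth_df[-wid_cols])
  truth$w_identity <- lapply(seq_len(nrow(truth_df)),
                             function(i) unname(unlist(truth_df[i, wid_cols])))
  truth <- structure(truth, class = c("ground_truth", class(truth)))
  behavior <- structure(list(
    lick_times = licks$time, frame_times = frames$time,
    lick_count = frames$lick_count, lick_state = frames$lick_state,
    locomotion = frames$locomotion, eye_area = frames$eye_area,
    face_features = as.matrix(frames[c("tongue_conf", "mouth_conf", "lip_dist")]),
    spout_in = frames$spout_in, frame_rate = meta$frame_rate
  ), class = "behavior_trace")
  ft <- frames$time
  structure(
    list(
      fluorescence = structure(fluo, frame_times = ft, frame_rate = meta$frame_rate),
      frame_times = ft, behavior = behavior, trials = trials, scheme = scheme,
      truth = truth, frame_rate = meta$frame_rate, seed = meta$seed
    ),
    class = "simulated_session"
  )
}
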