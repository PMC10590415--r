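#' Write a synthetic session to plain-text files
#'
#' Writes `trials.csv` (one row per trial), `spikes.csv` (long format:
#' `unit`, `trial`, `time` in seconds, stimulus onset at 0), `speed.csv`
#' (trials x timepoints, with the time axis as header), `ground_truth.json`,
#' and — when video frames exist — `frames.tif` (multi-frame 8-bit grayscale
#' at the configured frame rate).
#'
#' @param session a [SyntheticSession-class].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeSession <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(session@trials, file.path(dir, "trials.csv"),
                   row.names = FALSE)
  sp <- session@spikes
  long <- do.call(rbind, lapply(seq_along(sp), function(u)
    do.call(rbind, lapply(seq_along(sp[[u]]), function(tr)
      if (length(sp[[u]][[tr]]))
        data.frame(unit = u, trial = tr, time = sp[[u]][[tr]])
      else NULL))))
  utils::write.csv(long, file.path(dir, "spikes.csv"), row.names = FALSE)
  spd <- as.data.frame(session@speed)
  names(spd) <- sprintf("t%g", session@speedTime)
  utils::write.csv(spd, file.path(dir, "speed.csv"), row.names = FALSE)
  gt <- session@groundTruth
  gt$amplitudes <- as.list(gt$amplitudes)  # keep names through JSON
  gt$variables <- as.list(gt$variables)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  if (length(session@frames)) {
    fr <- lapply(seq_len(dim(session@frames)[3]),
                 function(i) session@frames[, , i] / 255)
    tiff::writeTIFF(fr, file.path(dir, "frames.tif"), bits.per.sample = 8L)
  }
  invisible(dir)
}

#' Read a session directory written by [writeSession()]
#'
#' @param dir session directory.
#' @return list with `trials`, `spikes` (unit-major list of lists), `speed`,
#'   `speedTime`, `frames` (or NULL) and `groundTruth`.
#' @export
readSession <- function(dir) {
  trials <- utils::read.csv(file.path(dir, "trials.csv"),
                            stringsAsFactors = FALSE)
  trials$visual_stim <- as.character(trials$visual_stim)
  long <- utils::read.csv(file.path(dir, "spikes.csv"))
  nU <- max(long$unit); nTr <- nrow(trials)
  spikes <- rep(list(rep(list(numeric(0)), nTr)), nU)
  for (u in seq_len(nU)) {
    lu <- long[long$unit == u, ]
    for (tr in unique(lu$trial))
      spikes[[u]][[tr]] <- sort(lu$time[lu$trial == tr])
  }
  spd <- as.matrix(utils::read.csv(file.path(dir, "speed.csv"),
                                   check.names = FALSE))
  speedTime <- as.numeric(sub("^t", "", colnames(spd)))
  frames <- NULL
  fp <- file.path(dir, "frames.tif")
  if (file.exists(fp)) {
    fr <- tiff::readTIFF(fp, all = TRUE)
    first <- if (is.matrix(fr[[1]])) fr[[1]] else fr[[1]][, , 1]
    frames <- array(0, dim = c(dim(first), length(fr)))
    for (i in seq_along(fr)) {
      m <- if (is.matrix(fr[[i]])) fr[[i]] else fr[[i]][, , 1]
      frames[, , i] <- round(m * 255)
    }
  }
  list(trials = trials, spikes = spikes, speed = unname(spd),
       speedTime = speedTime,
       frames = frames,
       groundTruth = jsonlite::read_json(file.path(dir, "ground_truth.json"),
                                         simplifyVector = TRUE))
}
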