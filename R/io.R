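# on-disk session container: flat binary LFP + JSON sidecar, CSV tables,
# JSON ground truth. Time convention: seconds from session start, half-open
# intervals [start, end).

#' Validate an epoch table
#'
#' Checks column presence, positive durations, and that epochs within each
#' trial (and the trial-less optostim block) do not overlap.
#'
#' @param epochs Epoch table data frame.
#' @return Invisibly `TRUE`; stops with the offending trial named otherwise.
#' @export
validate_epoch_table <- function(epochs) {
  need <- c("trial", "label", "t_start_s", "t_end_s")
  if (!all(need %in% names(epochs))) {
    stop("epoch table must have columns ", paste(need, collapse = ", "))
  }
  if (any(epochs$t_end_s <= epochs$t_start_s)) {
    stop("all epoch durations must be positive")
  }
  grp <- ifelse(is.na(epochs$trial), "optostim-block", epochs$trial)
  for (g in unique(grp)) {
    e <- epochs[grp == g, , drop = FALSE]
    e <- e[order(e$t_start_s), , drop = FALSE]
    if (nrow(e) > 1 && any(e$t_start_s[-1] < e$t_end_s[-nrow(e)] - 1e-9)) {
      stop("overlapping epochs in trial ", g)
    }
  }
  invisible(TRUE)
}

#' Write a session dataset to disk
#'
#' Layout: `lfp.bin` (float32, column-major per channel) + `lfp.json`
#' (rate, dimensions, channel table), `spikes.csv` (unit_id, time_s),
#' `units.json` (unit metadata), `waveforms.bin` + `waveforms.json`
#' (channel x sample mean waveforms per unit), `epochs.csv`, `light.csv`,
#' `ground_truth.json` (when present), and `manifest.json` tying the files
#' together.
#'
#' @param session Session list: `lfp`, `units`, `epochs`, `light`,
#'   optionally `ground_truth` and `config`.
#' @param dir Output directory (created if needed).
#' @param session_id Identifier stored in the manifest.
#' @return Invisibly, the manifest list.
#' @export
write_dataset <- function(session, dir, session_id = "synthetic-session") {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop("cannot create dataset directory ", dir)
  }
  lfp <- session$lfp
  con <- file(file.path(dir, "lfp.bin"), "wb")
  writeBin(as.numeric(lfp$samples), con, size = 4)
  close(con)
  jsonlite::write_json(
    list(rate_hz = lfp$rate, n_samples = nrow(lfp$samples),
         n_channels = ncol(lfp$samples), dtype = "float32",
         order = "column-major", channels = lfp$channels),
    file.path(dir, "lfp.json"), auto_unbox = TRUE, digits = NA)

  spikes <- do.call(rbind, lapply(session$units, function(u) {
    if (length(u$spike_times) == 0) return(NULL)
    data.frame(unit_id = u$id, time_s = u$spike_times)
  }))
  if (is.null(spikes)) spikes <- data.frame(unit_id = character(0),
                                            time_s = numeric(0))
  write.csv(spikes, file.path(dir, "spikes.csv"), row.names = FALSE)

  units_meta <- lapply(session$units, function(u) {
    list(id = u$id, region = u$region, peak_channel = u$peak_channel,
         waveform_rate = u$waveform_rate,
         is_cholinergic = isTRUE(u$is_cholinergic), template = u$template,
         waveform_channels = rownames(u$waveform),
         waveform_samples = if (is.null(u$waveform)) 0 else ncol(u$waveform))
  })
  jsonlite::write_json(units_meta, file.path(dir, "units.json"),
                       auto_unbox = TRUE, digits = NA)
  con <- file(file.path(dir, "waveforms.bin"), "wb")
  for (u in session$units) {
    if (!is.null(u$waveform)) writeBin(as.numeric(u$waveform), con, size = 8)
  }
  close(con)

  ep <- session$epochs
  write.csv(ep, file.path(dir, "epochs.csv"), row.names = FALSE)
  write.csv(session$light, file.path(dir, "light.csv"), row.names = FALSE)
  if (!is.null(session$ground_truth)) {
    jsonlite::write_json(unclass(session$ground_truth),
                         file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  manifest <- list(
    session_id = session_id,
    files = list(lfp = "lfp.bin", lfp_meta = "lfp.json",
                 spikes = "spikes.csv", units = "units.json",
                 waveforms = "waveforms.bin",
                 waveforms_meta = "units.json", epochs = "epochs.csv",
                 light = "light.csv",
                 ground_truth = if (!is.null(session$ground_truth)) {
                   "ground_truth.json"
                 } else NULL),
    config = if (!is.null(session$config)) {
      jsonlite::toJSON(unclass(session$config), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
    } else NULL)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Load a session dataset from disk
#'
#' Reads the container written by [write_dataset()], rebuilds the typed
#' in-memory objects, and validates their invariants: unique channel ids,
#' strictly increasing spike times, non-overlapping epochs, and waveform
#' channel ids present in the LFP channel table. The ground truth is
#' optional; its absence is not an error.
#'
#' @param dir Dataset directory containing `manifest.json`.
#' @return Session list: `lfp` ([lfp_recording()]), `units` (named list of
#'   [spike_unit()]), `epochs`, `light`, `ground_truth` (or `NULL`),
#'   `session_id`.
#' @export
load_session <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop("no manifest.json in ", dir)
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  meta <- jsonlite::read_json(file.path(dir, "lfp.json"),
                              simplifyVector = TRUE)
  chtab <- as.data.frame(meta$channels, stringsAsFactors = FALSE)
  con <- file(file.path(dir, "lfp.bin"), "rb")
  vals <- readBin(con, numeric(), n = meta$n_samples * meta$n_channels,
                  size = 4)
  close(con)
  if (length(vals) != meta$n_samples * meta$n_channels) {
    stop("lfp.bin is truncated: expected ",
         meta$n_samples * meta$n_channels, " values, got ", length(vals))
  }
  lfp <- lfp_recording(matrix(vals, meta$n_samples, meta$n_channels),
                       meta$rate_hz, chtab)

  spikes <- read.csv(file.path(dir, "spikes.csv"),
                     colClasses = c(unit_id = "character",
                                    time_s = "numeric"))
  units_meta <- jsonlite::read_json(file.path(dir, "units.json"),
                                    simplifyVector = FALSE)
  wcon <- file(file.path(dir, "waveforms.bin"), "rb")
  units <- list()
  for (um in units_meta) {
    wch <- unlist(um$waveform_channels)
    nw <- length(wch) * um$waveform_samples
    wf <- NULL
    if (nw > 0) {
      wf <- matrix(readBin(wcon, numeric(), n = nw, size = 8),
                   nrow = length(wch))
      rownames(wf) <- wch
      bad <- setdiff(wch, chtab$id)
      if (length(bad) > 0) {
        close(wcon)
        stop("waveform channels not present in LFP channel table: ",
             paste(bad, collapse = ", "))
      }
    }
    tt <- sort(spikes$time_s[spikes$unit_id == um$id])
    units[[um$id]] <- spike_unit(um$id, um$region, tt, waveform = wf,
                                 peak_channel = um$peak_channel,
                                 waveform_rate = um$waveform_rate,
                                 is_cholinergic = isTRUE(um$is_cholinergic),
                                 template = if (is.null(um$template)) {
                                   NA_character_
                                 } else um$template)
  }
  close(wcon)

  epochs <- read.csv(file.path(dir, "epochs.csv"))
  validate_epoch_table(epochs)
  light <- read.csv(file.path(dir, "light.csv"))
  gt <- NULL
  gpath <- file.path(dir, "ground_truth.json")
  if (file.exists(gpath)) {
    raw <- jsonlite::read_json(gpath, simplifyVector = TRUE)
    gt <- ground_truth(
      hotspots = as.data.frame(raw$hotspots, stringsAsFactors = FALSE),
      couplings = as.data.frame(raw$couplings, stringsAsFactors = FALSE),
      tagged_units = unlist(raw$tagged_units) %||% character(0),
      cholinergic_units = unlist(raw$cholinergic_units) %||% character(0),
      sta_effects = as.data.frame(raw$sta_effects,
                                  stringsAsFactors = FALSE))
  }
  list(lfp = lfp, units = units, epochs = epochs, light = light,
       ground_truth = gt, session_id = manifest$session_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
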