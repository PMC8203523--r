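# end-to-end pipeline over a loaded session: unit features/classification,
# optotagging, CCG connectivity, relative coherence + change map, STA

#' Pipeline configuration
#'
#' Validated parameter bundle for [run_pipeline()]. Band labels are checked
#' against the known bands before any computation starts.
#'
#' @param bands Named list of band ranges (Hz).
#' @param band Band label used for the coherence stages.
#' @param epoch Behavioral epoch for the change map.
#' @param alpha Significance level for unit-level and STA tests.
#' @param alpha_map Per-voxel significance level for the change map.
#' @param n_perm Permutations per voxel.
#' @param seed Master seed; each stage derives its own sub-seed.
#' @param region_pair Regions for the change map, `c(region_a, region_b)`.
#' @param k Number of k-means clusters.
#' @param max_ccg_pairs Cap on the number of unit pairs scanned.
#' @param modules Character vector of stages to run.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(bands = default_gamma_bands(),
                            band = "low_gamma", epoch = "decision",
                            alpha = 0.05, alpha_map = 0.01, n_perm = 1000,
                            seed = 1, region_pair = c("OFC", "V2"), k = 6,
                            max_ccg_pairs = 200,
                            modules = c("units", "optotag", "ccg",
                                        "cohmap", "sta")) {
  if (!band %in% names(bands)) {
    stop("unknown band label '", band, "' in pipeline config")
  }
  stopifnot(alpha > 0, alpha < 1, alpha_map > 0, alpha_map < 1,
            n_perm >= 100, length(region_pair) == 2)
  structure(list(bands = bands, band = band, epoch = epoch, alpha = alpha,
                 alpha_map = alpha_map, n_perm = n_perm,
                 seed = as.integer(seed), region_pair = region_pair, k = k,
                 max_ccg_pairs = max_ccg_pairs, modules = modules),
            class = "pipeline_config")
}

#' Run the full analysis pipeline on a session
#'
#' Executes the configured stages in order -- unit feature extraction and
#' classification, optogenetic tagging, cross-correlogram connectivity,
#' relative coherence with the epoch-level ANOVA and the permutation change
#' map, and spike-triggered gamma analysis for cholinergic units -- writing
#' CSV tables, a structured log, and a machine-readable run report to
#' `out_dir`. Results are deterministic given the config seed; on a stage
#' failure, completed outputs are preserved and the error names the stage.
#'
#' @param session Session list from [load_session()] or
#'   [generate_dataset()], or a dataset directory path.
#' @param out_dir Output directory.
#' @param config A [pipeline_config()].
#' @return Invisibly, the run report list.
#' @export
run_pipeline <- function(session, out_dir, config = pipeline_config()) {
  if (is.character(session)) session <- load_session(session)
  if (!inherits(config, "pipeline_config")) {
    stop("config must be a pipeline_config()")
  }
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    stop("cannot create output directory ", out_dir)
  }
  logpath <- file.path(out_dir, "pipeline.log")
  logmsg <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    paste0(...))
    cat(line, "\n", file = logpath, append = TRUE)
  }
  report <- list(parameters = list(
    band = config$band, bands = config$bands, epoch = config$epoch,
    alpha = config$alpha, alpha_map = config$alpha_map,
    n_perm = config$n_perm, seed = config$seed,
    region_pair = config$region_pair, k = config$k), stages = list())
  stage <- function(name, expr) {
    logmsg("stage ", name, ": start")
    out <- tryCatch(expr, error = function(e) {
      logmsg("stage ", name, ": FAILED: ", conditionMessage(e))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    logmsg("stage ", name, ": done")
    report$stages[[name]] <<- "ok"
    out
  }
  units <- session$units

  if ("units" %in% config$modules && length(units) >= max(3, config$k)) {
    feats <- stage("units", {
      f <- compute_unit_features(units)
      km <- classify_units(f, k = config$k,
                           seed = derive_seed(config$seed, 11))
      f$kmeans_label <- km$labels[f$unit]
      f$putative <- preliminary_ei_split(f$tp_latency_ms, f$mean_rate)
      chol <- f$unit[f$is_cholinergic]
      if (length(unique(f$kmeans_label[!f$unit %in% chol])) >= 2) {
        bt <- crossvalidate_bagged_tree(f, km$labels, chol,
                                        seed = derive_seed(config$seed, 12))
        f$predicted_label <- NA_integer_
        if (!is.null(bt$predicted_cholinergic)) {
          f$predicted_label[match(names(bt$predicted_cholinergic),
                                  f$unit)] <-
            as.integer(as.character(bt$predicted_cholinergic))
        }
        report$oob_accuracy <- bt$oob_accuracy
      }
      write.csv(f, file.path(out_dir, "features.csv"), row.names = FALSE)
      f
    })
  }

  if ("optotag" %in% config$modules && nrow(session$light) >= 100) {
    stage("optotag", {
      rows <- lapply(units, function(u) {
        ot <- optotag(u, session$light)
        data.frame(unit = u$id, evoked_rate = ot$evoked_rate,
                   control_mean = ot$control_mean,
                   control_sd = ot$control_sd, responsive = ot$responsive,
                   direction = ot$direction, n_stimuli = ot$n_stimuli)
      })
      write.csv(do.call(rbind, rows), file.path(out_dir, "optotag.csv"),
                row.names = FALSE)
    })
  }

  if ("ccg" %in% config$modules && length(units) >= 2) {
    stage("ccg", {
      ids <- names(units)
      pairs <- expand.grid(pre = ids, post = ids,
                           stringsAsFactors = FALSE)
      pairs <- pairs[pairs$pre != pairs$post, ]
      if (nrow(pairs) > config$max_ccg_pairs) {
        pairs <- pairs[seq_len(config$max_ccg_pairs), ]
      }
      rows <- list()
      for (i in seq_len(nrow(pairs))) {
        pre <- units[[pairs$pre[i]]]; post <- units[[pairs$post[i]]]
        if (length(pre$spike_times) < 100 ||
              length(post$spike_times) < 100) next
        cr <- ccg_detect(pre, post)
        rows[[length(rows) + 1L]] <-
          data.frame(pre = pre$id, post = post$id, detected = cr$detected,
                     sign = cr$sign,
                     n_significant_bins = nrow(cr$significant_bins))
      }
      conn <- if (length(rows)) do.call(rbind, rows) else
        data.frame(pre = character(0), post = character(0),
                   detected = logical(0), sign = character(0),
                   n_significant_bins = integer(0))
      write.csv(conn, file.path(out_dir, "connections.csv"),
                row.names = FALSE)
    })
  }

  if ("cohmap" %in% config$modules) {
    stage("cohmap", {
      ra <- config$region_pair[1]; rb <- config$region_pair[2]
      ch <- session$lfp$channels
      ca <- ch$id[ch$region == ra]; cb <- ch$id[ch$region == rb]
      if (length(ca) > 0 && length(cb) > 0) {
        rel <- relative_coherence(session, ca, cb, band = config$band,
                                  conditions = c("cue", "decision",
                                                 "approach", "optostim"))
        write.csv(rel, file.path(out_dir, "relative_coherence.csv"),
                  row.names = FALSE)
        if (length(unique(rel$condition)) >= 2 &&
              min(table(rel$condition)) >= 2) {
          an <- compare_epoch_coherence(rel, alpha = config$alpha)
          write.csv(an$tukey, file.path(out_dir, "tukey.csv"),
                    row.names = FALSE)
          report$anova_F <- an$F_stat
          report$anova_p <- an$p_value
        }
        map <- build_change_map(session, ra, rb, config$band, config$epoch,
                                alpha = config$alpha_map,
                                n_perm = config$n_perm,
                                seed = derive_seed(config$seed, 21))
        long <- data.frame(
          channel_a = rep(rownames(map$scores), ncol(map$scores)),
          channel_b = rep(colnames(map$scores),
                          each = nrow(map$scores)),
          score = as.vector(map$scores), p = as.vector(map$p),
          significant = as.vector(map$mask))
        write.csv(long, file.path(out_dir, "change_map.csv"),
                  row.names = FALSE)
        plot_change_map(map, file.path(out_dir, "change_map.png"),
                        only_significant = TRUE)
        report$map_significant_voxels <- sum(map$mask, na.rm = TRUE)
      }
    })
  }

  if ("sta" %in% config$modules) {
    stage("sta", {
      chol <- Filter(function(u) isTRUE(u$is_cholinergic), units)
      if (length(chol) > 0) {
        res <- do.call(rbind, lapply(chol, function(u) {
          sta_analysis(u, session$lfp, bands = config$bands,
                       alpha = config$alpha)
        }))
        write.csv(res, file.path(out_dir, "sta.csv"), row.names = FALSE)
        avail <- length(unique(res$channel[res$region ==
                                             res$region[1]]))
        summ <- suppressWarnings(
          summarize_percent_significant(res, n_sites = NULL))
        write.csv(summ, file.path(out_dir, "sta_summary.csv"),
                  row.names = FALSE)
      }
    })
  }

  report$session_id <- session$session_id %||% "in-memory"
  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  logmsg("pipeline complete")
  invisible(report)
}
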