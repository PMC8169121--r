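# Readers/writers for the pipeline's plain-text formats, session assembly,
# and the staged pipeline driver. Coordinates are stored in cm (arena
# origin at the initiation-port wall corner); time in seconds; frame
# indices 0-based; intervals half-open [start, end).

TRACKING_COLS <- c("frame", "time_s", "nose_x", "nose_y", "head_x", "head_y",
                   "body_x", "body_y")

#' Read a tracking CSV
#'
#' Expects columns frame, time_s, nose_x, nose_y, head_x, head_y, body_x,
#' body_y; optional per-keypoint likelihood columns (`nose_l`, `head_l`,
#' `body_l`) turn low-confidence points into NA.
#'
#' @param path CSV file.
#' @param min_likelihood confidence threshold (default 0.9).
#' @return tracking data.frame; the number of masked points is in attribute
#'   `n_low_confidence`.
#' @export
read_tracking_csv <- function(path, min_likelihood = 0.9) {
  df <- read.csv(path)
  miss <- setdiff(TRACKING_COLS, names(df))
  if (length(miss))
    stop_invalid("malformed tracking header; missing column(s): ",
                 paste(miss, collapse = ", "))
  n_masked <- 0L
  for (kp in c("nose", "head", "body")) {
    lcol <- paste0(kp, "_l")
    if (lcol %in% names(df)) {
      low <- df[[lcol]] < min_likelihood
      n_masked <- n_masked + sum(low, na.rm = TRUE)
      df[low, paste0(kp, c("_x", "_y"))] <- NA_real_
    }
  }
  out <- df[, TRACKING_COLS]
  attr(out, "n_low_confidence") <- n_masked
  out
}

#' Write a tracking CSV
#' @param traj tracking data.frame.
#' @param path output file.
#' @export
write_tracking_csv <- function(traj, path) {
  write.csv(traj[, TRACKING_COLS], path, row.names = FALSE)
}

#' Read / write sniff traces and events
#'
#' Trace CSV columns: time_s, signal. Event CSV columns: inhalation_s,
#' exhalation_s, duration_s, kept (exhalation/duration NA for the final,
#' open sniff).
#'
#' @param path CSV file.
#' @return `sniff_trace` / `sniff_events`.
#' @export
read_sniff_trace_csv <- function(path) {
  df <- read.csv(path)
  if (!all(c("time_s", "signal") %in% names(df)))
    stop_invalid("sniff trace CSV needs columns time_s, signal")
  sr <- 1 / median(diff(df$time_s))
  sniff_trace(df$signal, sample_rate = sr, t0 = df$time_s[1])
}

#' @rdname read_sniff_trace_csv
#' @param trace `sniff_trace` to write.
#' @export
write_sniff_trace_csv <- function(trace, path) {
  tt <- trace$t0 + (seq_along(trace$samples) - 1) / trace$sample_rate
  write.csv(data.frame(time_s = tt, signal = trace$samples), path,
            row.names = FALSE)
}

#' @rdname read_sniff_trace_csv
#' @export
read_sniff_events_csv <- function(path) {
  df <- read.csv(path)
  ev <- sniff_events(df$inhalation_s,
                     df$exhalation_s[!is.na(df$exhalation_s)])
  kept <- df$kept[!is.na(df$duration_s)]
  ev$kept_mask <- as.logical(kept)
  ev
}

#' @rdname read_sniff_trace_csv
#' @param events `sniff_events` to write.
#' @export
write_sniff_events_csv <- function(events, path) {
  n <- length(events$inhalation_s)
  ex <- rep(NA_real_, n)
  if (length(events$exhalation_s))
    ex[seq_along(events$exhalation_s)] <- events$exhalation_s
  write.csv(data.frame(
    inhalation_s = events$inhalation_s,
    exhalation_s = ex,
    duration_s = c(events$durations, NA_real_),
    kept = c(events$kept_mask, NA)), path, row.names = FALSE)
}

#' Serialize fitted AR-HMM parameters to JSON
#'
#' @param params `arhmm_params`.
#' @param path output JSON file.
#' @export
write_params_json <- function(params, path) {
  obj <- list(S = params$S, d = params$d, pi = params$pi, init = params$init,
              A = params$A, b = params$b, Q = params$Q)
  jsonlite::write_json(obj, path, digits = NA, matrix = "rowmajor")
}

#' @rdname write_params_json
#' @return `arhmm_params`.
#' @export
read_params_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  arhmm_params(pi = matrix(unlist(o$pi), o$S, o$S, byrow = TRUE),
               A = lapply(seq_len(o$S), function(s)
                 matrix(unlist(o$A[s, , ]), o$d, o$d)),
               b = lapply(seq_len(o$S), function(s) as.numeric(o$b[s, ])),
               Q = lapply(seq_len(o$S), function(s)
                 matrix(unlist(o$Q[s, , ]), o$d, o$d)),
               init = as.numeric(o$init))
}

#' Write a spatial map as TSV with a JSON sidecar
#'
#' @param map `spatial_map`.
#' @param path TSV path; the sidecar is written at `paste0(path, ".json")`.
#' @export
write_map_tsv <- function(map, path) {
  write.table(map$grid, path, sep = "\t", row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(bin_size = map$bin_size, extent = map$extent,
                            smoothing = map$smoothing),
                       paste0(path, ".json"), auto_unbox = TRUE, null = "null")
}

#' Assemble a session bundle from flat tables
#'
#' Slices continuous tracking and sniff events into trials by the metadata
#' table (half-open intervals \[start_s, end_s)). Trials outside the
#' tracking range are excluded (indices in attribute `excluded`). The
#' 2-frame tracking-to-sniff alignment shift is applied here, once.
#'
#' @param tracking tracking data.frame (session clock).
#' @param sniff `sniff_events` (session clock).
#' @param meta data.frame with columns start_s, end_s, side, choice,
#'   correct, and optionally ratio.
#' @param frame_rate Hz (default 80).
#' @param px_per_cm pixel scale (default NA, data already in cm).
#' @param align_shift frames to advance tracking relative to the sniff
#'   clock (default 2).
#' @return `session_bundle`.
#' @export
assemble_session <- function(tracking, sniff, meta, frame_rate = 80,
                             px_per_cm = NA_real_, align_shift = 2L) {
  o <- order(meta$start_s)
  meta <- meta[o, , drop = FALSE]
  if (any(meta$start_s[-1] < meta$end_s[-nrow(meta)]))
    stop_invalid("overlapping trials in metadata")
  shift_s <- align_shift / frame_rate
  trk <- tracking
  trk$time_s <- trk$time_s + shift_s # tracking shifted forward onto sniff clock
  excluded <- integer(0)
  trials <- list()
  for (i in seq_len(nrow(meta))) {
    sel <- trk$time_s >= meta$start_s[i] & trk$time_s < meta$end_s[i]
    if (!any(sel)) { excluded <- c(excluded, i); next }
    inh_sel <- sniff$inhalation_s >= meta$start_s[i] &
      sniff$inhalation_s < meta$end_s[i]
    inh <- sniff$inhalation_s[inh_sel]
    ev <- if (sum(inh_sel) >= 2) {
      ex <- sniff$exhalation_s[sniff$exhalation_s >= min(inh) &
                                 sniff$exhalation_s <= max(inh)]
      ke <- sniff$kept_mask[which(inh_sel)[-sum(inh_sel)]]
      e <- sniff_events(inh, ex); e$kept_mask <- ke; e
    } else NULL
    trials[[length(trials) + 1]] <- list(
      trajectory = trk[sel, , drop = FALSE],
      sniff = ev, sniff_trace = NULL,
      meta = as.list(meta[i, , drop = FALSE]),
      truth = NULL)
  }
  out <- structure(list(mouse_id = "unknown", session_id = "unknown",
                        frame_rate = frame_rate, px_per_cm = px_per_cm,
                        left_is_high_lat = TRUE, config = NULL,
                        trials = trials),
                   class = "session_bundle")
  attr(out, "excluded") <- excluded
  out
}

#' Run the staged analysis pipeline on a synthetic session
#'
#' Executes simulate -> sniff -> kinematics -> fit -> states -> spatial ->
#' decode -> plume on generated data, writing each stage's outputs and a
#' provenance manifest into `out_dir`. Deterministic given the config and
#' seed; re-running overwrites identical outputs.
#'
#' @param config list (or path to a YAML/JSON file) with optional blocks
#'   `simulate` (session_config arguments), `fit` (S, n_iter, n_burn),
#'   `plume` (gen_plume_session arguments) and a required integer `seed`.
#' @param out_dir output directory (created).
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
    else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (is.null(config$seed)) stop_invalid("config must carry an explicit seed")
  known <- c("seed", "simulate", "fit", "plume")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) stop_invalid("unknown config block(s): ",
                                    paste(unknown, collapse = ", "))
  seed <- as.integer(config$seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  scfg <- do.call(session_config, config$simulate %||% list())
  session <- simulate_session(scfg, seed = child_seed(seed, 1))
  # -- sniff + kinematics per trial --------------------------------------
  kin_rows <- list(); sniff_rows <- list()
  for (i in seq_along(session$trials)) {
    tr <- session$trials[[i]]
    sm <- smooth_trace(tr$sniff_trace)
    ev <- detect_sniffs(sm, refine_trace = tr$sniff_trace)
    if (length(ev$durations) >= 2) ev <- filter_sniff_durations(ev)
    kin <- compute_kinematics(tr$trajectory)
    kin$trial <- i
    kin_rows[[i]] <- kin
    sniff_rows[[i]] <- data.frame(trial = i, inhalation_s = ev$inhalation_s)
  }
  write.csv(do.call(rbind, kin_rows), file.path(out_dir, "kinematics.csv"),
            row.names = FALSE)
  write.csv(do.call(rbind, sniff_rows), file.path(out_dir, "sniff_events.csv"),
            row.names = FALSE)
  # -- AR-HMM fit on nose+head coordinates -------------------------------
  fcfg <- config$fit %||% list()
  S <- fcfg$S %||% 4L
  trials_xy <- lapply(session$trials, function(tr)
    as.matrix(tr$trajectory[, c("nose_x", "nose_y", "head_x", "head_y")]))
  fit <- gibbs_fit(trials_xy, S = S,
                   cfg = gibbs_config(n_iter = fcfg$n_iter %||% 150,
                                      n_burn = fcfg$n_burn %||% 100,
                                      seed = child_seed(seed, 2)))
  write_params_json(fit$expected_params, file.path(out_dir, "model.json"))
  map_df <- do.call(rbind, lapply(seq_along(fit$map_sequences), function(i)
    data.frame(trial = i, frame = seq_along(fit$map_sequences[[i]]) - 1L,
               motif = fit$map_sequences[[i]])))
  write.csv(map_df, file.path(out_dir, "map_sequences.csv"), row.names = FALSE)
  # -- states: usage filter + two-group clustering -----------------------
  kept <- usage_filter(fit$map_sequences)
  pi_kept <- fit$expected_params$pi[kept, kept, drop = FALSE]
  pi_kept <- pi_kept / rowSums(pi_kept)
  rownames(pi_kept) <- as.character(kept)
  grouping <- cluster_transition_matrix(pi_kept)
  glabels <- group_names_by_speed(session, fit$map_sequences, grouping)
  frame_labels <- state_frame_labels(fit$map_sequences, grouping, labels = glabels)
  write.csv(data.frame(motif = grouping$motif_ids,
                       group = glabels[grouping$group]),
            file.path(out_dir, "state_grouping.csv"), row.names = FALSE)
  # -- spatial maps -------------------------------------------------------
  all_long <- unlist(lapply(session$trials, function(tr) tr$trajectory$nose_x))
  all_lat <- unlist(lapply(session$trials, function(tr) tr$trajectory$nose_y))
  occ <- occupancy_map(all_long, all_lat, bin_size = 0.5)
  write_map_tsv(occ, file.path(out_dir, "occupancy.tsv"))
  lab_vec <- unlist(frame_labels)
  som <- state_occupancy_maps(all_long, all_lat, lab_vec, bin_size = 1)
  write_map_tsv(iai(som$investigation, som$approach), file.path(out_dir, "iai.tsv"))
  write.csv(session_performance(session), file.path(out_dir, "performance.csv"),
            row.names = FALSE)
  # -- decoding: left vs right choice from transition features -----------
  feats <- transition_design(fit$map_sequences, S = S)
  choice <- vapply(session$trials, function(tr) tr$meta$choice, character(1))
  dec_res <- tryCatch({
    dec <- lda_decode(feats, choice, folds = min(5, min(table(choice))),
                      seed = child_seed(seed, 3))
    write.csv(as.data.frame(dec$confusion), file.path(out_dir, "decoding_confusion.csv"))
    dec$accuracy
  }, error = function(e) NA_real_)
  # -- plume --------------------------------------------------------------
  pcfg <- config$plume %||% list(n_trials_per_bin = 5, sample_rate = 200)
  pcfg$seed <- child_seed(seed, 4)
  pg <- do.call(gen_plume_session, pcfg)
  am <- auroc_map_absolute(pg)
  write.table(am$grid, file.path(out_dir, "auroc_absolute.tsv"), sep = "\t",
              row.names = FALSE, col.names = FALSE)
  manifest <- list(seed = seed, stages = c("simulate", "sniff", "kinematics",
                                           "fit", "states", "spatial",
                                           "decode", "plume"),
                   n_trials = length(session$trials), S = S,
                   decode_accuracy = dec_res,
                   package_version = as.character(utils::packageVersion("sniffsearch")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

# Name motif groups by mean nose speed: the slower group is investigation.
group_names_by_speed <- function(session, map_sequences, grouping) {
  sp <- lapply(seq_along(session$trials), function(i) {
    k <- compute_kinematics(session$trials[[i]]$trajectory)
    k$nose_speed
  })
  lut <- setNames(grouping$group, grouping$motif_ids)
  gsp <- c(`1` = 0, `2` = 0); gn <- c(`1` = 0, `2` = 0)
  for (i in seq_along(map_sequences)) {
    g <- lut[as.character(map_sequences[[i]])]
    v <- sp[[i]]
    for (gg in c(1, 2)) {
      sel <- !is.na(g) & g == gg & !is.na(v)
      gsp[gg] <- gsp[gg] + sum(v[sel]); gn[gg] <- gn[gg] + sum(sel)
    }
  }
  mean_sp <- gsp / pmax(gn, 1)
  if (mean_sp[1] <= mean_sp[2]) c("investigation", "approach")
  else c("approach", "investigation")
}
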