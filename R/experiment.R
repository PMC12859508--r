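#' Read and validate an experiment configuration file
#'
#' One YAML file defines an experiment: the videos to analyze, the pixel
#' size (required for plain TIFFs), temperature, detection/boundary
#' parameters and population-filter thresholds. Unknown keys are errors
#' so typos cannot silently fall back to defaults.
#'
#' Recognized keys: `experiment_name`, `videos` (list of paths, relative
#' to the config file), `pixel_size`, `temperature`, `minimum_intensity`,
#' `min_size`, `max_size`, `fill_threshold`, `smoothing_width`,
#' `tracking_threshold`, `tracking_memory`, `boundary_mode`,
#' `continuity_max_step`, `q_max`, `l_max`, `min_sigma`,
#' `min_continuity_fraction`, `max_epsilon`, `min_delta_epsilon`,
#' `min_frames`, `output_dir`.
#'
#' @param path YAML file.
#' @return list with `name`, `videos`, `pixel_size`, `temperature`,
#'   `config` ([imaging_config()]), `filters` ([filter_spec()]), `l_max`,
#'   `output_dir`.
#' @export
read_experiment_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  raw <- yaml::read_yaml(path)
  known <- c("experiment_name", "videos", "pixel_size", "temperature",
             "minimum_intensity", "min_size", "max_size", "fill_threshold",
             "smoothing_width", "tracking_threshold", "tracking_memory",
             "boundary_mode", "continuity_max_step", "q_max", "l_max",
             "min_sigma", "min_continuity_fraction", "max_epsilon",
             "min_delta_epsilon", "min_frames", "output_dir")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  if (is.null(raw$videos) || !length(raw$videos)) {
    stop("config must name at least one video")
  }
  base <- dirname(normalizePath(path))
  videos <- vapply(raw$videos, function(v) {
    if (file.exists(v)) v else file.path(base, v)
  }, character(1))
  get <- function(nm, default) if (is.null(raw[[nm]])) default else raw[[nm]]
  config <- imaging_config(
    min_intensity = get("minimum_intensity", 0.3),
    min_size = get("min_size", 15),
    max_size = get("max_size", 45),
    fill_threshold = get("fill_threshold", 0.5),
    smoothing_width = get("smoothing_width", 1.0),
    track_distance = get("tracking_threshold", 15),
    track_memory = get("tracking_memory", 10),
    boundary_mode = get("boundary_mode", "condensate"),
    continuity_max_step = get("continuity_max_step", 3),
    q_max = get("q_max", 15))
  filters <- filter_spec(
    min_sigma = get("min_sigma", 1e-10),
    min_continuity_fraction = get("min_continuity_fraction", 0.60),
    max_epsilon = get("max_epsilon", 0.5),
    min_delta_epsilon = get("min_delta_epsilon", 0.03),
    min_frames = get("min_frames", 200))
  list(name = get("experiment_name", "experiment"), videos = videos,
       pixel_size = get("pixel_size", NA_real_),
       temperature = get("temperature", 298),
       config = config, filters = filters, l_max = get("l_max", 75),
       output_dir = get("output_dir", base))
}

# Stage 1+2 for one video: detect, track, extract boundaries, Fourier
# modes. Returns per-object mode sets plus bookkeeping.
analyze_stack <- function(stack, config, progress = FALSE) {
  state <- tracker_state(config)
  assignments <- vector("list", length(stack$frames))
  per_object <- list()   # id -> list(mode_sets, n_present, intensity, cx, cy)
  for (f in seq_along(stack$frames)) {
    frame <- stack$frames[[f]]
    det <- detect_centers(frame, config)
    kept <- list()
    if (nrow(det) > 0) {
      for (i in seq_len(nrow(det))) {
        ext <- estimate_extent(frame, c(det$x[i], det$y[i]), config)
        if (is.null(ext)) next
        kept[[length(kept) + 1]] <- ext
      }
    }
    centers <- if (length(kept)) {
      data.frame(x = vapply(kept, function(k) k$centroid[1], numeric(1)),
                 y = vapply(kept, function(k) k$centroid[2], numeric(1)))
    } else data.frame(x = numeric(0), y = numeric(0))
    adv <- advance_tracker(state, centers, f - 1L)
    state <- adv$state
    assignments[[f]] <- adv$assignment
    for (i in seq_along(kept)) {
      id <- as.character(adv$assignment[i])
      ext <- kept[[i]]
      bb <- ext$bbox
      sub <- frame[(bb[2]:bb[4]) + 1, (bb[1]:bb[3]) + 1, drop = FALSE]
      ctr <- ext$centroid - bb[1:2]
      rec <- per_object[[id]]
      if (is.null(rec)) {
        rec <- list(mode_sets = list(), n_present = 0L, intensity = 0,
                    cx = ext$centroid[1], cy = ext$centroid[2])
      }
      rec$n_present <- rec$n_present + 1L
      rec$intensity <- rec$intensity + mean(frame[ext$mask])
      contour <- tryCatch({
        fld <- build_field(sub, ctr, config$smoothing_width,
                           config$boundary_mode)
        trace_boundary(fld)
      }, error = function(e) NULL)
      if (!is.null(contour) &&
          validate_contour(contour, config$continuity_max_step)) {
        contour$center <- contour$center + bb[1:2]
        rec$mode_sets[[length(rec$mode_sets) + 1]] <-
          contour_modes(contour, config$q_max)
      }
      per_object[[id]] <- rec
    }
    if (progress && f %% 100 == 0) {
      message(sprintf("  frame %d/%d", f, length(stack$frames)))
    }
  }
  list(per_object = per_object, assignments = assignments,
       spans = filter_new_tracks(assignments))
}

# Stage 3: accumulate + fit each object of one analyzed video.
fit_stack_objects <- function(analysis, stack, temperature, l_max = 75,
                              q_max = 15, min_fit_frames = 2,
                              blur_sigma = 0) {
  rows <- list()
  for (id in names(analysis$per_object)) {
    rec <- analysis$per_object[[id]]
    n_modes <- length(rec$mode_sets)
    if (n_modes < min_fit_frames) next
    sr <- accumulate_modes(rec$mode_sets, n_total = rec$n_present,
                           pixel_size = stack$pixel_size,
                           blur_sigma = blur_sigma)
    fit <- tryCatch(
      fit_spectrum(sr, temperature, q_range = 2:q_max, l_max = l_max),
      error = function(e) NULL)
    if (is.null(fit)) next
    rows[[length(rows) + 1]] <- data.frame(
      video = stack$name, object_id = as.integer(id),
      sigma = fit$sigma, sigma_uNm = fit$sigma_uNm, kappa = fit$kappa,
      sigma_bar = fit$sigma_bar, mean_radius_um = sr$mean_radius_um,
      epsilon = fit$epsilon, epsilon_sigma_only = fit$epsilon_sigma_only,
      delta_epsilon = fit$delta_epsilon, durbin_watson = fit$durbin_watson,
      n_frames = sr$n_frames, continuity = sr$continuity,
      mean_intensity = rec$intensity / max(rec$n_present, 1),
      cx = rec$cx, cy = rec$cy, se_sigma = fit$se_sigma,
      se_kappa = fit$se_kappa, converged = fit$converged,
      experiment = stack$name, timestamp = NA_real_)
  }
  if (!length(rows)) {
    return(empty_aggregate())
  }
  do.call(rbind, rows)
}

empty_aggregate <- function() {
  cols <- aggregate_columns
  out <- lapply(cols, function(x) {
    if (x %in% c("video", "experiment")) character(0)
    else if (x %in% c("object_id", "n_frames")) integer(0)
    else if (x == "converged") logical(0)
    else numeric(0)
  })
  names(out) <- cols
  as.data.frame(out, stringsAsFactors = FALSE)
}

# drop .tif/.tiff and a trailing .ome from a video file name
video_basename <- function(path) {
  sub("\\.ome$", "", tools::file_path_sans_ext(basename(path)))
}

# write per-object per-frame Fourier components + flags for one video
write_intermediate <- function(analysis, stack, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "objects")
  for (id in names(analysis$per_object)) {
    rec <- analysis$per_object[[id]]
    if (!length(rec$mode_sets)) next
    grp <- paste0("objects/id_", id)
    rhdf5::h5createGroup(path, grp)
    V <- vapply(rec$mode_sets, function(m) m$V, rec$mode_sets[[1]]$V)
    V <- matrix(V, nrow = length(rec$mode_sets[[1]]$V))
    rhdf5::h5write(Re(V), path, paste0(grp, "/V_real"))
    rhdf5::h5write(Im(V), path, paste0(grp, "/V_imag"))
    rhdf5::h5write(vapply(rec$mode_sets, `[[`, numeric(1), "mean_radius"),
                   path, paste0(grp, "/mean_radius_px"))
    rhdf5::h5write(rec$n_present, path, paste0(grp, "/n_present"))
  }
  invisible(path)
}

#' Run a full flicker-spectroscopy experiment
#'
#' Executes the three pipeline stages for every video named in the
#' configuration (detection + tracking, boundary + Fourier extraction,
#' spectrum fitting), applies the population filters, and writes the
#' aggregate fittings HDF5 file plus per-video intermediates and a plain
#' text run log into the output directory. An unreadable video is
#' skipped with a logged warning; a plain TIFF without a configured pixel
#' size is a hard error before any processing.
#'
#' @param config_path path to the experiment YAML.
#' @param write_intermediates write per-video HDF5 intermediates.
#' @return invisibly, a list with `aggregate` (all fitted records),
#'   `passing` (post-filter records), `rejections`, `aggregate_path`.
#' @export
run_experiment <- function(config_path, write_intermediates = TRUE) {
  cfg <- read_experiment_config(config_path)
  out_dir <- cfg$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, paste0(cfg$name, "_run.log"))
  log_lines <- c(sprintf("experiment: %s", cfg$name),
                 sprintf("videos: %d", length(cfg$videos)))
  all_rows <- list()
  for (v in cfg$videos) {
    stack <- tryCatch(
      read_frame_stack(v, pixel_size_override = cfg$pixel_size),
      error = function(e) e)
    if (inherits(stack, "error")) {
      if (grepl("pixel size missing", conditionMessage(stack))) {
        stop(stack)   # configuration error: do not silently skip
      }
      warning("skipping unreadable video ", v, ": ",
              conditionMessage(stack))
      log_lines <- c(log_lines,
                     sprintf("SKIP %s: %s", v, conditionMessage(stack)))
      next
    }
    analysis <- analyze_stack(stack, cfg$config)
    if (write_intermediates) {
      write_intermediate(analysis, stack,
                         file.path(out_dir,
                                   paste0(video_basename(v), "_modes.h5")))
    }
    rows <- fit_stack_objects(analysis, stack, cfg$temperature,
                              l_max = cfg$l_max,
                              q_max = cfg$config$q_max,
                              blur_sigma = cfg$config$smoothing_width)
    rows$experiment <- cfg$name
    log_lines <- c(log_lines,
                   sprintf("video %s: %d tracked objects, %d fitted",
                           stack$name, nrow(analysis$spans), nrow(rows)))
    all_rows[[length(all_rows) + 1]] <- rows
  }
  aggregate <- if (length(all_rows)) do.call(rbind, all_rows)
               else empty_aggregate()
  filt <- apply_population_filters(aggregate, cfg$filters)
  agg_path <- file.path(out_dir, paste0(cfg$name, "_aggregate.h5"))
  write_aggregate(aggregate, agg_path)
  log_lines <- c(log_lines,
                 sprintf("fitted: %d  passing: %d", nrow(aggregate),
                         nrow(filt$records)),
                 paste0("rejections: ",
                        paste(names(filt$rejections), filt$rejections,
                              sep = "=", collapse = " ")))
  writeLines(log_lines, log_path)
  invisible(list(aggregate = aggregate, passing = filt$records,
                 rejections = filt$rejections, aggregate_path = agg_path))
}

#' Export an aggregate file to CSV
#'
#' @param h5_path aggregate .h5 file.
#' @param csv_path output CSV path (default: same name, .csv).
#' @return `csv_path`, invisibly.
#' @export
export_aggregate_csv <- function(h5_path, csv_path = NULL) {
  if (is.null(csv_path)) {
    csv_path <- paste0(tools::file_path_sans_ext(h5_path), ".csv")
  }
  write.csv(read_aggregate(h5_path), csv_path, row.names = FALSE)
  invisible(csv_path)
}
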