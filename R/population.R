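#' Population-level filter thresholds
#'
#' The published population filters: interfacial tension above
#' `min_sigma` (10^-10 N/m screens out non-physical fits), a continuous
#' boundary in more than `min_continuity_fraction` of frames, fitting
#' error below `max_epsilon`, tension-plus-rigidity vs tension-only error
#' difference above `min_delta_epsilon` (so bending rigidity is actually
#' identifiable), and a minimum number of contributing frames.
#'
#' @param min_sigma N/m.
#' @param min_continuity_fraction fraction in (0, 1).
#' @param max_epsilon fit error bound.
#' @param min_delta_epsilon model-comparison bound.
#' @param min_frames minimum contributing frames (default 200; lower it
#'   for short videos).
#' @return an object of class `filter_spec`.
#' @export
filter_spec <- function(min_sigma = 1e-10, min_continuity_fraction = 0.60,
                        max_epsilon = 0.5, min_delta_epsilon = 0.03,
                        min_frames = 200) {
  stopifnot(is.finite(min_sigma), is.finite(min_continuity_fraction),
            is.finite(max_epsilon), is.finite(min_delta_epsilon),
            is.finite(min_frames))
  structure(list(min_sigma = min_sigma,
                 min_continuity_fraction = min_continuity_fraction,
                 max_epsilon = max_epsilon,
                 min_delta_epsilon = min_delta_epsilon,
                 min_frames = min_frames),
            class = "filter_spec")
}

#' Apply the population filters
#'
#' A record passes iff sigma > min_sigma AND continuity >
#' min_continuity_fraction AND epsilon < max_epsilon AND delta_epsilon >
#' min_delta_epsilon AND n_frames >= min_frames. Rejections are tallied
#' by the first failing filter in that order (pass/fail itself is
#' order-independent).
#'
#' @param records data.frame with columns sigma, continuity, epsilon,
#'   delta_epsilon, n_frames (as produced by [run_experiment()] /
#'   [aggregate_records()]).
#' @param spec a [filter_spec()].
#' @return list with `records` (passing rows), `rejections` (named
#'   counts), `pass` (logical vector).
#' @export
apply_population_filters <- function(records, spec = filter_spec()) {
  checks <- list(
    sigma = records$sigma > spec$min_sigma,
    continuity = records$continuity > spec$min_continuity_fraction,
    epsilon = records$epsilon < spec$max_epsilon,
    delta_epsilon = records$delta_epsilon > spec$min_delta_epsilon,
    n_frames = records$n_frames >= spec$min_frames)
  fails <- !do.call(cbind, checks)
  pass <- rowSums(fails) == 0
  first_fail <- apply(fails, 1, function(f) {
    w <- which(f)
    if (length(w)) names(checks)[w[1]] else NA_character_
  })
  rejections <- vapply(names(checks),
                       function(nm) sum(first_fail == nm, na.rm = TRUE),
                       integer(1))
  list(records = records[pass, , drop = FALSE], rejections = rejections,
       pass = pass)
}

#' Population summary statistics
#'
#' Interfacial tension and bending rigidity are log-normally distributed
#' across a population, so they are reported as the geometric mean with a
#' geometric standard deviation factor (the interval geometric mean
#' x/ geometric SD is the analogue of mean +/- 1 SD). Other quantities
#' use arithmetic mean and SD.
#'
#' @param values numeric vector (positive under `scale = "lognormal"`).
#' @param scale "lognormal" or "linear".
#' @return list with `center`, `spread`, `lower`, `upper`, `n`.
#' @export
summarize_population <- function(values, scale = c("lognormal", "linear")) {
  scale <- match.arg(scale)
  values <- values[!is.na(values)]
  if (!length(values)) stop("no values to summarize")
  if (scale == "lognormal") {
    if (any(values <= 0)) stop("lognormal summary requires positive values")
    mu <- mean(log(values))
    s <- if (length(values) > 1) sd(log(values)) else 0
    center <- exp(mu); spread <- exp(s)
    list(center = center, spread = spread, lower = center / spread,
         upper = center * spread, n = length(values))
  } else {
    center <- mean(values)
    s <- if (length(values) > 1) sd(values) else 0
    list(center = center, spread = s, lower = center - s,
         upper = center + s, n = length(values))
  }
}

aggregate_columns <- c("video", "object_id", "sigma", "sigma_uNm", "kappa",
                       "sigma_bar", "mean_radius_um", "epsilon",
                       "epsilon_sigma_only", "delta_epsilon",
                       "durbin_watson", "n_frames", "continuity",
                       "mean_intensity", "cx", "cy", "se_sigma", "se_kappa",
                       "converged", "experiment", "timestamp")

#' Write the aggregate fittings file
#'
#' One HDF5 file with a row per analyzed object carrying the fitted
#' mechanical parameters, diagnostics and provenance, stored as plain
#' C-type columns under `/aggregate` so any HDF5 tooling can read it. A
#' `schema_version` attribute is written at the root.
#'
#' @param records data.frame in the aggregate layout (see
#'   `flickerspec:::aggregate_columns`).
#' @param path output .h5 path (overwritten).
#' @return `path`, invisibly.
#' @export
write_aggregate <- function(records, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "aggregate")
  for (col in names(records)) {
    v <- records[[col]]
    if (is.logical(v)) v <- as.integer(v)
    if (is.factor(v)) v <- as.character(v)
    rhdf5::h5write(v, path, paste0("aggregate/", col))
  }
  rhdf5::h5write(names(records), path, "aggregate/.columns")
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute("1.0", fid, "schema_version")
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' Read an aggregate fittings file
#'
#' @param path .h5 file written by [write_aggregate()].
#' @return data.frame.
#' @export
read_aggregate <- function(path) {
  cols <- as.character(rhdf5::h5read(path, "aggregate/.columns"))
  out <- lapply(cols, function(col) {
    as.vector(rhdf5::h5read(path, paste0("aggregate/", col)))
  })
  names(out) <- cols
  out <- as.data.frame(out, stringsAsFactors = FALSE)
  if ("converged" %in% cols) out$converged <- as.logical(out$converged)
  out
}
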