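#' Create an empty tracker state
#'
#' The tracker links detections across frames on position alone. It
#' remembers the last known position of every live object; an object
#' missing from a frame starts a countdown at `track_memory` and is
#' deleted permanently when the countdown reaches zero, so a
#' re-appearance within `track_memory` consecutive missing frames keeps
#' its ID and a later one is treated as a new object. IDs are unique
#' non-negative integers assigned in order of first appearance.
#'
#' @param config an [imaging_config()] (match radius and memory).
#' @return an object of class `tracker_state`.
#' @export
tracker_state <- function(config) {
  structure(list(ids = integer(0), x = numeric(0), y = numeric(0),
                 countdown = integer(0),    # NA = seen last frame
                 next_id = 0L,
                 track_distance = config$track_distance,
                 track_memory = config$track_memory),
            class = "tracker_state")
}

#' Advance the tracker by one frame
#'
#' Matches detections to remembered objects greedily in ascending
#' distance order (ties broken by lower detection index), accepting only
#' pairs within the match radius. Matched objects refresh their stored
#' position and cancel any countdown; unmatched detections get new
#' sequential IDs; unmatched remembered objects start (at
#' `track_memory`) or decrement their countdown and are deleted when it
#' reaches zero.
#'
#' @param state a `tracker_state`.
#' @param detections data.frame with columns x, y (may have zero rows).
#' @param frame_index integer (unused by the matching itself; recorded
#'   by callers).
#' @return list with `state` (updated) and `assignment` (integer vector
#'   of IDs, one per detection row).
#' @export
advance_tracker <- function(state, detections, frame_index = NA_integer_) {
  n_det <- nrow(detections)
  n_mem <- length(state$ids)
  assignment <- rep(NA_integer_, n_det)
  matched_mem <- logical(n_mem)
  if (n_det > 0 && n_mem > 0) {
    dx <- outer(detections$x, state$x, "-")
    dy <- outer(detections$y, state$y, "-")
    D <- sqrt(dx^2 + dy^2)
    cand <- which(D <= state$track_distance, arr.ind = TRUE)
    if (nrow(cand) > 0) {
      # greedy ascending distance; ties by lower detection index then
      # lower memory slot, for a deterministic, order-independent result
      ord <- order(D[cand], cand[, 1], cand[, 2])
      cand <- cand[ord, , drop = FALSE]
      used_det <- logical(n_det)
      for (k in seq_len(nrow(cand))) {
        i <- cand[k, 1]; j <- cand[k, 2]
        if (used_det[i] || matched_mem[j]) next
        used_det[i] <- TRUE
        matched_mem[j] <- TRUE
        assignment[i] <- state$ids[j]
        state$x[j] <- detections$x[i]
        state$y[j] <- detections$y[i]
        state$countdown[j] <- NA_integer_
      }
    }
  }
  # new objects
  new_idx <- which(is.na(assignment))
  for (i in new_idx) {
    assignment[i] <- state$next_id
    state$ids <- c(state$ids, state$next_id)
    state$x <- c(state$x, detections$x[i])
    state$y <- c(state$y, detections$y[i])
    state$countdown <- c(state$countdown, NA_integer_)
    state$next_id <- state$next_id + 1L
    matched_mem <- c(matched_mem, TRUE)
  }
  # missing objects: start or decrement countdown; delete at zero
  miss <- which(!matched_mem)
  drop <- integer(0)
  for (j in miss) {
    if (is.na(state$countdown[j])) {
      state$countdown[j] <- state$track_memory
    } else {
      state$countdown[j] <- state$countdown[j] - 1L
    }
    if (state$countdown[j] <= 0L) drop <- c(drop, j)
  }
  if (length(drop)) {
    state$ids <- state$ids[-drop]
    state$x <- state$x[-drop]
    state$y <- state$y[-drop]
    state$countdown <- state$countdown[-drop]
  }
  list(state = state, assignment = assignment)
}

#' Per-ID frame spans over a completed video
#'
#' Summarizes the tracker output so downstream filtering can see when an
#' object was re-labelled (e.g. lost for longer than the memory and
#' re-found as a new ID, which would otherwise double-count it).
#'
#' @param assignments list, one element per frame, each an integer vector
#'   of IDs assigned in that frame.
#' @return data.frame with columns id, first_frame, last_frame, n_frames
#'   (frames are 0-based).
#' @export
filter_new_tracks <- function(assignments) {
  if (!length(assignments) || !length(unlist(assignments))) {
    return(data.frame(id = integer(0), first_frame = integer(0),
                      last_frame = integer(0), n_frames = integer(0)))
  }
  frames <- rep(seq_along(assignments) - 1L,
                vapply(assignments, length, integer(1)))
  ids <- unlist(assignments)
  agg <- lapply(split(frames, ids), function(f) {
    c(first = min(f), last = max(f), n = length(f))
  })
  out <- data.frame(id = as.integer(names(agg)),
                    first_frame = vapply(agg, `[[`, integer(1), "first"),
                    last_frame = vapply(agg, `[[`, integer(1), "last"),
                    n_frames = vapply(agg, `[[`, integer(1), "n"))
  rownames(out) <- NULL
  out[order(out$id), , drop = FALSE]
}
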