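# Greedy nearest-neighbour linking of per-frame candidates into tracks.

#' Link per-frame candidates into spot tracks
#'
#' Frame-by-frame greedy nearest-neighbour assignment: candidate-track pairs
#' are matched in order of increasing displacement (ties broken in favour of
#' the brighter candidate), a match is allowed while the displacement is at
#' most `max_disp_px` and at most `max_gap_frames` frames were missed, each
#' candidate joins at most one track, and unmatched candidates seed new
#' tracks.
#'
#' @param candidates Data frame with `frame` (0-based), `row`, `col`,
#'   `summed_intensity` (as from [detect_stack()]).
#' @param max_disp_px Maximum per-link displacement in pixels.
#' @param max_gap_frames Maximum number of consecutive missed frames.
#' @return The input rows with a `track_id` column, ordered by track then
#'   frame. Frames within a track are strictly increasing.
#' @export
link_tracks <- function(candidates, max_disp_px = 5, max_gap_frames = 1) {
  req <- c("frame", "row", "col", "summed_intensity")
  stopifnot(all(req %in% names(candidates)), max_disp_px > 0,
            max_gap_frames >= 0)
  n <- nrow(candidates)
  if (n == 0) return(cbind(candidates, track_id = integer(0)))
  candidates <- candidates[order(candidates$frame), , drop = FALSE]
  track_id <- integer(n)
  # active track state
  act_id <- integer(0); act_row <- numeric(0); act_col <- numeric(0)
  act_frame <- integer(0)
  next_id <- 1L
  for (f in sort(unique(candidates$frame))) {
    idx <- which(candidates$frame == f)
    # drop expired tracks
    live <- act_frame >= f - 1L - max_gap_frames
    act_id <- act_id[live]; act_row <- act_row[live]
    act_col <- act_col[live]; act_frame <- act_frame[live]
    assigned_cand <- rep(FALSE, length(idx))
    if (length(act_id) > 0) {
      d <- sqrt(outer(act_row, candidates$row[idx], "-")^2 +
                outer(act_col, candidates$col[idx], "-")^2)
      pairs <- which(d <= max_disp_px, arr.ind = TRUE)
      if (nrow(pairs) > 0) {
        ord <- order(d[pairs],
                     -candidates$summed_intensity[idx[pairs[, 2]]])
        used_track <- rep(FALSE, length(act_id))
        for (k in ord) {
          ti <- pairs[k, 1]; ci <- pairs[k, 2]
          if (used_track[ti] || assigned_cand[ci]) next
          used_track[ti] <- TRUE
          assigned_cand[ci] <- TRUE
          track_id[idx[ci]] <- act_id[ti]
          act_row[ti] <- candidates$row[idx[ci]]
          act_col[ti] <- candidates$col[idx[ci]]
          act_frame[ti] <- f
        }
      }
    }
    for (ci in which(!assigned_cand)) {
      track_id[idx[ci]] <- next_id
      act_id <- c(act_id, next_id)
      act_row <- c(act_row, candidates$row[idx[ci]])
      act_col <- c(act_col, candidates$col[idx[ci]])
      act_frame <- c(act_frame, f)
      next_id <- next_id + 1L
    }
  }
  out <- cbind(candidates, track_id = track_id)
  out <- out[order(out$track_id, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  out
}
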