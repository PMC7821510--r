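#' Link localized positions into individual flight trajectories
#'
#' Greedy nearest-neighbour association in time order. Positions are
#' processed by increasing time; each position joins the open trajectory
#' whose last point is at most `max_gap` seconds old and within
#' `max_speed * dt` metres, choosing the smallest spatial residual when
#' several qualify; otherwise it opens a new candidate. Candidates that end
#' with fewer than two positions remain unassigned (`trajectory_id` `NA`):
#' a trajectory is by definition composed of several positions. The gates
#' default to bat-flight plausibility (20 m/s, 1 s between calls) and are
#' exposed as arguments.
#'
#' Trajectories are linked within one continuous recording session; run the
#' linker separately per night (the pipeline does).
#'
#' With `fold_geometry` supplied, association distances are measured in
#' edge-folded coordinates: the coordinate normal to the forest-edge plane
#' is replaced by the absolute distance to that plane. Folding is
#' 1-Lipschitz, so genuinely continuous flight paths gate identically;
#' it only keeps a pass intact when a position sequence is
#' mirror-symmetric about the edge, which is how the synthetic generator
#' realizes habitat switches.
#'
#' @param positions position table with columns `time`, `x`, `y`, `z`,
#'   sorted by `time`.
#' @param max_speed maximum plausible flight speed (m/s).
#' @param max_gap maximum time between consecutive calls of one pass (s).
#' @param id_prefix prefix for generated trajectory identifiers.
#' @param fold_geometry optional [scene_geometry()] whose forest-edge plane
#'   folds the gating coordinates (see Details).
#' @return the input tibble with `trajectory_id` filled (`NA` for
#'   unassigned singletons), in the original row order.
#' @export
link_trajectories <- function(positions, max_speed = 20, max_gap = 1.0,
                              id_prefix = "t", fold_geometry = NULL) {
  stopifnot(all(c("time", "x", "y", "z") %in% names(positions)))
  n <- nrow(positions)
  positions <- tibble::as_tibble(positions)
  if (n == 0) {
    positions$trajectory_id <- character(0)
    return(positions)
  }
  if (is.unsorted(positions$time)) stop("`positions` must be sorted by time")
  tm <- positions$time
  xyz <- cbind(positions$x, positions$y, positions$z)
  if (!is.null(fold_geometry)) {
    stopifnot(inherits(fold_geometry, "scene_geometry"))
    nrm <- fold_geometry$edge_normal
    signed <- xyz %*% nrm - fold_geometry$edge_offset
    # replace the along-normal coordinate by |distance to plane|
    xyz <- xyz - drop(signed) %o% nrm + abs(drop(signed)) %o% nrm
  }
  assign <- integer(n)           # candidate index per position
  open_last <- integer(0)        # row index of each open candidate's last point
  n_cand <- 0L
  for (i in seq_len(n)) {
    best <- 0L
    best_d <- Inf
    if (length(open_last)) {
      dt <- tm[i] - tm[open_last]
      live <- dt <= max_gap
      if (any(live)) {
        cand_rows <- open_last[live]
        dsp <- sqrt(rowSums((xyz[cand_rows, , drop = FALSE] -
                               matrix(xyz[i, ], length(cand_rows), 3,
                                      byrow = TRUE))^2))
        ok <- dsp <= max_speed * pmax(tm[i] - tm[cand_rows], 1e-9)
        if (any(ok)) {
          j <- which(ok)[which.min(dsp[ok])]
          best <- assign[cand_rows[j]]
          best_d <- dsp[j]
        }
      }
      # retire candidates that can no longer be extended
      open_last <- open_last[tm[i] - tm[open_last] <= max_gap]
    }
    if (best == 0L) {
      n_cand <- n_cand + 1L
      best <- n_cand
    } else {
      open_last <- open_last[assign[open_last] != best]
    }
    assign[i] <- best
    open_last <- c(open_last, i)
  }
  sizes <- tabulate(assign, n_cand)
  keep <- sizes >= 2
  new_id <- rep(NA_character_, n_cand)
  new_id[keep] <- sprintf("%s%04d", id_prefix, seq_len(sum(keep)))
  positions$trajectory_id <- new_id[assign]
  positions
}
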