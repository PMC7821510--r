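#' Segment call detections into five-second files
#'
#' Recordings are cut into consecutive five-second intervals — long enough
#' to cover an average bat pass — and species assignment then operates per
#' interval. Binning is half-open, `[t, t + 5)`, anchored at the start of
#' the recording (the earliest call time).
#'
#' @param calls table with a time column (`time` or `t_emit`), time-sorted.
#' @param window window length (s).
#' @return the input tibble with an integer `file_id` column (0-based
#'   window index).
#' @export
segment_five_seconds <- function(calls, window = 5) {
  calls <- tibble::as_tibble(calls)
  tcol <- intersect(c("time", "t_emit", "t"), names(calls))[1]
  if (is.na(tcol)) stop("`calls` must have a time column ('time', 't_emit' or 't')")
  if (nrow(calls) == 0) {
    calls$file_id <- integer(0)
    return(calls)
  }
  tm <- calls[[tcol]]
  if (is.unsorted(tm)) stop("`calls` must be sorted by time")
  calls$file_id <- as.integer(floor((tm - tm[1]) / window))
  calls
}

#' Assign species groups from peak frequency within five-second files
#'
#' Stand-in for an acoustic classifier: each call is labelled by the
#' non-overlapping peak-frequency band containing it (defaults:
#' *Eptesicus/Nyctalus* 18–32 kHz, *Myotis/Plecotus* 33–41 kHz,
#' *Pipistrellus* 42–55 kHz). When calls of different groups occur within
#' the same five-second file, the calls of each band are further split into
#' spatially continuous series using the trajectory-linking gates, so that
#' each series of sequential positions carries one label. Calls outside
#' every band are left unclassified (`NA`).
#'
#' @param calls table with columns `peak_freq` (kHz), `file_id` (from
#'   [segment_five_seconds()]), a time column, and — when positions are
#'   available — `x`, `y`, `z` for the continuity split.
#' @param bands named list of `c(lo, hi)` kHz bands (closed intervals).
#' @param max_speed,max_gap continuity gates, as in [link_trajectories()].
#' @return the input tibble with `species_group` and `series_id` columns.
#' @export
assign_species_groups <- function(calls,
                                  bands = sim_config()$peak_freq_bands,
                                  max_speed = 20, max_gap = 1.0) {
  calls <- tibble::as_tibble(calls)
  stopifnot(all(c("peak_freq", "file_id") %in% names(calls)))
  bm <- do.call(rbind, bands)
  o <- order(bm[, 1])
  if (length(bands) > 1 && any(bm[o, 1][-1] < bm[o, 2][-length(bands)]))
    stop("`bands` must not overlap")
  grp <- rep(NA_character_, nrow(calls))
  for (g in names(bands))
    grp[!is.na(calls$peak_freq) &
          calls$peak_freq >= bands[[g]][1] &
          calls$peak_freq <= bands[[g]][2]] <- g
  calls$species_group <- grp

  tcol <- intersect(c("time", "t_emit", "t"), names(calls))[1]
  have_xyz <- all(c("x", "y", "z") %in% names(calls))
  series <- rep(NA_character_, nrow(calls))
  counter <- 0L
  for (f in unique(calls$file_id)) {
    for (g in names(bands)) {
      idx <- which(calls$file_id == f & !is.na(grp) & grp == g)
      if (!length(idx)) next
      counter <- counter + 1L
      if (length(idx) == 1L || !have_xyz) {
        series[idx] <- sprintf("s%05d", counter)
        next
      }
      # split a band's calls into spatially continuous series
      tm <- calls[[tcol]][idx]
      dxyz <- sqrt(diff(calls$x[idx])^2 + diff(calls$y[idx])^2 +
                     diff(calls$z[idx])^2)
      dt <- diff(tm)
      brk <- dt > max_gap | dxyz > max_speed * pmax(dt, 1e-9)
      sid <- counter + c(0L, cumsum(brk))
      series[idx] <- sprintf("s%05d", sid)
      counter <- max(sid)
    }
  }
  calls$series_id <- series
  calls
}
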