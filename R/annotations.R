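# Laughter annotation parsing and relative-duration computation.
#
# Intervals follow a half-open [onset, offset) convention: touching intervals
# merge, and lengths add without double counting.

#' Parse a tab-delimited annotation export
#'
#' Reads ELAN-style exported annotations with columns \code{participant},
#' \code{tier}, \code{onset_s}, \code{offset_s}. Rows are validated
#' (\code{offset > onset >= 0}), sorted, and within-participant overlaps are
#' merged.
#'
#' @param path file path to the tab-delimited export.
#' @param participants optional character vector of known participant ids;
#'   unknown ids raise an error when supplied.
#' @return Named list of per-participant data frames (onset_s, offset_s).
#' @export
parse_annotations <- function(path, participants = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("participant", "tier", "onset_s", "offset_s")
  if (!all(need %in% names(df)))
    stop_input("annotation file must have columns ", paste(need, collapse = ", "))
  validate_intervals(df[, c("onset_s", "offset_s")], rows = seq_len(nrow(df)))
  if (!is.null(participants)) {
    unknown <- setdiff(unique(df$participant), participants)
    if (length(unknown))
      stop_input("unknown participant(s): ", paste(unknown, collapse = ", "))
  }
  lapply(split(df[, c("onset_s", "offset_s")], df$participant),
         merge_interval_df)
}

# validate interval rows with informative line numbers
validate_intervals <- function(iv, rows = NULL) {
  if (nrow(iv) == 0) return(invisible(iv))
  bad <- which(!(iv$offset_s > iv$onset_s) | iv$onset_s < 0 |
                 !is.finite(iv$onset_s) | !is.finite(iv$offset_s))
  if (length(bad)) {
    where <- if (is.null(rows)) bad else rows[bad]
    stop_input("invalid interval(s) (need 0 <= onset < offset) at row(s) ",
               paste(where, collapse = ", "))
  }
  invisible(iv)
}

#' Union of two participants' laughter tracks
#'
#' Merges the two interval lists into the set of time periods during which at
#' least one participant was laughing; the dyad's total laughter duration is
#' the summed length of that union.
#'
#' @param track_a,track_b data frames with onset_s, offset_s (validated).
#' @return List with \code{intervals} (merged data frame) and \code{total_s}.
#' @export
dyad_union <- function(track_a, track_b) {
  iv <- rbind(track_a[, c("onset_s", "offset_s")],
              track_b[, c("onset_s", "offset_s")])
  merged <- merge_interval_df(iv)
  list(intervals = merged,
       total_s = if (nrow(merged)) sum(merged$offset_s - merged$onset_s) else 0)
}

#' Phase window constructor / lookup
#'
#' @param phase phase label.
#' @param timeline data frame from \code{\link{phase_timeline}}, or NULL to
#'   pass explicit \code{start_s}, \code{end_s}, \code{preonset_s}.
#' @param start_s,end_s,preonset_s explicit window coordinates (session time).
#' @return A list of class \code{phase_window}.
#' @export
phase_window <- function(phase, timeline = NULL, start_s = NULL, end_s = NULL,
                         preonset_s = 0) {
  if (!is.null(timeline)) {
    row <- timeline[timeline$phase == phase, ]
    if (nrow(row) != 1) stop_input("phase not found in timeline: ", phase)
    start_s <- row$start_s; end_s <- row$end_s; preonset_s <- row$preonset_s
  }
  if (end_s <= start_s) stop_input("phase window must have end_s > start_s")
  if (start_s - preonset_s < 0) stop_input("pre-onset extends before time 0")
  structure(list(phase = phase, start_s = start_s, end_s = end_s,
                 preonset_s = preonset_s), class = "phase_window")
}

#' Assign intervals to phases
#'
#' Each interval is clipped to the extended window
#' \code{[start - preonset, end)} of every phase it intersects. Because the
#' pre-onset extension covers the gap before a task, laughter occurring
#' between two tasks falls into the subsequent phase's window by
#' construction. Portions outside all extended windows are dropped (and
#' reported via the \code{"dropped_s"} attribute).
#'
#' @param intervals data frame with onset_s, offset_s.
#' @param windows list of \code{\link{phase_window}} objects, chronologically
#'   ordered and non-overlapping after extension.
#' @return Named list (by phase) of clipped interval data frames.
#' @export
assign_to_phase <- function(intervals, windows) {
  validate_intervals(intervals)
  exts <- lapply(windows, function(w)
    c(w$start_s - w$preonset_s, w$end_s))
  if (length(exts) > 1) {
    for (i in seq_along(exts)[-1])
      if (exts[[i]][1] < exts[[i - 1]][2])
        stop_input("extended phase windows overlap or are out of order")
  }
  out <- list()
  covered <- 0
  for (i in seq_along(windows)) {
    w <- exts[[i]]
    on <- pmax(intervals$onset_s, w[1])
    off <- pmin(intervals$offset_s, w[2])
    keep <- off > on
    clipped <- data.frame(onset_s = on[keep], offset_s = off[keep])
    covered <- covered + if (nrow(clipped)) sum(clipped$offset_s - clipped$onset_s) else 0
    out[[windows[[i]]$phase]] <- merge_interval_df(clipped)
  }
  total <- if (nrow(intervals)) sum(intervals$offset_s - intervals$onset_s) else 0
  attr(out, "dropped_s") <- max(0, total - covered)
  out
}

#' Relative laughter duration within a phase window
#'
#' Union length of the (already clipped) intervals divided by the length of
#' the extended window, \code{end - start + preonset}; a proportion in
#' [0, 1].
#'
#' @param phase_intervals clipped interval data frame.
#' @param window a \code{\link{phase_window}}.
#' @return Proportion of the extended window covered by laughter.
#' @export
relative_duration <- function(phase_intervals, window) {
  W <- window$end_s - window$start_s + window$preonset_s
  if (W <= 0) stop_input("zero-length phase window")
  merged <- merge_interval_df(phase_intervals)
  tot <- if (nrow(merged)) sum(merged$offset_s - merged$onset_s) else 0
  min(tot / W, 1)
}

#' Per-dyad relative laughter durations (LBMP, LBFI)
#'
#' Computes, for every dyad, the dyad-union laughter intervals per phase and
#' the relative duration within each extended phase window. With the default
#' two-phase plan the columns are \code{lbmp} (manipulation) and \code{lbfi}
#' (free interaction).
#'
#' @param annotations long data frame with dyad_id, participant, onset_s,
#'   offset_s (two participants per dyad).
#' @param phase_plan phase plan data frame (see \code{\link{sim_config}}).
#' @param dyad_ids optional vector of dyad ids to report (so dyads without
#'   any laughter still get a zero row).
#' @return Data frame: dyad_id, one relative-duration column per phase
#'   (named \code{lbmp}/\code{lbfi} for the default phases, otherwise
#'   \code{rel_<phase>}), and total seconds per phase.
#' @export
dyad_behavior <- function(annotations, phase_plan = default_phase_plan(),
                          dyad_ids = NULL) {
  tl <- phase_timeline(phase_plan)
  windows <- lapply(tl$phase, phase_window, timeline = tl)
  dyads <- dyad_ids %||% unique(annotations$dyad_id)
  short <- function(ph) switch(ph, manipulation = "lbmp",
                               free_interaction = "lbfi",
                               paste0("rel_", ph))
  rows <- lapply(dyads, function(d) {
    sub <- annotations[annotations$dyad_id == d, ]
    ps <- unique(sub$participant)
    tracks <- lapply(ps, function(p)
      merge_interval_df(sub[sub$participant == p, c("onset_s", "offset_s")]))
    row <- list(dyad_id = d)
    for (i in seq_along(windows)) {
      w <- windows[[i]]
      per_phase <- lapply(tracks, function(tr) assign_to_phase(tr, list(w))[[w$phase]])
      u <- if (length(per_phase) == 0) {
        data.frame(onset_s = numeric(0), offset_s = numeric(0))
      } else if (length(per_phase) == 1) {
        per_phase[[1]]
      } else {
        Reduce(function(a, b) dyad_union(a, b)$intervals, per_phase)
      }
      row[[short(w$phase)]] <- relative_duration(u, w)
      row[[paste0("total_", w$phase, "_s")]] <-
        if (nrow(u)) sum(u$offset_s - u$onset_s) else 0
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
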