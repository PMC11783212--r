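#' Screen a structure against representative structures
#'
#' One [align_structures()] call per representative; the screening TM-score is
#' normalized by the representative's length (`tm_norm_b` with the
#' representative as `b`), so the representative acts as a fixed yardstick
#' across queries of different lengths. The tier follows the best TM:
#' `below` (< 0.5), `moderate` (0.5 to 0.7 inclusive), `high` (> 0.7).
#'
#' @param m Query `StructureModel`.
#' @param reps Non-empty list of representative `StructureModel`s.
#' @return A `ScreenResult`: list with `id`, `tm_per_rep` (named numeric),
#'   `best_tm`, `tier`.
#' @export
screen <- function(m, reps) {
  if (!length(reps)) stop("need at least one representative")
  rep_ids <- vapply(reps, function(r) r$id, "")
  tm <- vapply(reps, function(r) align_structures(m, r)$tm_norm_b, 0)
  names(tm) <- rep_ids
  best <- max(tm)
  tier <- if (best < 0.5) "below" else if (best > 0.7) "high" else "moderate"
  structure(list(id = m$id, tm_per_rep = tm, best_tm = best, tier = tier),
            class = "ScreenResult")
}

#' Screen every member of a StructureSet
#' @param s `StructureSet`.
#' @param reps List of representative `StructureModel`s.
#' @param verbose Log progress.
#' @return List of `ScreenResult`, one per member.
#' @export
screen_set <- function(s, reps, verbose = FALSE) {
  out <- vector("list", length(s$members))
  for (i in seq_along(s$members)) {
    out[[i]] <- screen(s$members[[i]], reps)
    if (verbose && i %% 50L == 0L)
      log_msg("INFO", sprintf("screen: %d / %d", i, length(s$members)))
  }
  names(out) <- names(s$members)
  out
}

#' Threshold tally of screen results
#'
#' `counts[t, r]` = number of structures with TM strictly greater than
#' threshold `t` against at least `r` representatives. Monotone
#' non-increasing along both axes.
#'
#' @param results List of `ScreenResult` screened against the same
#'   representative set.
#' @param thresholds TM thresholds (default 0.5, 0.6, 0.7).
#' @param min_reps Minimum representative counts (default 1..4, truncated to
#'   the number of representatives).
#' @return A `ThresholdTally`: integer matrix with thresholds as rows and
#'   min_reps as columns.
#' @export
tally <- function(results, thresholds = c(0.5, 0.6, 0.7), min_reps = 1:4) {
  if (length(results)) {
    rep_sets <- unique(lapply(results, function(r) names(r$tm_per_rep)))
    if (length(rep_sets) != 1) stop("inconsistent representative sets")
    min_reps <- min_reps[min_reps <= length(rep_sets[[1]])]
  }
  M <- matrix(0L, length(thresholds), length(min_reps),
              dimnames = list(paste0(">", thresholds),
                              paste0(">=", min_reps)))
  for (res in results) {
    for (ti in seq_along(thresholds)) {
      npass <- sum(res$tm_per_rep > thresholds[ti])
      M[ti, ] <- M[ti, ] + as.integer(npass >= min_reps)
    }
  }
  structure(M, class = c("ThresholdTally", "matrix"))
}

#' Two-representative scatter table
#'
#' One row per screened structure with its TM against two chosen
#' representatives plus an optional family label — the data behind
#' representative-vs-representative scatter plots.
#'
#' @param results List of `ScreenResult`.
#' @param rep_x,rep_y Representative ids (must be in every result).
#' @param labels Optional named character vector id -> family label.
#' @return Data frame: id, tm_x, tm_y, family.
#' @export
two_rep_scatter <- function(results, rep_x, rep_y, labels = NULL) {
  do.call(rbind, lapply(results, function(r) {
    if (!all(c(rep_x, rep_y) %in% names(r$tm_per_rep)))
      stop("unknown representative id")
    data.frame(id = r$id, tm_x = unname(r$tm_per_rep[rep_x]),
               tm_y = unname(r$tm_per_rep[rep_y]),
               family = if (is.null(labels)) NA_character_
                        else unname(labels[r$id]),
               stringsAsFactors = FALSE)
  }))
}

#' Screen results as a flat table
#' @param results List of `ScreenResult`.
#' @return Data frame: id, one tm_ column per representative, best_tm, tier.
#' @export
screen_table <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    row <- data.frame(id = r$id, stringsAsFactors = FALSE)
    for (rid in names(r$tm_per_rep))
      row[[paste0("tm_", rid)]] <- unname(r$tm_per_rep[rid])
    row$best_tm <- r$best_tm
    row$tier <- r$tier
    row
  }))
}
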