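# Preprocessing: raw detection/recovery records -> encounter histories on the
# occasion grid, plus the cleanup rules (flank deletion, single-outside-record
# removal, censoring at translocation).

# Internal observation coding, shared by both layouts (subarea-2 codes unused
# in the one-area layout): 1 detected sub1, 2 recovered dead sub1, 3 detected
# sub2, 4 recovered dead sub2, 5 detected outside, 6 recovered dead outside,
# 7 not detected.
OBS_ND <- 7L

SUBAREA_LEVELS <- c("sub1", "sub2", "outside")

area_index <- function(subarea) {
  idx <- match(subarea, SUBAREA_LEVELS)
  if (anyNA(idx)) {
    stop("unknown subarea label(s): ",
         paste(unique(subarea[is.na(idx)]), collapse = ", "))
  }
  idx
}

#' Observation code labels for a layout
#'
#' @param layout `"two_subarea"` or `"one_area"`.
#' @return named integer vector mapping code labels to internal code values.
#' @export
obs_codes <- function(layout = c("two_subarea", "one_area")) {
  layout <- match.arg(layout)
  if (layout == "two_subarea") {
    c(detected_alive_sub1 = 1L, recovered_dead_sub1 = 2L,
      detected_alive_sub2 = 3L, recovered_dead_sub2 = 4L,
      detected_alive_outside = 5L, recovered_dead_outside = 6L,
      not_detected = 7L)
  } else {
    c(detected_alive_inside = 1L, recovered_dead_inside = 2L,
      detected_alive_outside = 5L, recovered_dead_outside = 6L,
      not_detected = 7L)
  }
}

#' Bin dated records of one individual into occasion codes
#'
#' Maps each record to the occasion containing its date. Multiple detections
#' in the same subarea and occasion collapse to one code. When an individual
#' is detected in more than one subarea within an occasion, the subarea of the
#' chronologically last detection is used and the conflict is logged. A
#' dead-recovery record takes precedence over alive detections in the same
#' occasion.
#'
#' @param records data frame with columns `date`, `subarea`
#'   (`"sub1"|"sub2"|"outside"`) and optionally `dead` (logical; carcass
#'   recovery rows).
#' @param grid an [occasion_grid()].
#' @return integer vector of internal observation codes (length
#'   `grid$n_occasions`), with attribute `"conflicts"` listing occasions where
#'   detections spanned several subareas.
#' @export
bin_to_occasions <- function(records, grid) {
  y <- rep(OBS_ND, grid$n_occasions)
  if (nrow(records) == 0L) return(y)
  if (is.null(records$dead)) records$dead <- FALSE
  occ <- occasion_of_date(grid, records$date)
  area <- area_index(records$subarea)
  conflicts <- integer(0)
  for (t in unique(occ)) {
    sel <- occ == t
    if (any(records$dead[sel])) {        # dead recovery outranks detections
      a <- area[sel & records$dead][1L]
      y[t] <- 2L * a
      next
    }
    areas_t <- area[sel]
    if (length(unique(areas_t)) > 1L) {
      conflicts <- c(conflicts, t)
      ord <- order(as.Date(records$date[sel]))
      a <- areas_t[ord[length(ord)]]     # chronologically last detection
    } else {
      a <- areas_t[1L]
    }
    y[t] <- 2L * a - 1L
  }
  attr(y, "conflicts") <- conflicts
  y
}

#' Delete the less abundant single-flank group
#'
#' Individuals identified from one flank only cannot be matched across sides,
#' so a lynx may appear as two pseudo-individuals. Keeping all of them biases
#' survival downwards; deleting all single-flank individuals biases it too.
#' The rule applied here keeps every both-flank individual and deletes, among
#' single-flank individuals, the whole group (left-only or right-only) with
#' fewer individuals. Ties are broken by deleting the left-only group.
#'
#' @param flanks data frame with columns `id` and `flank`
#'   (`"both"|"left"|"right"`).
#' @return list with `retained_ids`, `deleted_ids`, `deleted_side` (`"left"`,
#'   `"right"` or `NA` when nothing was deleted) and a one-row `report` of
#'   group counts.
#' @export
filter_single_flanks <- function(flanks) {
  stopifnot(all(flanks$flank %in% c("both", "left", "right")))
  flanks <- flanks[!duplicated(flanks$id), , drop = FALSE]
  n_both <- sum(flanks$flank == "both")
  n_left <- sum(flanks$flank == "left")
  n_right <- sum(flanks$flank == "right")
  if (n_left == 0L && n_right == 0L) {
    side <- NA_character_
  } else if (n_left <= n_right) {        # tie deletes the left-only group
    side <- "left"
  } else {
    side <- "right"
  }
  deleted <- if (is.na(side)) character(0) else flanks$id[flanks$flank == side]
  list(
    retained_ids = setdiff(flanks$id, deleted),
    deleted_ids = deleted,
    deleted_side = side,
    report = data.frame(n_both = n_both, n_left_only = n_left,
                        n_right_only = n_right, n_deleted = length(deleted),
                        deleted_side = if (is.na(side)) "none" else side)
  )
}

#' Apply per-individual record cleanup rules
#'
#' Three rules: (1) an individual detected outside the study population in
#' exactly one occasion, with inside detections both before and after, is
#' treated as if it had stayed inside — the single outside record is removed;
#' (2) occasions at and after the translocation censor occasion are dropped
#' from the likelihood (history truncated); (3) individuals whose first known
#' record is the capture for translocation are excluded.
#'
#' @param history an encounter history list with elements `y` (internal
#'   codes), `first`, `last` (last occasion in the likelihood window: trailing
#'   non-detections are informative, so this is the end of the study, the
#'   occasion of the dead recovery, or the censor cut), and optionally
#'   `censor_occasion` and `translocation_first`.
#' @return the history with `y`, `first`, `last`, and flags `excluded` and
#'   `outside_removed` updated.
#' @export
apply_record_cleanup <- function(history) {
  history$excluded <- isTRUE(history$translocation_first)
  history$outside_removed <- FALSE
  y <- history$y
  outside_det <- which(y == 5L)
  inside_det <- which(y %in% c(1L, 3L))
  if (length(outside_det) == 1L &&
      any(inside_det < outside_det) && any(inside_det > outside_det)) {
    y[outside_det] <- OBS_ND
    history$outside_removed <- TRUE
  }
  history$y <- y
  if (!is.null(history$censor_occasion) && !is.na(history$censor_occasion)) {
    cut <- history$censor_occasion - 1L
    if (cut < history$last) {
      if (cut < length(history$y))
        history$y[(cut + 1L):length(history$y)] <- OBS_ND
      history$last <- cut
    }
  }
  observed <- which(history$y != OBS_ND)
  if (length(observed) == 0L || history$last < observed[1L]) {
    history$excluded <- TRUE
  } else {
    history$first <- observed[1L]
  }
  history
}

#' Build encounter histories from record tables
#'
#' Bins detections and recoveries on the occasion grid, assigns per-occasion
#' age classes and telemetry status, applies the cleanup rules, and drops
#' never-detected or excluded individuals. Recovery is terminal: a detection
#' after a dead recovery is an inconsistent record set and raises an error.
#'
#' @param detections data frame `id, date, subarea, source, flank`.
#' @param recoveries data frame `id, date, subarea` (only rows whose `id`
#'   appears among monitored individuals are attached to histories).
#' @param individuals data frame `id, sex ("F"|"M"|"unknown"),
#'   birth_lynx_year (NA ok), censor_occasion (NA ok), translocation_first
#'   (logical), telemetry` (string of 1-based occasion ranges like
#'   `"12-20;30-35"`, or `""`).
#' @param grid an [occasion_grid()].
#' @return list with `histories` (named list) and `report` (cleanup counts).
#' @export
build_histories <- function(detections, recoveries, individuals, grid) {
  histories <- list()
  n_outside_removed <- 0L
  n_excluded_transloc <- 0L
  n_never_detected <- 0L
  n_recovery_only <- 0L
  yr_of_occ <- grid$table$lynx_year
  for (k in seq_len(nrow(individuals))) {
    ind <- individuals[k, ]
    det <- detections[detections$id == ind$id, , drop = FALSE]
    det$dead <- rep(FALSE, nrow(det))
    rec <- recoveries[recoveries$id == ind$id, , drop = FALSE]
    if (nrow(rec) > 0L) {
      rec <- data.frame(id = rec$id, date = rec$date, subarea = rec$subarea,
                        dead = TRUE)
      det <- rbind(det[, c("id", "date", "subarea", "dead")], rec)
    } else if (nrow(det) > 0L) {
      det <- det[, c("id", "date", "subarea", "dead")]
    }
    y <- bin_to_occasions(det, grid)
    observed <- which(y != OBS_ND)
    if (length(observed) == 0L) { n_never_detected <- n_never_detected + 1L; next }
    first <- observed[1L]
    if (y[first] %in% c(2L, 4L, 6L)) {
      # never seen alive: such carcasses inform the age-at-death sample only
      n_recovery_only <- n_recovery_only + 1L
      next
    }
    dead_occ <- which(y %in% c(2L, 4L, 6L))
    if (length(dead_occ) > 1L)
      stop("individual ", ind$id, " has multiple dead-recovery occasions")
    if (length(dead_occ) == 1L && any(observed > dead_occ))
      stop("individual ", ind$id, " has detections after its dead recovery")
    # likelihood window ends at the recovery occasion or the end of the study
    last <- if (length(dead_occ) == 1L) dead_occ else grid$n_occasions
    tele <- rep(0L, grid$n_occasions)
    if (!is.null(ind$telemetry) && !is.na(ind$telemetry) &&
        nzchar(ind$telemetry)) {
      for (rg in strsplit(ind$telemetry, ";", fixed = TRUE)[[1L]]) {
        ab <- as.integer(strsplit(rg, "-", fixed = TRUE)[[1L]])
        tele[ab[1L]:ab[2L]] <- 1L
      }
    }
    h <- list(
      id = ind$id,
      sex = match(ind$sex, c("F", "M")),   # NA = unknown
      birth_lynx_year = ind$birth_lynx_year,
      first = first, last = last, y = as.integer(y),
      censor_occasion = if (is.null(ind$censor_occasion)) NA_integer_ else
        ind$censor_occasion,
      translocation_first = isTRUE(ind$translocation_first),
      tele = tele
    )
    h <- apply_record_cleanup(h)
    if (h$outside_removed) n_outside_removed <- n_outside_removed + 1L
    if (h$excluded) {
      if (isTRUE(h$translocation_first))
        n_excluded_transloc <- n_excluded_transloc + 1L
      next
    }
    first_year <- yr_of_occ[h$first]
    # occasions before birth/first detection are never used in the
    # likelihood; clamp so the class is defined everywhere
    ref_year <- if (!is.na(h$birth_lynx_year)) h$birth_lynx_year else first_year
    h$age_class <- assign_age_class(rep(h$birth_lynx_year, grid$n_occasions),
                                    pmax(yr_of_occ, ref_year),
                                    rep(first_year, grid$n_occasions))
    histories[[ind$id]] <- h
  }
  list(histories = histories,
       report = data.frame(
         n_individuals_in = nrow(individuals),
         n_histories = length(histories),
         n_never_detected = n_never_detected,
         n_recovery_only = n_recovery_only,
         n_excluded_translocation_first = n_excluded_transloc,
         n_single_outside_removed = n_outside_removed))
}
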