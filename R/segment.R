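# Segmentation of twilight series into stationary periods and migration
# legs.  The underlying rule is the classic one for archival light loggers:
# a consistent run of similar sunrise and sunset times means the bird is
# stationary; a sudden, consistent change in either twilight means it moved.
# Here that visual rule becomes an explicit change-point analysis (filter,
# binary segmentation, velocity labelling, merge, boundary refinement); see
# detect_stationary_periods() for the steps and thresholds.

#' Extract twilight times from a raw light log
#'
#' Treats any light reading above `threshold` as daylight: for each calendar
#' day, sunrise is the time of the first such record and sunset the time of
#' the last.  This deliberately ignores the shape of the light curve; with a
#' threshold below the lowest daylight reading, false positives (light during
#' true night) are effectively impossible for a bird that does not use
#' artificially lit habitat, while false negatives (shading) produce the
#' familiar one-sided error of late sunrise / early sunset.
#'
#' @param light_log data.frame with columns `timestamp` (POSIXct, UTC) and
#'   `light` (arbitrary logger units).
#' @param threshold light value strictly above which a record counts as
#'   daylight; default -1 accepts every recorded light value > -1, i.e. any
#'   non-dark record.
#' @return data.frame with columns `date`, `sunrise_utc`, `sunset_utc`
#'   (decimal hours UTC; NA on all-dark days) and `missing` (logical, TRUE
#'   when a day has no above-threshold record).
#' @export
extract_twilights_from_light <- function(light_log, threshold = -1) {
  stopifnot(is.data.frame(light_log),
            all(c("timestamp", "light") %in% names(light_log)))
  if (nrow(light_log) == 0) stop("light log is empty")
  if (is.unsorted(light_log$timestamp))
    stop("light log records must be ordered in time")
  day <- as.Date(light_log$timestamp, tz = "UTC")
  hour <- as.numeric(light_log$timestamp -
                       as.POSIXct(paste(day, "00:00:00"), tz = "UTC"),
                     units = "hours")
  lit <- light_log$light > threshold
  days <- seq(min(day), max(day), by = "day")
  out <- data.frame(date = days, sunrise_utc = NA_real_,
                    sunset_utc = NA_real_, missing = TRUE)
  lit_day <- day[lit]
  lit_hour <- hour[lit]
  if (length(lit_day)) {
    sr <- tapply(lit_hour, lit_day, min)
    ss <- tapply(lit_hour, lit_day, max)
    idx <- match(as.Date(names(sr)), out$date)
    out$sunrise_utc[idx] <- as.numeric(sr)
    out$sunset_utc[idx] <- as.numeric(ss)
    out$missing[idx] <- FALSE
  }
  out
}

#' Correct linear clock drift
#'
#' Logger clocks drift; over a deployment the drift is assumed linear, so
#' each twilight time is shifted by the fraction of the total drift accrued
#' by that date.  A positive `total_drift` means the clock ran fast by that
#' many minutes at the end of the deployment (recorded times too late), so
#' times are shifted earlier.
#'
#' @param twilights data.frame with `date`, `sunrise_utc`, `sunset_utc`.
#' @param total_drift minutes of drift accumulated between `start` and `end`.
#' @param start,end deployment span; default to the twilight series range.
#' @return the twilight data.frame with corrected times.
#' @export
correct_clock_drift <- function(twilights, total_drift,
                                start = min(twilights$date),
                                end = max(twilights$date)) {
  span <- as.numeric(as.Date(end) - as.Date(start))
  frac <- if (span > 0)
    as.numeric(twilights$date - as.Date(start)) / span else 0
  shift_h <- frac * total_drift / 60
  twilights$sunrise_utc <- twilights$sunrise_utc - shift_h
  twilights$sunset_utc <- twilights$sunset_utc - shift_h
  twilights
}

#' Flag intervals within one week of an equinox
#'
#' Latitude from day length is unreliable in the days around March 20 and
#' September 22; analyses that depend on latitude are conventionally re-run
#' excluding stationary periods and legs that touch a window of one week
#' either side.
#'
#' @param start,end interval dates (may be equal for a single day).
#' @return logical: does the interval intersect Mar 13--27 or Sep 15--29 of
#'   any spanned year?
#' @export
flag_equinox <- function(start, end = start) {
  start <- as.Date(start); end <- as.Date(end)
  stopifnot(all(end >= start))
  mapply(function(s, e) {
    yrs <- seq(as.integer(format(as.Date(s, origin = "1970-01-01"), "%Y")),
               as.integer(format(as.Date(e, origin = "1970-01-01"), "%Y")))
    windows <- c(lapply(yrs, function(y)
      c(as.Date(sprintf("%d-03-13", y)), as.Date(sprintf("%d-03-27", y)))),
      lapply(yrs, function(y)
        c(as.Date(sprintf("%d-09-15", y)), as.Date(sprintf("%d-09-29", y)))))
    any(vapply(windows, function(w) s <= w[2] && e >= w[1], logical(1)))
  }, start, end, USE.NAMES = FALSE)
}

#' Segment a twilight series into stationary periods and migration legs
#'
#' Formalises the visual rule for archival light loggers -- a consistent run
#' of similar sunrise/sunset times means the bird is stationary, a sudden
#' consistent change means it moved -- as a change-point analysis in five
#' steps:
#' \enumerate{
#'   \item a 3-day moving minimum (sunrise) / maximum (sunset) strips the
#'     one-sided shading error;
#'   \item binary segmentation splits the filtered series wherever the
#'     contrast between the 5-day medians either side of a candidate day,
#'     after removing the locally estimated seasonal slope, exceeds
#'     `shift_threshold`;
#'   \item segments whose robust twilight velocity exceeds what seasonal
#'     change can produce (midpoint faster than `shift_threshold`/3 min/day,
#'     or day length faster than 0.8 x `shift_threshold`), or that are
#'     shorter than `min_stationary` days, are labelled migration;
#'   \item adjacent stationary runs separated by at most 3 days whose
#'     slope-adjusted levels agree within `cum_threshold`/2 over wide
#'     flanking windows are re-joined (a cluster of heavily shaded days can
#'     mimic a relocation);
#'   \item each boundary is refined day by day: a transition-zone day is
#'     claimed by the period whose level it matches (twilight midpoint
#'     within 2/3 of `shift_threshold`; least-shaded two-day day length
#'     within `shift_threshold`), and days matching neither side are the
#'     migration leg.
#' }
#'
#' The default `shift_threshold` of 15 minutes corresponds to a 3.75-degree
#' longitude shift (4 min/degree), just below the smallest relocation a
#' practised eye reliably picks out of a twilight plot (~17 min);
#' `cum_threshold` is the cumulative level change that declares movement
#' over a week-scale window; half of it is the merge tolerance in step 4.
#'
#' Detection uses only relative twilight levels, so it is invariant to a
#' constant clock offset.
#'
#' @param twilights data.frame with `date`, `sunrise_utc`, `sunset_utc`;
#'   days with NA twilights (polar or missing) inherit the state of the
#'   surrounding classified days.
#' @param shift_threshold minutes; per-day jump tolerance (default 15).
#' @param cum_threshold minutes; week-scale cumulative drift tolerance
#'   (default 30).
#' @param min_stationary minimum days for a stationary period (default 2).
#' @return data.frame with columns `date`, `state` ("stationary" or
#'   "migrating"), `period_id` (sequential id of the stationary period, NA
#'   while migrating) and `leg_id` (sequential id of the migration leg, NA
#'   while stationary).
#' @export
detect_stationary_periods <- function(twilights, shift_threshold = 15,
                                      cum_threshold = 30,
                                      min_stationary = 2) {
  stopifnot(nrow(twilights) >= min_stationary)
  ok <- !is.na(twilights$sunrise_utc) & !is.na(twilights$sunset_utc)
  sr <- twilights$sunrise_utc[ok] * 60   # minutes
  ss <- twilights$sunset_utc[ok] * 60
  day <- as.numeric(twilights$date[ok] - min(twilights$date))
  n <- length(sr)
  if (n < min_stationary) stop("too few valid twilight days to segment")

  # Shading is one-sided -- it can only delay the apparent sunrise and
  # advance the apparent sunset -- so a 3-day moving minimum on sunrise and
  # moving maximum on sunset strips most of it (the least-shaded day in the
  # window is closest to truth) while displacing a true relocation by at
  # most one day.
  rollw <- function(x, fun, h) vapply(seq_along(x), function(i)
    fun(x[max(1, i - h):min(length(x), i + h)]), numeric(1))
  srf <- rollw(sr, min, 1)
  ssf <- rollw(ss, max, 1)

  # --- binary segmentation on level contrasts --------------------------
  # Candidate change points are scored by the contrast between the 5-day
  # medians of the filtered twilights either side, after removing the
  # local seasonal slope (estimated from day-to-day differences clear of
  # the candidate transition).  The series is split recursively while the
  # best contrast exceeds shift_threshold.  Medians over 5 days make the
  # statistic robust to residual shading; the slope correction stops the
  # smooth seasonal change in twilight times from masquerading as
  # movement on long residences.
  local_contrast <- function(idx, j) {
    before <- idx[idx < j]; after <- idx[idx >= j]
    if (length(before) < min_stationary || length(after) < min_stationary)
      return(0)
    b <- utils::tail(before, 5); a <- utils::head(after, 5)
    guard <- c(idx[idx >= j - 8 & idx <= j - 3],
               idx[idx >= j + 2 & idx <= j + 7])
    con <- function(x) {
      d <- diff(x[idx]) / pmax(diff(day[idx]), 1)
      dg <- d[utils::head(idx, -1) %in% guard]
      slope <- if (length(dg) > 2) stats::median(dg) else 0
      dt <- stats::median(day[a]) - stats::median(day[b])
      abs(stats::median(x[a]) - stats::median(x[b]) - dt * slope)
    }
    max(con(srf), con(ssf))
  }
  split_run <- function(idx) {
    if (length(idx) < 2 * min_stationary) return(list(idx))
    cons <- vapply(idx, function(j) local_contrast(idx, j), numeric(1))
    j <- idx[which.max(cons)]
    if (max(cons) <= shift_threshold) return(list(idx))
    c(split_run(idx[idx < j]), split_run(idx[idx >= j]))
  }
  segs <- split_run(seq_len(n))

  # --- label each segment stationary or migrating ----------------------
  # A transit segment is one whose twilights move faster than seasonal
  # change can explain: the robust (median) day-to-day slope of either
  # twilight exceeds shift_threshold/3 min/day (5 min/day at the default,
  # about double the fastest seasonal rate at the study latitudes).
  # Segments shorter than the stationary minimum are transit by the
  # two-day rule.
  # Judged in the midpoint / day-length basis: the midpoint tracks
  # longitude only (its seasonal drift, the equation of time, stays under
  # ~0.3 min/day), so a modest rate threshold applies; day length drifts
  # seasonally up to ~8-10 min/day at high boreal latitudes in spring, so
  # it gets a looser one that only genuine latitude transits exceed.
  sl <- function(x, idx) abs(stats::median(diff(x[idx]) /
                                             pmax(diff(day[idx]), 1)))
  runs <- lapply(segs, function(idx) {
    transit <- length(idx) < min_stationary ||
      sl((srf + ssf) / 2, idx) > shift_threshold / 3 ||
      sl(ssf - srf, idx) > 0.8 * shift_threshold
    list(type = if (transit) "migrating" else "stationary", idx = idx)
  })

  # merge pass: two stationary runs separated by at most 3 days whose
  # twilight levels agree -- after allowing for the shared seasonal slope
  # across the gap -- are one residence briefly interrupted by noise
  repeat {
    st_pos <- which(vapply(runs, function(r) r$type == "stationary",
                           logical(1)))
    merged <- FALSE
    for (q in seq_len(max(0, length(st_pos) - 1))) {
      ka <- st_pos[q]; kb <- st_pos[q + 1]
      A <- runs[[ka]]$idx; B <- runs[[kb]]$idx
      if (min(B) - max(A) - 1 > 3) next
      # Wide (10-day) windows either side of the junction: a pseudo-step
      # from a run of heavily shaded days averages out over 10 days, while
      # a true relocation persists.  Seasonal slopes come from the same
      # windows, so smooth high-latitude change cancels in the comparison.
      ta <- utils::tail(A, 10); hb <- utils::head(B, 10)
      slope <- function(x, i) {
        s <- if (length(i) > 1)
          stats::median(diff(x[i]) / pmax(diff(day[i]), 1)) else 0
        max(-12, min(12, s))
      }
      dt <- stats::median(day[hb]) - stats::median(day[ta])
      gap_sr <- abs(stats::median(srf[hb]) - stats::median(srf[ta]) -
                      dt * mean(c(slope(srf, ta), slope(srf, hb))))
      gap_ss <- abs(stats::median(ssf[hb]) - stats::median(ssf[ta]) -
                      dt * mean(c(slope(ssf, ta), slope(ssf, hb))))
      if (max(gap_sr, gap_ss) > cum_threshold / 2) next
      runs[[ka]]$idx <- seq(min(A), max(B))
      for (kk in (ka + 1):kb) runs[[kk]]$idx <- integer(0)
      runs <- Filter(function(r) length(r$idx) > 0, runs)
      merged <- TRUE
      break
    }
    if (!merged) break
  }

  # refine boundaries: velocity segmentation places boundaries to within a
  # couple of days; each transition zone (up to three edge days of the two
  # flanking periods plus the migrating days between them) is then
  # re-classified day by day against the twilight levels of the two
  # periods, measured just outside the zone so seasonal drift cannot bias
  # the comparison.  A day is claimed by the side it matches within half
  # the threshold, using one-sided shading-stripping pairs that cannot look
  # across the boundary being tested; days matching neither side are
  # migration.
  for (refine_pass in 1) {
  st_pos <- which(vapply(runs, function(r) r$type == "stationary",
                         logical(1)))
  if (length(st_pos) >= 2) {
    lev <- function(idx) c(stats::median((srf[idx] + ssf[idx]) / 2),
                           stats::median(ssf[idx] - srf[idx]),
                           stats::median(day[idx]))
    for (q in seq_len(length(st_pos) - 1)) {
      ka <- st_pos[q]; kb <- st_pos[q + 1]
      A <- runs[[ka]]$idx; B <- runs[[kb]]$idx
      mids <- if (kb > ka + 1)
        sort(unlist(lapply(runs[(ka + 1):(kb - 1)], `[[`, "idx")))
      else integer(0)
      na_keep <- max(min_stationary, length(A) - 3)
      nb_keep <- max(min_stationary, length(B) - 3)
      Acore <- A[seq_len(na_keep)]
      Bcore <- utils::tail(B, nb_keep)
      zone <- sort(c(setdiff(A, Acore), mids, setdiff(B, Bcore)))
      if (!length(zone)) next
      lA <- lev(utils::tail(Acore, 5)); lB <- lev(utils::head(Bcore, 5))
      # A day matches a period when its twilight midpoint (longitude proxy;
      # one-sided shading cancels in it) sits within 2/3 of the threshold
      # of the period level, and the least-shaded day length over the day
      # and its period-side neighbour agrees with the level within the
      # threshold.  The two-day maximum strips the exponential shading tail
      # without letting the comparison look across the boundary by more
      # than one day.
      match_level <- function(j, l, side) {
        mid_j <- (sr[j] + ss[j]) / 2
        p <- if (side == "A") c(max(1, j - 1), j) else c(j, min(n, j + 1))
        dlen_p <- max(ss[p]) - min(sr[p])
        ok <- abs(mid_j - l[1]) <= 2 * shift_threshold / 3 &&
          abs(dlen_p - l[2]) <= shift_threshold
        score <- abs(mid_j - l[1]) + abs(dlen_p - l[2]) / 2
        c(ok, score)
      }
      mA <- vapply(zone, match_level, numeric(2), l = lA, side = "A")
      mB <- vapply(zone, match_level, numeric(2), l = lB, side = "B")
      side <- ifelse(mA[1, ] > 0 & (mB[1, ] == 0 | mA[2, ] <= mB[2, ]), "A",
                     ifelse(mB[1, ] > 0, "B", "M"))
      # periods are contiguous: A keeps its leading matches and B its
      # trailing ones, tolerating a single non-matching day (one heavily
      # shaded day inside a period should not clip its edge); everything
      # between is the leg
      lead_n <- function(v, want) {
        p <- 0; skipped <- 0
        for (i in seq_along(v)) {
          if (v[i] == want) p <- i
          else if (v[i] == "M" && skipped < 2 && any(v[-seq_len(i)] == want) &&
                     !any(v[seq_len(i)] != want & v[seq_len(i)] != "M"))
            skipped <- skipped + 1
          else break
        }
        p
      }
      nA <- lead_n(side, "A")
      nB <- lead_n(rev(side), "B")
      nB <- min(nB, length(side) - nA)
      runs[[ka]]$idx <- c(Acore, zone[seq_len(nA)])
      runs[[kb]]$idx <- sort(c(zone[seq_len(nB) + length(zone) - nB], Bcore))
      mid <- if (nA + nB < length(zone))
        zone[(nA + 1):(length(zone) - nB)] else integer(0)
      if (kb > ka + 1) {
        for (kk in (ka + 1):(kb - 1)) runs[[kk]]$idx <- integer(0)
        runs[[ka + 1]]$idx <- mid
      } else if (length(mid)) {
        runs <- append(runs, list(list(type = "migrating", idx = mid)),
                       after = ka)
        st_pos <- which(vapply(runs, function(r) r$type == "stationary",
                               logical(1)))
      }
    }
  }
  runs <- Filter(function(r) length(r$idx) > 0, runs)
  }

  # dissolve again: refinement may have shrunk a run below the minimum
  for (k in seq_along(runs))
    if (runs[[k]]$type == "stationary" &&
        length(runs[[k]]$idx) < min_stationary)
      runs[[k]]$type <- "migrating"

  state <- character(n); pid_of <- rep(NA_integer_, n)
  lid_of <- rep(NA_integer_, n)
  pid <- 0L; lid <- 0L; prev_type <- ""
  for (r in runs) {
    state[r$idx] <- r$type
    if (r$type == "stationary") {
      pid <- pid + 1L
      pid_of[r$idx] <- pid
    } else {
      if (prev_type != "migrating") lid <- lid + 1L
      lid_of[r$idx] <- lid
    }
    prev_type <- r$type
  }

  out <- data.frame(date = twilights$date, state = NA_character_,
                    period_id = NA_integer_, leg_id = NA_integer_)
  out$state[ok] <- state
  out$period_id[ok] <- pid_of
  out$leg_id[ok] <- lid_of
  # NA-twilight days (polar or missing) inherit the nearest previous
  # classified day (leading NAs take the first).  One exception: a gap
  # preceded by migration and followed by a stationary period is an Arctic
  # breeding residence whose midsummer has no twilights -- the bird was at
  # the site throughout, so the gap joins the following period.  Every day
  # is thus accounted for in exactly one state.
  classified <- which(!is.na(out$state))
  na_rows <- which(is.na(out$state))
  if (length(na_rows)) {
    src <- vapply(na_rows, function(k) {
      prev <- classified[classified < k]
      nxt <- classified[classified > k]
      if (!length(prev)) return(min(classified))
      if (length(nxt) &&
          out$state[max(prev)] == "migrating" &&
          out$state[min(nxt)] == "stationary") return(min(nxt))
      max(prev)
    }, integer(1))
    out$state[na_rows] <- out$state[src]
    out$period_id[na_rows] <- out$period_id[src]
    out$leg_id[na_rows] <- out$leg_id[src]
  }
  out
}

#' Stationary-period and leg boundaries at half-day resolution
#'
#' Migration start and end dates are recorded to the nearest half day: a
#' bird departs at the sunset of its last stationary day (+0.5) and arrives
#' by the sunrise of its first stationary day at the new site (+0.0).
#'
#' @param segments output of [detect_stationary_periods()].
#' @return data.frame, one row per stationary period: `period_id`, `start`,
#'   `end` (numeric days since the series start, in half-day units),
#'   `start_date`, `end_date`, `n_days`.
#' @export
period_boundaries <- function(segments) {
  st <- segments[segments$state == "stationary", ]
  if (nrow(st) == 0) return(data.frame(period_id = integer(0)))
  origin <- min(segments$date)
  agg <- lapply(split(st, st$period_id), function(d) {
    data.frame(period_id = d$period_id[1],
               start = as.numeric(min(d$date) - origin),
               end = as.numeric(max(d$date) - origin) + 0.5,
               start_date = min(d$date), end_date = max(d$date),
               n_days = nrow(d))
  })
  out <- do.call(rbind, agg)
  out[order(out$start), , drop = FALSE]
}
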