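#' Evenson intensity cut points for children
#'
#' Counts-per-minute thresholds from the child-specific calibration
#' literature: sedentary at or below 100 cpm, moderate at or above 2296 cpm,
#' vigorous at or above 4012 cpm. All thresholds are configurable.
#'
#' @param sedentary_cpm sedentary ceiling (counts/min).
#' @param moderate_cpm moderate floor (counts/min).
#' @param vigorous_cpm vigorous floor (counts/min).
#' @return named list of thresholds.
#' @export
evenson_cutpoints <- function(sedentary_cpm = 100, moderate_cpm = 2296,
                              vigorous_cpm = 4012) {
  list(sedentary_cpm = sedentary_cpm, moderate_cpm = moderate_cpm,
       vigorous_cpm = vigorous_cpm)
}

# scale cpm thresholds to the epoch length: floor for ceilings, ceiling for
# floors, so the per-epoch rule is never more permissive than the cpm rule
scale_cutpoints <- function(cutpoints, epoch_len = 10) {
  f <- 60 / epoch_len
  if (cutpoints$sedentary_cpm >= cutpoints$moderate_cpm)
    stop_("configuration error: non-monotone cut points (sedentary %.0f >= moderate %.0f)",
          cutpoints$sedentary_cpm, cutpoints$moderate_cpm)
  list(sedentary_max = floor(cutpoints$sedentary_cpm / f),
       mvpa_min = ceiling(cutpoints$moderate_cpm / f))
}

#' Detect accelerometer non-wear time
#'
#' Marks as non-wear every maximal window of total length at least
#' `window_min` minutes consisting of zero counts, allowing interruptions:
#' consecutive nonzero runs of at most `interruption_min` minutes are
#' absorbed into the window, while a longer nonzero run terminates it.
#' Windows begin and end on zero epochs. All other epochs are wear.
#'
#' @param counts non-negative integer counts, one per epoch.
#' @param epoch_len epoch length in seconds (default 10).
#' @param window_min minimum non-wear window length in minutes (default 60).
#' @param interruption_min maximum absorbable nonzero run in minutes
#'   (default 2).
#' @return logical wear mask (`TRUE` = wear), same length as `counts`.
#' @export
detect_nonwear <- function(counts, epoch_len = 10, window_min = 60,
                           interruption_min = 2) {
  n <- length(counts)
  if (n == 0) return(logical(0))
  if (any(counts < 0)) stop_("counts must be non-negative")
  per_min <- 60 / epoch_len
  win_e <- window_min * per_min
  int_e <- interruption_min * per_min
  r <- rle(counts == 0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  wear <- rep(TRUE, n)
  i <- 1
  while (i <= length(r$lengths)) {
    if (!r$values[i]) { i <- i + 1; next }
    # candidate window: runs i..j, extended across short interior interruptions
    j <- i
    total <- r$lengths[i]
    while (j + 2 <= length(r$lengths) &&
           r$lengths[j + 1] <= int_e && r$values[j + 2]) {
      total <- total + r$lengths[j + 1] + r$lengths[j + 2]
      j <- j + 2
    }
    if (total >= win_e) wear[starts[i]:ends[j]] <- FALSE
    i <- j + 2  # skip the terminating nonzero run
  }
  wear
}

#' Classify epochs into sedentary, light and MVPA intensity
#'
#' Scales counts-per-minute thresholds to the epoch length (for 10-s epochs,
#' cpm/6 with floor for the sedentary ceiling and ceiling for the moderate
#' floor) and assigns each epoch exactly one class. Boundaries are closed:
#' a count equal to the scaled sedentary ceiling is sedentary, and one equal
#' to the scaled moderate floor is MVPA.
#'
#' @inheritParams detect_nonwear
#' @param cutpoints thresholds from [evenson_cutpoints()].
#' @return factor with levels `sedentary`, `light`, `mvpa`.
#' @export
classify_epochs <- function(counts, cutpoints = evenson_cutpoints(),
                            epoch_len = 10) {
  thr <- scale_cutpoints(cutpoints, epoch_len)
  cls <- ifelse(counts <= thr$sedentary_max, "sedentary",
                ifelse(counts >= thr$mvpa_min, "mvpa", "light"))
  factor(cls, levels = c("sedentary", "light", "mvpa"))
}

#' Summarise one child-day of epoch data
#'
#' Computes wear and per-intensity minutes over wear epochs only (each epoch
#' contributes `epoch_len / 60` minutes) and flags the day valid when wear
#' time is at least `valid_min` minutes. Sedentary, light and MVPA minutes
#' always sum exactly to wear minutes.
#'
#' @param series one-day data frame with columns `child_id`, `day_id`,
#'   `weekend`, `counts`.
#' @param wear logical wear mask from [detect_nonwear()].
#' @param classes intensity factor from [classify_epochs()].
#' @param epoch_len epoch length in seconds.
#' @param valid_min minimum wear minutes for a valid day (default 500).
#' @return one-row data frame: `child_id`, `day_id`, `weekend`,
#'   `wear_minutes`, `sedentary_minutes`, `light_minutes`, `mvpa_minutes`,
#'   `valid`.
#' @export
summarize_day <- function(series, wear, classes, epoch_len = 10,
                          valid_min = 500) {
  n <- nrow(series)
  if (length(wear) != n || length(classes) != n)
    stop_("misaligned inputs: series has %d epochs, wear %d, classes %d",
          n, length(wear), length(classes))
  mins <- epoch_len / 60
  tab <- table(classes[wear])
  wear_minutes <- sum(wear) * mins
  data.frame(child_id = series$child_id[1],
             day_id = series$day_id[1],
             weekend = isTRUE(series$weekend[1]),
             wear_minutes = wear_minutes,
             sedentary_minutes = as.numeric(tab[["sedentary"]]) * mins,
             light_minutes = as.numeric(tab[["light"]]) * mins,
             mvpa_minutes = as.numeric(tab[["mvpa"]]) * mins,
             valid = wear_minutes >= valid_min,
             stringsAsFactors = FALSE)
}

#' Summarise a child's activity across days
#'
#' Averages MVPA and sedentary minutes over valid days only. Children with
#' fewer than `min_valid_days` valid days receive `NA` means, to be multiply
#' imputed downstream.
#'
#' @param day_summaries data frame of [summarize_day()] rows for one or more
#'   children.
#' @param min_valid_days minimum valid days for defined means (default 3).
#' @return data frame with one row per child: `child_id`, `n_valid_days`,
#'   `n_valid_weekend_days`, `mean_mvpa`, `mean_sedentary`.
#' @export
summarize_child <- function(day_summaries, min_valid_days = 3) {
  stopifnot(nrow(day_summaries) >= 1)
  out <- lapply(split(day_summaries, day_summaries$child_id), function(d) {
    v <- d[d$valid, , drop = FALSE]
    enough <- nrow(v) >= min_valid_days
    data.frame(child_id = d$child_id[1],
               n_valid_days = nrow(v),
               n_valid_weekend_days = sum(v$weekend),
               mean_mvpa = if (enough) mean(v$mvpa_minutes) else NA_real_,
               mean_sedentary = if (enough) mean(v$sedentary_minutes) else NA_real_,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Process an epoch-level table into per-child activity summaries
#'
#' Convenience wrapper: applies non-wear detection, epoch classification and
#' day/child summarisation to a long table of epochs.
#'
#' @param epochs data frame with columns `child_id`, `day_id`, `weekend`,
#'   `epoch_index`, `counts`.
#' @inheritParams summarize_day
#' @inheritParams summarize_child
#' @param cutpoints thresholds from [evenson_cutpoints()].
#' @return list with `days` ([summarize_day()] rows) and `children`
#'   ([summarize_child()] rows).
#' @export
process_epochs <- function(epochs, cutpoints = evenson_cutpoints(),
                           epoch_len = 10, valid_min = 500,
                           min_valid_days = 3) {
  days <- lapply(split(epochs, list(epochs$child_id, epochs$day_id),
                       drop = TRUE), function(d) {
    d <- d[order(d$epoch_index), , drop = FALSE]
    wear <- detect_nonwear(d$counts, epoch_len = epoch_len)
    cls <- classify_epochs(d$counts, cutpoints, epoch_len)
    summarize_day(d, wear, cls, epoch_len, valid_min)
  })
  days <- do.call(rbind, days)
  rownames(days) <- NULL
  list(days = days, children = summarize_child(days, min_valid_days))
}
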