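# Adequacy classification of tidal volume and ventilation interval, and
# per-session summaries.

#' Adequacy thresholds
#'
#' The study definitions of adequate ventilation: optimal tidal volume
#' 420--480 mL with an adult bag and 120--180 mL with a paediatric bag (the
#' same 60 mL width for both), maximum deliverable volumes 1300 / 300 mL,
#' and an optimal ventilation interval of one breath every 6--8 s. All
#' interval bounds are inclusive.
#'
#' @param tv_optimal_adult,tv_optimal_paediatric Length-2 closed intervals
#'   (mL) of optimal tidal volume per bag type.
#' @param tv_max_adult,tv_max_paediatric Maximum deliverable volume (mL);
#'   volumes above it are classified hyperventilation and flagged
#'   implausible.
#' @param vi_optimal Length-2 closed interval (s) of the optimal
#'   onset-to-onset ventilation interval.
#' @return An object of class `threshold_set`.
#' @export
threshold_set <- function(tv_optimal_adult = c(420, 480),
                          tv_optimal_paediatric = c(120, 180),
                          tv_max_adult = 1300,
                          tv_max_paediatric = 300,
                          vi_optimal = c(6, 8)) {
  chk <- function(iv) length(iv) == 2 && iv[1] < iv[2]
  stopifnot(chk(tv_optimal_adult), chk(tv_optimal_paediatric),
            chk(vi_optimal),
            tv_max_adult >= tv_optimal_adult[2],
            tv_max_paediatric >= tv_optimal_paediatric[2])
  structure(list(tv_optimal = list(adult = as.numeric(tv_optimal_adult),
                                   paediatric = as.numeric(tv_optimal_paediatric)),
                 tv_max = list(adult = tv_max_adult,
                               paediatric = tv_max_paediatric),
                 vi_optimal = as.numeric(vi_optimal)),
            class = "threshold_set")
}

#' Classify a tidal volume
#'
#' `"optimal"` iff `lower <= volume <= upper` for the bag type (bounds
#' inclusive); below is `"hypo"`, above is `"hyper"`. Volumes exceeding the
#' bag's maximum deliverable volume are still `"hyper"` but are marked in
#' the `"implausible"` attribute.
#'
#' @param volume Tidal volume(s), mL, non-negative; vectorised.
#' @param bv_type `"adult"` or `"paediatric"`.
#' @param thresholds A [threshold_set()].
#' @return Character vector in `{"hypo","optimal","hyper"}` with a logical
#'   attribute `"implausible"`.
#' @export
classify_tv <- function(volume, bv_type = c("adult", "paediatric"),
                        thresholds = threshold_set()) {
  bv_type <- match.arg(bv_type)
  if (any(volume < 0, na.rm = TRUE)) stop("`volume` must be non-negative")
  iv <- thresholds$tv_optimal[[bv_type]]
  out <- ifelse(volume < iv[1], "hypo",
                ifelse(volume > iv[2], "hyper", "optimal"))
  attr(out, "implausible") <- !is.na(volume) &
    volume > thresholds$tv_max[[bv_type]]
  out
}

#' Classify a ventilation interval
#'
#' `"optimal"` iff the onset-to-onset interval lies in the closed optimal
#' range (6--8 s by default), otherwise `"suboptimal"`. `NA` intervals (the
#' last breath of a session has none) stay `NA`.
#'
#' @param interval Interval(s) in seconds, positive; vectorised.
#' @param thresholds A [threshold_set()].
#' @return Character vector in `{"optimal","suboptimal"}` or `NA`.
#' @export
classify_vi <- function(interval, thresholds = threshold_set()) {
  if (any(interval <= 0, na.rm = TRUE)) stop("`interval` must be positive")
  iv <- thresholds$vi_optimal
  ifelse(is.na(interval), NA_character_,
         ifelse(interval >= iv[1] & interval <= iv[2],
                "optimal", "suboptimal"))
}

#' One ventilation session
#'
#' Bundles the detected breaths of one 2-minute session with its trial
#' metadata (participant, arm, bag type, crossover period).
#'
#' @param participant_id Participant identifier.
#' @param arm `"RAV"` (device-assisted) or `"NV"` (non-assisted).
#' @param bv_type `"adult"` or `"paediatric"`.
#' @param period Crossover period, 1 or 2.
#' @param breaths A `breath_events` data frame (see [detect_breaths()]).
#' @return An object of class `session_record`.
#' @export
session_record <- function(participant_id, arm = c("RAV", "NV"),
                           bv_type = c("adult", "paediatric"),
                           period = 1L, breaths) {
  arm <- match.arg(arm)
  bv_type <- match.arg(bv_type)
  stopifnot(period %in% c(1L, 2L), is.data.frame(breaths))
  structure(list(participant_id = participant_id, arm = arm,
                 bv_type = bv_type, period = as.integer(period),
                 breaths = breaths),
            class = "session_record")
}

#' Summarize a ventilation session
#'
#' Per-session adequacy counts and moments: tidal-volume class counts
#' (hypo/optimal/hyper, partitioning all breaths), interval class counts
#' (optimal/suboptimal over the `n_breaths - 1` onset-to-onset intervals;
#' the last breath has no interval), and means/sample SDs of both.
#'
#' @param session A [session_record()].
#' @param thresholds A [threshold_set()].
#' @return An object of class `session_summary`: `n_breaths`, `tv_counts`,
#'   `vi_counts`, `tv_mean`, `tv_sd`, `vi_mean`, `vi_sd`, `n_implausible`.
#' @export
summarize_session <- function(session, thresholds = threshold_set()) {
  stopifnot(inherits(session, "session_record"))
  br <- session$breaths
  n <- nrow(br)
  tv_counts <- c(hypo = 0L, optimal = 0L, hyper = 0L)
  vi_counts <- c(optimal = 0L, suboptimal = 0L)
  n_impl <- 0L
  tv_mean <- tv_sd <- vi_mean <- vi_sd <- NA_real_
  if (n > 0) {
    cls <- classify_tv(br$tv_ml, session$bv_type, thresholds)
    tv_counts <- tv_counts + c(hypo = sum(cls == "hypo"),
                               optimal = sum(cls == "optimal"),
                               hyper = sum(cls == "hyper"))
    n_impl <- sum(attr(cls, "implausible"))
    tv_mean <- mean(br$tv_ml)
    if (n > 1) tv_sd <- stats::sd(br$tv_ml)
    iv <- br$interval_s[-n]          # the last breath has no interval
    iv <- iv[!is.na(iv)]
    if (length(iv)) {
      vcls <- classify_vi(iv, thresholds)
      vi_counts <- vi_counts + c(optimal = sum(vcls == "optimal"),
                                 suboptimal = sum(vcls == "suboptimal"))
      vi_mean <- mean(iv)
      if (length(iv) > 1) vi_sd <- stats::sd(iv)
    }
  }
  structure(list(participant_id = session$participant_id,
                 arm = session$arm, bv_type = session$bv_type,
                 period = session$period,
                 n_breaths = n, tv_counts = tv_counts,
                 vi_counts = vi_counts,
                 tv_mean = tv_mean, tv_sd = tv_sd,
                 vi_mean = vi_mean, vi_sd = vi_sd,
                 n_implausible = n_impl),
            class = "session_summary")
}

#' @export
print.session_summary <- function(x, ...) {
  cat(sprintf("<session_summary> participant %s, %s, %s bag, period %d\n",
              x$participant_id, x$arm, x$bv_type, x$period))
  cat(sprintf("  %d breaths: TV hypo/optimal/hyper = %d/%d/%d (mean %.1f mL)\n",
              x$n_breaths, x$tv_counts[["hypo"]], x$tv_counts[["optimal"]],
              x$tv_counts[["hyper"]], x$tv_mean))
  cat(sprintf("  intervals optimal/suboptimal = %d/%d (mean %.2f s)\n",
              x$vi_counts[["optimal"]], x$vi_counts[["suboptimal"]],
              x$vi_mean))
  invisible(x)
}

#' @export
as.data.frame.session_summary <- function(x, ...) {
  data.frame(participant = x$participant_id, arm = x$arm,
             bv = x$bv_type, period = x$period, n_breaths = x$n_breaths,
             tv_hypo = x$tv_counts[["hypo"]],
             tv_optimal = x$tv_counts[["optimal"]],
             tv_hyper = x$tv_counts[["hyper"]],
             vi_optimal = x$vi_counts[["optimal"]],
             vi_suboptimal = x$vi_counts[["suboptimal"]],
             tv_mean = x$tv_mean, tv_sd = x$tv_sd,
             vi_mean = x$vi_mean, vi_sd = x$vi_sd,
             n_implausible = x$n_implausible)
}
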