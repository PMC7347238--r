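#' Call the modal allele of a repeat profile
#'
#' The modal allele is the repeat number of the tallest bin — the "major
#' allele" marked on a bulk-PCR profile. Ties are broken toward the smaller
#' repeat number: PCR stutter makes left shoulders taller, so ties are
#' resolved conservatively against calling an expansion.
#'
#' @param profile A [repeat_profile()].
#' @return Integer repeat number of the modal allele.
#' @export
call_modal_allele <- function(profile) {
  stopifnot(inherits(profile, "repeat_profile"))
  # bins are sorted by repeat number, so which.max lands on the smallest tie
  profile$repeat_no[which.max(profile$height)]
}

#' Compute the Expansion Index of a repeat profile
#'
#' The Expansion Index (EI) is a windowed variant of the Somatic Instability
#' Index. Peaks with height at least `threshold_fraction` of the tallest peak
#' are retained; under the default window (`"modal_and_above"`) the retained
#' set is further restricted to repeats at or above the modal allele, i.e. the
#' window runs from the tallest peak to the largest above-threshold allele.
#' Retained heights are normalized to weights summing to one, and
#' \deqn{EI = \sum_i w_i (r_i - r_{ref})}
#' where \eqn{r_{ref}} is the reference repeat (typically the line's day-0
#' modal allele). EI is invariant under uniform scaling of heights, zero for a
#' single-allele profile referenced to itself, and non-negative whenever the
#' reference is the profile's own modal allele under the default window.
#'
#' The `"all_above_threshold"` window drops the right-side restriction and
#' admits peaks below the modal allele, which is the only way a negative EI
#' can arise when the reference is the modal allele.
#'
#' @param profile A [repeat_profile()].
#' @param reference_repeat Integer reference repeat number.
#' @param threshold_fraction Inclusion threshold as a fraction of the tallest
#'   peak, in (0, 1). Default 0.10.
#' @param window `"modal_and_above"` (default) or `"all_above_threshold"`.
#' @return An `instability_result`: list with `modal_repeat`,
#'   `expansion_index`, `threshold_fraction`, `reference_repeat`, `window`,
#'   and `included_peaks` (data frame of repeat number and normalized weight).
#' @examples
#' p <- repeat_profile(c(280, 281, 282), c(100, 50, 25))
#' compute_expansion_index(p, reference_repeat = 280)$expansion_index  # 4/7
#' @export
compute_expansion_index <- function(profile, reference_repeat,
                                    threshold_fraction = 0.10,
                                    window = c("modal_and_above", "all_above_threshold")) {
  stopifnot(inherits(profile, "repeat_profile"))
  window <- match.arg(window)
  if (!is.numeric(threshold_fraction) || length(threshold_fraction) != 1L ||
      threshold_fraction <= 0 || threshold_fraction >= 1)
    stop("threshold_fraction must be a single number in (0, 1)")
  reference_repeat <- as.integer(reference_repeat)
  if (is.na(reference_repeat)) stop("reference_repeat must be an integer")
  r <- profile$repeat_no
  h <- profile$height
  h_max <- max(h)
  modal <- r[which.max(h)]
  keep <- h >= threshold_fraction * h_max
  if (window == "modal_and_above") keep <- keep & r >= modal
  w <- h[keep] / sum(h[keep])
  ei <- sum(w * (r[keep] - reference_repeat))
  structure(list(
    modal_repeat = modal,
    expansion_index = ei,
    threshold_fraction = threshold_fraction,
    reference_repeat = reference_repeat,
    window = window,
    included_peaks = data.frame(repeat_no = r[keep], weight = w)
  ), class = "instability_result")
}

#' @export
print.instability_result <- function(x, ...) {
  cat(sprintf("Expansion Index %.3f (modal %d, reference %d, threshold %.2f, window %s; %d peaks)\n",
              x$expansion_index, x$modal_repeat, x$reference_repeat,
              x$threshold_fraction, x$window, nrow(x$included_peaks)))
  invisible(x)
}

#' Assemble a time course of repeat profiles
#'
#' @param line_id Cell-line identifier.
#' @param genotype Genotype label (e.g. "WT", "Mlh3_null").
#' @param profiles List of [repeat_profile()]s, each carrying a `day`
#'   attribute (or supply `days`). Days must be distinct; samples are sorted
#'   by day.
#' @param days Optional numeric vector of days overriding the profiles' `day`
#'   attributes.
#' @return A `time_course` object.
#' @export
time_course <- function(line_id, genotype, profiles, days = NULL) {
  if (length(profiles) < 1L) stop("a time course needs at least one sample")
  if (is.null(days)) days <- vapply(profiles, function(p) attr(p, "day"), numeric(1))
  days <- as.numeric(days)
  if (anyNA(days) || any(days < 0)) stop("every sample needs a non-negative day")
  if (anyDuplicated(days)) stop("days must be strictly increasing (no duplicates)")
  ord <- order(days)
  structure(list(line_id = as.character(line_id),
                 genotype = as.character(genotype),
                 days = days[ord], profiles = profiles[ord]),
            class = "time_course")
}

profile_at_day <- function(tc, day) {
  i <- match(day, tc$days)
  if (is.na(i)) stop("no sample at day ", day, " for line ", tc$line_id)
  tc$profiles[[i]]
}

flag_late_days <- function(...) {
  # heterogeneity builds up with time in culture and the modal allele becomes
  # progressively harder to pin down; warn rather than refuse
  d <- max(...)
  if (d > 52)
    warning(sprintf(paste0("day %g is beyond 52 days in culture; allele ",
                           "heterogeneity may make the modal repeat number unreliable"), d),
            call. = FALSE)
}

#' Modal repeat gain between two days of a time course
#'
#' @param tc A [time_course()].
#' @param day_a,day_b Days present in the time course.
#' @return Integer: modal allele at `day_b` minus modal allele at `day_a`.
#' @export
delta_repeats <- function(tc, day_a, day_b) {
  stopifnot(inherits(tc, "time_course"))
  flag_late_days(day_a, day_b)
  call_modal_allele(profile_at_day(tc, day_b)) -
    call_modal_allele(profile_at_day(tc, day_a))
}

#' Change in Expansion Index between two days of a time course
#'
#' Both EIs are computed against the same reference repeat. Under the default
#' `"day0_modal"` policy the reference is the modal allele of the time
#' course's earliest sample, held fixed across later days — the baseline
#' marked on bulk-PCR profile figures. A `"fixed"` policy with a user-supplied
#' `reference_repeat` is also accepted (e.g. a parental pre-editing allele).
#'
#' @param tc A [time_course()].
#' @param day_a,day_b Days present in the time course.
#' @param reference `"day0_modal"` (default) or `"fixed"`.
#' @param reference_repeat Required when `reference = "fixed"`.
#' @param threshold_fraction,window Passed to [compute_expansion_index()].
#' @return Numeric: EI(day_b) - EI(day_a).
#' @export
delta_expansion_index <- function(tc, day_a, day_b,
                                  reference = c("day0_modal", "fixed"),
                                  reference_repeat = NULL,
                                  threshold_fraction = 0.10,
                                  window = "modal_and_above") {
  stopifnot(inherits(tc, "time_course"))
  reference <- match.arg(reference)
  flag_late_days(day_a, day_b)
  ref <- switch(reference,
    day0_modal = call_modal_allele(tc$profiles[[1L]]),
    fixed = {
      if (is.null(reference_repeat)) stop("reference = 'fixed' needs reference_repeat")
      as.integer(reference_repeat)
    })
  ei <- function(day) compute_expansion_index(
    profile_at_day(tc, day), reference_repeat = ref,
    threshold_fraction = threshold_fraction, window = window)$expansion_index
  ei(day_b) - ei(day_a)
}

#' Fit an expansion rate by ordinary least squares
#'
#' Regresses repeats added on days in culture. The coefficient of
#' determination is computed as 1 - RSS/TSS; exactly collinear points
#' (including a flat line reproduced exactly) give R^2 = 1.
#'
#' @param days Numeric vector of days, or a two-column data frame/matrix of
#'   (day, repeats_added).
#' @param repeats_added Numeric vector of cumulative repeats gained.
#' @return A `rate_fit`: list with `slope` (repeats/day), `intercept`
#'   (repeats), `r_squared`, `n_points`.
#' @examples
#' fit_expansion_rate(c(0, 52), c(0, 18))  # slope 18/52
#' @export
fit_expansion_rate <- function(days, repeats_added = NULL) {
  if (is.null(repeats_added)) {
    days <- as.data.frame(days)
    repeats_added <- days[[2L]]
    days <- days[[1L]]
  }
  days <- as.numeric(days)
  repeats_added <- as.numeric(repeats_added)
  if (length(days) != length(repeats_added)) stop("days and repeats_added lengths differ")
  if (length(unique(days)) < 2L)
    stop("need at least two distinct days to fit an expansion rate")
  fit <- stats::lm(repeats_added ~ days)
  pred <- stats::fitted(fit)
  rss <- sum((repeats_added - pred)^2)
  tss <- sum((repeats_added - mean(repeats_added))^2)
  scale2 <- max(tss, mean(repeats_added)^2, 1)
  r2 <- if (rss <= 1e-12 * scale2) 1 else 1 - rss / tss
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = r2,
                 n_points = length(days)),
            class = "rate_fit")
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf("Expansion rate: %.4f repeats/day (intercept %.3f, R^2 = %.4f, n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}

#' Days needed to add one repeat
#'
#' @param fit A [fit_expansion_rate()] result, or a positive slope.
#' @return 1 / slope, in days per repeat.
#' @export
days_per_repeat <- function(fit) {
  slope <- if (inherits(fit, "rate_fit")) fit$slope else as.numeric(fit)
  if (!is.finite(slope) || slope <= 0)
    stop("days per repeat is undefined for a non-positive expansion rate")
  1 / slope
}

#' Bounds on the number of expansion events behind a net repeat gain
#'
#' If each expansion event adds between `min_step` and `max_step` repeats,
#' a net gain of `total_gain` repeats requires at least
#' `ceiling(total_gain / max_step)` and at most `floor(total_gain / min_step)`
#' events. With steps of one or two repeats, a gain of 19 repeats implies
#' between 10 and 19 events.
#'
#' @param total_gain Positive integer net repeat gain.
#' @param min_step,max_step Positive integer step bounds, `max_step >= min_step`.
#' @return Named integer vector `c(min_events, max_events)`.
#' @examples
#' expansion_event_bounds(19)  # c(min_events = 10, max_events = 19)
#' @export
expansion_event_bounds <- function(total_gain, min_step = 1L, max_step = 2L) {
  total_gain <- as.integer(total_gain)
  min_step <- as.integer(min_step)
  max_step <- as.integer(max_step)
  if (is.na(total_gain) || total_gain < 1L) stop("total_gain must be a positive integer")
  if (is.na(min_step) || is.na(max_step) || min_step < 1L || max_step < min_step)
    stop("need max_step >= min_step >= 1")
  c(min_events = as.integer(ceiling(total_gain / max_step)),
    max_events = as.integer(floor(total_gain / min_step)))
}
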