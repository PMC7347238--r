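test_that("modal allele is the tallest bin, ties broken toward smaller repeats", {
  expect_equal(call_modal_allele(repeat_profile(c(277, 278), c(500, 200))), 277L)
  expect_equal(call_modal_allele(repeat_profile(c(277, 279), c(300, 300))), 277L)

  # a stuttered profile built around a major allele of 277 still calls 277
  st <- structure(list(day = 0, alleles = rep(277L, 500), genotype = "WT"),
                  class = "population_state")
  prof <- render_trace(st, stutter_model(minus_ratio = 0.6, plus_ratio = 0.1, span = 4))
  expect_equal(call_modal_allele(prof), 277L)
})

test_that("Expansion Index matches hand-computed values", {
  expect_equal(compute_expansion_index(repeat_profile(280, 1000), 280)$expansion_index, 0)

  p <- repeat_profile(c(280, 281, 282), c(100, 50, 25))
  r <- compute_expansion_index(p, reference_repeat = 280)
  expect_equal(r$expansion_index, (0 * 100 + 1 * 50 + 2 * 25) / 175)
  expect_equal(sum(r$included_peaks$weight), 1)
  expect_equal(r$modal_repeat, 280L)

  # raising the threshold to 0.30 excludes the 282 bin (25 < 30)
  r2 <- compute_expansion_index(p, 280, threshold_fraction = 0.30)
  expect_equal(r2$expansion_index, 50 / 150)
  expect_equal(nrow(r2$included_peaks), 2L)

  expect_error(compute_expansion_index(p, 280, threshold_fraction = 0), "threshold")
  expect_error(compute_expansion_index(p, 280, threshold_fraction = 1), "threshold")
})

test_that("EI is scale-invariant and agrees with the brute-force oracle", {
  set.seed(11)
  for (i in 1:400) {
    prof <- random_profile()
    ref <- sample(prof$repeat_no, 1)
    thr <- runif(1, 0.05, 0.5)
    win <- sample(c("modal_and_above", "all_above_threshold"), 1)
    got <- compute_expansion_index(prof, ref, thr, win)$expansion_index
    expect_equal(got, oracle_ei(prof$repeat_no, prof$height, ref, thr, win))
    # uniform height scaling leaves EI unchanged
    scaled <- repeat_profile(prof$repeat_no, prof$height * 37.5)
    expect_equal(compute_expansion_index(scaled, ref, thr, win)$expansion_index, got)
  }
})

test_that("EI referenced to the modal allele is non-negative under the default window", {
  set.seed(12)
  for (i in 1:200) {
    prof <- random_profile()
    modal <- call_modal_allele(prof)
    expect_gte(compute_expansion_index(prof, modal)$expansion_index, 0)
  }
})

test_that("rightward mass transfer between included peaks never decreases EI", {
  set.seed(13)
  tried <- 0
  for (i in 1:300) {
    prof <- random_profile(n_bins = sample(3:12, 1))
    modal <- call_modal_allele(prof)
    res <- compute_expansion_index(prof, modal)
    inc <- res$included_peaks$repeat_no
    if (length(inc) < 3L) next
    # transfer mass from a lower to a higher included (non-modal) bin, small
    # enough to keep the inclusion set and the modal bin unchanged
    from <- inc[2L]
    to <- inc[length(inc)]
    h <- prof$height
    i_from <- match(from, prof$repeat_no)
    i_to <- match(to, prof$repeat_no)
    thr_h <- 0.10 * max(h)
    amount <- min((h[i_from] - thr_h) * 0.9, (max(h) - h[i_to]) * 0.9)
    if (amount <= 0) next
    h2 <- h
    h2[i_from] <- h2[i_from] - amount
    h2[i_to] <- h2[i_to] + amount
    shifted <- repeat_profile(prof$repeat_no, h2)
    res2 <- compute_expansion_index(shifted, modal)
    if (!identical(res2$included_peaks$repeat_no, inc)) next
    tried <- tried + 1
    expect_gte(res2$expansion_index, res$expansion_index - 1e-12)
  }
  expect_gt(tried, 50)
})

test_that("delta operations reproduce point-mass and published-average cases", {
  tc <- time_course("WT_ave", "WT",
                    list(repeat_profile(287, 100, day = 0),
                         repeat_profile(305, 100, day = 52)))
  expect_equal(delta_repeats(tc, 0, 52), 18L)

  tc2 <- time_course("Mlh3_1", "Mlh3_null",
                     list(repeat_profile(280, 100, day = 0),
                          repeat_profile(279, 100, day = 52)))
  expect_equal(delta_repeats(tc2, 0, 52), -1L)

  same <- repeat_profile(c(280, 281), c(100, 30))
  tc3 <- time_course("x", "WT", list(same, same), days = c(0, 52))
  expect_equal(delta_repeats(tc3, 0, 52), 0L)
  expect_equal(delta_expansion_index(tc3, 0, 52), 0)

  expect_error(delta_repeats(tc, 0, 40), "no sample at day 40")
  expect_warning(
    delta_repeats(time_course("x", "WT", list(same, same), days = c(0, 68)), 0, 68),
    "beyond 52 days")
})

test_that("delta EI uses one fixed reference for both days", {
  p0 <- repeat_profile(c(280, 281), c(100, 20), day = 0)
  p1 <- repeat_profile(c(280, 281, 283, 285), c(100, 60, 50, 30), day = 52)
  tc <- time_course("L", "WT", list(p0, p1))
  ref <- call_modal_allele(p0)
  expected <- compute_expansion_index(p1, ref)$expansion_index -
    compute_expansion_index(p0, ref)$expansion_index
  expect_equal(delta_expansion_index(tc, 0, 52), expected)
  # a user-supplied fixed reference shifts both EIs equally: same delta
  expect_equal(delta_expansion_index(tc, 0, 52, reference = "fixed",
                                     reference_repeat = 270),
               expected)
  expect_gt(delta_expansion_index(tc, 0, 52), 0)
})

test_that("expansion-rate regression recovers exact and simulated courses", {
  f <- fit_expansion_rate(c(0, 52), c(0, 18))
  expect_equal(f$slope, 18 / 52)
  expect_equal(f$r_squared, 1)
  expect_equal(f$n_points, 2L)

  f3 <- fit_expansion_rate(c(0, 26, 52), c(0, 9, 18))
  expect_equal(f3$slope, 18 / 52)
  expect_equal(f3$r_squared, 1)

  # flat course is exactly collinear too
  expect_equal(fit_expansion_rate(c(0, 26, 52), c(0, 0, 0))$r_squared, 1)

  # noiseless linear course: slope and intercept to machine precision
  days <- seq(0, 52, by = 13)
  r_true <- 0.36
  f4 <- fit_expansion_rate(days, 2 + r_true * days)
  expect_equal(f4$slope, r_true, tolerance = 1e-9)
  expect_equal(f4$intercept, 2, tolerance = 1e-9)
  expect_equal(f4$r_squared, 1)

  expect_error(fit_expansion_rate(0, 0), "two distinct days")
  expect_error(fit_expansion_rate(c(5, 5), c(0, 1)), "two distinct days")
})

test_that("days_per_repeat is the reciprocal rate and rejects non-positive slopes", {
  expect_equal(days_per_repeat(fit_expansion_rate(c(0, 52), c(0, 18))),
               52 / 18)
  expect_equal(days_per_repeat(0.5), 2)
  expect_error(days_per_repeat(0), "non-positive")
  expect_error(days_per_repeat(fit_expansion_rate(c(0, 52), c(5, 0))), "non-positive")
})

test_that("expansion event bounds match exhaustive step-composition enumeration", {
  expect_equal(expansion_event_bounds(19, 1, 2),
               c(min_events = 10L, max_events = 19L))
  expect_equal(expansion_event_bounds(1, 1, 2),
               c(min_events = 1L, max_events = 1L))
  expect_equal(expansion_event_bounds(18, 1, 3),
               c(min_events = 6L, max_events = 18L))

  # oracle: enumerate attainable event counts for compositions of g from
  # steps in {min_step..max_step}
  attainable_counts <- function(g, lo, hi) {
    reach <- list(`0` = 0L)
    for (k in 1:g) {
      counts <- integer(0)
      for (s in lo:hi) {
        prev <- reach[[as.character(k - s)]]
        if (k - s >= 0 && !is.null(prev)) counts <- c(counts, prev + 1L)
      }
      if (length(counts)) reach[[as.character(k)]] <- sort(unique(counts))
    }
    reach[[as.character(g)]]
  }
  for (case in list(c(19, 1, 2), c(18, 1, 3), c(7, 2, 3), c(12, 3, 5))) {
    counts <- attainable_counts(case[1], case[2], case[3])
    b <- expansion_event_bounds(case[1], case[2], case[3])
    expect_equal(unname(b["min_events"]), min(counts))
    expect_equal(unname(b["max_events"]), max(counts))
  }

  expect_error(expansion_event_bounds(0), "positive")
  expect_error(expansion_event_bounds(10, 2, 1), "min_step")
})
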