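# Stochastic stepwise-expansion simulator. Every stochastic draw flows from a
# single integer seed via R's default generator; the caller's RNG state is
# saved and restored around each simulation.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_old) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Configure a repeat-expansion simulation
#'
#' Models a clonal cell population carrying a long CGG-repeat allele. Per cell
#' and per day, expansion events arrive as a Poisson process with rate
#' `expansion_rate`; each event adds a step drawn from `step_probs` (by
#' default one repeat with probability 0.8, two with probability 0.2, since
#' most expansion events add only one or two repeats). Contractions are an
#' independent Poisson process with its own step distribution. There is no
#' division/selection model: the population expands in concert and only the
#' allele multiset evolves.
#'
#' @param n_cells Number of cells (alleles) in the population.
#' @param start_repeat Starting repeat number (the model system carries ~280).
#' @param expansion_rate Expansion events per cell per day (>= 0).
#' @param step_probs Named numeric vector of positive step sizes and their
#'   probabilities (must sum to 1), e.g. `c("1" = 0.8, "2" = 0.2)`.
#' @param contraction_rate Contraction events per cell per day (>= 0).
#' @param contraction_step_probs Named numeric vector over negative steps,
#'   e.g. `c("-1" = 1)`.
#' @param duration_days Length of the culture period.
#' @param sample_days Days at which the population is sampled; all must lie in
#'   `[0, duration_days]`.
#' @param seed Integer seed controlling all stochastic draws.
#' @param genotype Label attached to outputs.
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(n_cells = 10000L,
                              start_repeat = 280L,
                              expansion_rate = 0.30,
                              step_probs = c("1" = 0.8, "2" = 0.2),
                              contraction_rate = 0,
                              contraction_step_probs = c("-1" = 1),
                              duration_days = 52,
                              sample_days = c(0, 40, 52),
                              seed = 1L,
                              genotype = "custom") {
  n_cells <- as.integer(n_cells)
  start_repeat <- as.integer(start_repeat)
  if (n_cells < 1L) stop("n_cells must be positive")
  if (start_repeat < 1L) stop("start_repeat must be positive")
  if (expansion_rate < 0 || contraction_rate < 0) stop("rates must be non-negative")
  check_steps <- function(p, sign, what) {
    s <- as.integer(names(p))
    if (anyNA(s) || any(sign * s < 1L)) stop(what, " step sizes must be ", if (sign > 0) "positive" else "negative", " integers")
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) stop(what, " step probabilities must be non-negative and sum to 1")
  }
  check_steps(step_probs, +1L, "expansion")
  check_steps(contraction_step_probs, -1L, "contraction")
  sample_days <- sort(as.numeric(sample_days))
  if (any(sample_days < 0) || any(sample_days > duration_days))
    stop("sample_days must lie within [0, duration_days]")
  if (anyDuplicated(sample_days)) stop("sample_days must be distinct")
  structure(list(n_cells = n_cells, start_repeat = start_repeat,
                 expansion_rate = expansion_rate, step_probs = step_probs,
                 contraction_rate = contraction_rate,
                 contraction_step_probs = contraction_step_probs,
                 duration_days = as.numeric(duration_days),
                 sample_days = sample_days,
                 seed = as.integer(seed), genotype = genotype),
            class = "simulation_config")
}

#' Preset simulation configurations per genotype
#'
#' Encodes the qualitative regimes of the mESC model: wild type expands at a
#' rate calibrated to a net modal gain of ~18 repeats in 52 days
#' (`expansion_rate * E[step] = 0.36` repeats/day); MLH3- and PMS2-null lines
#' do not expand and drift down slowly by single-repeat contractions; PMS1-null
#' lines show only a rare single-repeat gain that becomes visible after ~68
#' days.
#'
#' @param name One of `"WT"`, `"Mlh3_null"`, `"Pms2_null"`, `"Pms1_null"`.
#' @param ... Overrides passed to [simulation_config()] (e.g. `n_cells`,
#'   `sample_days`, `seed`, `start_repeat`).
#' @return A [simulation_config()].
#' @export
genotype_preset <- function(name = c("WT", "Mlh3_null", "Pms2_null", "Pms1_null"),
                            ...) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% c("WT", "Mlh3_null", "Pms2_null", "Pms1_null"))
    stop("unknown genotype preset: ", paste(name, collapse = ", "))
  base <- switch(name,
    WT = list(expansion_rate = 0.30, step_probs = c("1" = 0.8, "2" = 0.2),
              contraction_rate = 0,
              duration_days = 52, sample_days = c(0, 40, 52)),
    Mlh3_null = list(expansion_rate = 0, contraction_rate = 0.02,
                     contraction_step_probs = c("-1" = 1),
                     duration_days = 68, sample_days = c(0, 52, 68)),
    Pms2_null = list(expansion_rate = 0, contraction_rate = 0.02,
                     contraction_step_probs = c("-1" = 1),
                     duration_days = 68, sample_days = c(0, 52, 68)),
    Pms1_null = list(expansion_rate = 0.005, step_probs = c("1" = 1),
                     contraction_rate = 0,
                     duration_days = 68, sample_days = c(0, 52, 68)))
  args <- utils::modifyList(c(base, list(genotype = name)), list(...))
  do.call(simulation_config, args)
}

# total step gain for a vector of per-cell event counts
draw_step_totals <- function(n_events, step_probs) {
  total <- integer(length(n_events))
  pos <- which(n_events > 0L)
  if (length(pos)) {
    vals <- as.integer(names(step_probs))
    n_draw <- sum(n_events[pos])
    steps <- if (length(vals) == 1L) rep.int(vals, n_draw)
             else sample(vals, n_draw, replace = TRUE, prob = step_probs)
    total[pos] <- as.integer(rowsum(steps, rep(seq_along(pos), n_events[pos])))
  }
  total
}

#' Simulate a repeat-expansion time course
#'
#' Evolves each cell's allele independently between consecutive sample days:
#' the number of expansion (contraction) events in an interval of length dt is
#' Poisson with mean `rate * dt`, and each event adds its sampled step. Repeat
#' numbers are floored at 1. Output is reproducible bit-exactly from
#' `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return A list of `population_state` objects, one per `sample_days` entry:
#'   each has `day`, `alleles` (integer vector of length `n_cells`), and
#'   `genotype`.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    days <- config$sample_days
    alleles <- rep.int(config$start_repeat, config$n_cells)
    states <- vector("list", length(days))
    prev <- 0
    for (i in seq_along(days)) {
      dt <- days[i] - prev
      if (dt > 0) {
        if (config$expansion_rate > 0) {
          n_exp <- stats::rpois(config$n_cells, config$expansion_rate * dt)
          alleles <- alleles + draw_step_totals(n_exp, config$step_probs)
        }
        if (config$contraction_rate > 0) {
          n_con <- stats::rpois(config$n_cells, config$contraction_rate * dt)
          alleles <- alleles + draw_step_totals(n_con, config$contraction_step_probs)
        }
        alleles <- pmax(alleles, 1L)
      }
      states[[i]] <- structure(list(day = days[i], alleles = alleles,
                                    genotype = config$genotype),
                               class = "population_state")
      prev <- days[i]
    }
    states
  })
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("Population state at day %g (%s): %d cells, modal allele %d, mean %.2f\n",
              x$day, x$genotype, length(x$alleles),
              as.integer(names(which.max(table(x$alleles)))), mean(x$alleles)))
  invisible(x)
}

#' PCR stutter and noise model for trace rendering
#'
#' Stutter is modelled as a geometric, asymmetric kernel: an allele at repeat
#' r contributes weight `minus_ratio^k` at r-k and `plus_ratio^k` at r+k for
#' k up to `span`, normalized so the kernel sums to one (total height is
#' conserved). Minus stutter dominates, reproducing the left-skewed shoulders
#' of repeat PCR profiles. Optional per-bin multiplicative lognormal noise
#' with the given coefficient of variation emulates run-to-run height jitter.
#'
#' @param minus_ratio Geometric ratio of minus stutter, in [0, 1). Default 0.5.
#' @param plus_ratio Geometric ratio of plus stutter, in [0, 1). Default 0.05.
#' @param span Maximum stutter offset in repeat units (integer >= 0). Default 5.
#' @param height_noise_cv Coefficient of variation of per-bin height noise
#'   (>= 0, 0 = noiseless). Default 0.
#' @return A `stutter_model` object.
#' @export
stutter_model <- function(minus_ratio = 0.5, plus_ratio = 0.05, span = 5L,
                          height_noise_cv = 0) {
  if (minus_ratio < 0 || minus_ratio >= 1 || plus_ratio < 0 || plus_ratio >= 1)
    stop("stutter ratios must lie in [0, 1)")
  span <- as.integer(span)
  if (is.na(span) || span < 0L) stop("span must be a non-negative integer")
  if (height_noise_cv < 0) stop("height_noise_cv must be non-negative")
  structure(list(minus_ratio = minus_ratio, plus_ratio = plus_ratio,
                 span = span, height_noise_cv = height_noise_cv),
            class = "stutter_model")
}

stutter_kernel <- function(stutter) {
  k <- seq_len(stutter$span)
  w <- c(rev(stutter$minus_ratio^k), 1, stutter$plus_ratio^k)
  w / sum(w)  # offsets -span..+span
}

#' Render a population state as a stuttered repeat profile
#'
#' Convolves the population's allele histogram with the stutter kernel and
#' applies per-bin multiplicative noise. With a zero-stutter, zero-noise model
#' the profile equals the raw allele histogram.
#'
#' @param state A `population_state` from [simulate_population()].
#' @param stutter A [stutter_model()].
#' @param seed Seed for the noise draws (required for reproducibility when
#'   `height_noise_cv > 0`).
#' @param sample_id Sample identifier attached to the profile.
#' @return A [repeat_profile()] with the state's day attached.
#' @export
render_trace <- function(state, stutter = stutter_model(), seed = NULL,
                         sample_id = NA_character_) {
  stopifnot(inherits(state, "population_state"), inherits(stutter, "stutter_model"))
  rng <- range(state$alleles)
  counts <- tabulate(state$alleles - rng[1L] + 1L, rng[2L] - rng[1L] + 1L)
  span <- stutter$span
  kern <- stutter_kernel(stutter)
  reps <- seq(rng[1L] - span, rng[2L] + span)
  heights <- numeric(length(reps))
  for (j in seq_along(kern)) {
    off <- j - span - 1L  # offset in repeat units
    at <- seq_along(counts) + span + off
    heights[at] <- heights[at] + counts * kern[j]
  }
  keep <- reps >= 0L
  reps <- reps[keep]
  heights <- heights[keep]
  if (stutter$height_noise_cv > 0) {
    cv <- stutter$height_noise_cv
    sdlog <- sqrt(log1p(cv^2))
    heights <- with_seed(seed,
      heights * stats::rlnorm(length(heights), meanlog = -sdlog^2 / 2, sdlog = sdlog))
  }
  repeat_profile(reps, heights, sample_id = sample_id, day = state$day)
}

#' Sample a small-pool PCR experiment from a population state
#'
#' Each pool receives a Poisson(`mean_molecules_per_pool`) number of template
#' molecules drawn uniformly with replacement from the population's alleles.
#' Pools with zero molecules are recorded as negative. `modal_shift` is added
#' to every sampled allele, emulating the constant left shift that nested PCR
#' imposes on called repeat numbers (use -2 for a two-repeat left shift).
#'
#' @param state A `population_state`.
#' @param mean_molecules_per_pool Mean template molecules per pool (>= 0).
#' @param n_pools Number of pools (positive integer).
#' @param modal_shift Integer offset applied to every sampled allele. Default 0.
#' @param seed Integer seed.
#' @return A list of class `sppcr_sample`: `day`, `alleles` (integer vector,
#'   one per amplified molecule), `pool_id` (parallel to `alleles`),
#'   `n_pools`, `negative_pools`, `modal_shift`.
#' @export
sample_sp_pcr <- function(state, mean_molecules_per_pool, n_pools,
                          modal_shift = 0L, seed = NULL) {
  stopifnot(inherits(state, "population_state"))
  if (mean_molecules_per_pool < 0) stop("mean_molecules_per_pool must be non-negative")
  n_pools <- as.integer(n_pools)
  if (is.na(n_pools) || n_pools < 1L) stop("n_pools must be a positive integer")
  with_seed(seed, {
    counts <- stats::rpois(n_pools, mean_molecules_per_pool)
    total <- sum(counts)
    alleles <- if (total > 0)
      sample(state$alleles, total, replace = TRUE) + as.integer(modal_shift)
    else integer(0)
    structure(list(day = state$day,
                   alleles = as.integer(alleles),
                   pool_id = rep.int(seq_len(n_pools), counts),
                   n_pools = n_pools,
                   negative_pools = sum(counts == 0L),
                   modal_shift = as.integer(modal_shift)),
              class = "sppcr_sample")
  })
}

#' Bundle SP-PCR samples from several days into a dataset
#'
#' @param line_id Line identifier.
#' @param samples List of `sppcr_sample` objects from [sample_sp_pcr()], one
#'   per day.
#' @return An [sppcr_dataset()] with pooled bookkeeping totals.
#' @export
sppcr_from_samples <- function(line_id, samples) {
  days <- vapply(samples, function(s) s$day, numeric(1))
  tp <- lapply(samples, function(s) s$alleles)
  names(tp) <- as.character(days)
  sppcr_dataset(line_id, tp,
                n_pools = sum(vapply(samples, function(s) s$n_pools, integer(1))),
                negative_pools = sum(vapply(samples, function(s) s$negative_pools, integer(1))))
}
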