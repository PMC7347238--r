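#' Wilcoxon-Mann-Whitney rank-sum test with exact small-sample p-values
#'
#' Computes the Mann-Whitney U statistic for `x` (pairs won by `x`, with ties
#' counted half) via midranks. For small samples the p-value is exact: when
#' there are no ties and `min(n1, n2) <= 8` it comes from the exact null
#' distribution of U; with ties and `n1 + n2 <= 12` it comes from complete
#' enumeration of all `choose(n1 + n2, n1)` group labelings of the midranks.
#' Otherwise a normal approximation with tie-corrected variance and a 0.5
#' continuity correction is used.
#'
#' @param x,y Numeric vectors (both non-empty).
#' @param alternative `"two_sided"` (default), `"greater"` (x shifted right),
#'   or `"less"`.
#' @param method `"auto"` (default; rules above), `"exact"` or
#'   `"normal_approx"` to force a route. Forcing `"exact"` on a large tied
#'   sample is an error.
#' @return A `rank_sum_result`: list with `u_statistic`, `p_value`, `method`
#'   (`"exact"` or `"normal_approx"`), `n1`, `n2`, `alternative`.
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))$p_value  # exact 2/20 = 0.10
#' @export
rank_sum_test <- function(x, y,
                          alternative = c("two_sided", "greater", "less"),
                          method = c("auto", "exact", "normal_approx")) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be non-empty")
  if (anyNA(x) || anyNA(y)) stop("samples must not contain NA")
  n1 <- length(x)
  n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)  # midranks
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(pooled) > 0L

  if (method == "auto") {
    method <- if ((!ties && min(n1, n2) <= 8L) || (ties && n1 + n2 <= 12L))
      "exact" else "normal_approx"
  }

  p <- if (method == "exact") {
    if (!ties) {
      p_exact_noties(u, n1, n2, alternative)
    } else {
      if (n1 + n2 > 12L)
        stop("exact p-value with ties requires n1 + n2 <= 12 (enumeration); use the normal approximation")
      p_exact_enumerate(r, n1, u, alternative)
    }
  } else {
    p_normal_approx(u, r, n1, n2, alternative)
  }

  structure(list(u_statistic = u, p_value = min(1, max(0, p)),
                 method = method, n1 = n1, n2 = n2,
                 alternative = alternative),
            class = "rank_sum_result")
}

# exact p from the null distribution of U (no ties); same conventions as the
# classical two-sample Wilcoxon test
p_exact_noties <- function(u, n1, n2, alternative) {
  switch(alternative,
    greater = stats::pwilcox(u - 1, n1, n2, lower.tail = FALSE),
    less = stats::pwilcox(u, n1, n2),
    two_sided = {
      if (u > n1 * n2 / 2)
        min(1, 2 * stats::pwilcox(u - 1, n1, n2, lower.tail = FALSE))
      else
        min(1, 2 * stats::pwilcox(u, n1, n2))
    })
}

# complete enumeration over all group labelings of the (mid)ranks
p_exact_enumerate <- function(r, n1, u_obs, alternative) {
  n <- length(r)
  idx <- utils::combn(n, n1)
  u_all <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
  eps <- 1e-9
  mu <- n1 * (n - n1) / 2
  switch(alternative,
    greater = mean(u_all >= u_obs - eps),
    less = mean(u_all <= u_obs + eps),
    two_sided = mean(abs(u_all - mu) >= abs(u_obs - mu) - eps))
}

p_normal_approx <- function(u, r, n1, n2, alternative) {
  n <- n1 + n2
  mu <- n1 * n2 / 2
  tie_tab <- table(r)
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)  # all observations identical
  sigma <- sqrt(sigma2)
  cc <- 0.5  # continuity correction toward the mean
  switch(alternative,
    greater = stats::pnorm((u - mu - cc) / sigma, lower.tail = FALSE),
    less = stats::pnorm((u - mu + cc) / sigma),
    two_sided = 2 * stats::pnorm((abs(u - mu) - cc) / sigma, lower.tail = FALSE))
}

#' @export
print.rank_sum_result <- function(x, ...) {
  cat(sprintf("Rank-sum test (%s, %s): U = %g, p = %.4g (n1 = %d, n2 = %d)\n",
              x$alternative, x$method, x$u_statistic, x$p_value, x$n1, x$n2))
  invisible(x)
}

#' Classify later-day alleles against the day-0 range
#'
#' A later allele is counted as expanded if it exceeds `max(day0) + margin`,
#' contracted if below `min(day0) - margin`, and within range otherwise.
#' "Unequivocally expanded" is operationalized with `margin = 0`, i.e.
#' strictly greater than the largest day-0 allele.
#'
#' @param day0 Integer vector of day-0 allele repeat numbers (non-empty).
#' @param later Integer vector of later-day allele repeat numbers.
#' @param margin Non-negative integer slack added to the day-0 range.
#' @return An `allele_classification`: list with counts `expanded`,
#'   `contracted`, `within_range`, the `day0_range`, and the `margin`.
#' @export
classify_alleles <- function(day0, later, margin = 0L) {
  if (length(day0) == 0L) stop("day-0 allele list must be non-empty")
  margin <- as.integer(margin)
  if (is.na(margin) || margin < 0L) stop("margin must be a non-negative integer")
  lo <- min(day0) - margin
  hi <- max(day0) + margin
  structure(list(expanded = sum(later > hi),
                 contracted = sum(later < lo),
                 within_range = sum(later >= lo & later <= hi),
                 day0_range = c(min = min(day0), max = max(day0)),
                 margin = margin),
            class = "allele_classification")
}

#' Poisson zero-class estimate of molecules per pool
#'
#' At limiting dilution the number of amplifiable molecules per reaction is
#' Poisson distributed, so the mean occupancy is estimated from the fraction
#' of negative (no-product) pools: `lambda = -log(negative_pools / n_pools)`.
#'
#' @param n_pools Total number of pools (positive integer).
#' @param negative_pools Number of pools with no product; must be at least 1
#'   for a finite estimate.
#' @return Estimated mean molecules per pool.
#' @examples
#' estimate_molecules_per_pool(100, 37)  # -log(0.37) = 0.994
#' @export
estimate_molecules_per_pool <- function(n_pools, negative_pools) {
  n_pools <- as.integer(n_pools)
  negative_pools <- as.integer(negative_pools)
  if (is.na(n_pools) || n_pools < 1L) stop("n_pools must be a positive integer")
  if (is.na(negative_pools) || negative_pools < 0L || negative_pools > n_pools)
    stop("negative_pools must lie in [0, n_pools]")
  if (negative_pools == 0L)
    stop("no negative pools: the occupancy estimate is unbounded; dilute the template further")
  -log(negative_pools / n_pools)
}

#' Assemble a small-pool PCR dataset
#'
#' @param line_id Cell-line identifier.
#' @param timepoints Named list mapping day (as name, e.g. `"0"`, `"68"`) to
#'   an integer vector of single-molecule allele repeat numbers.
#' @param n_pools,negative_pools Optional pool bookkeeping for occupancy
#'   estimation (totals across the dataset).
#' @return An `sppcr_dataset` object.
#' @export
sppcr_dataset <- function(line_id, timepoints, n_pools = NA_integer_,
                          negative_pools = NA_integer_) {
  if (is.null(names(timepoints)) || any(!nzchar(names(timepoints))))
    stop("timepoints must be a named list, names giving the day")
  if (any(vapply(timepoints, length, integer(1)) == 0L))
    stop("every analyzed timepoint needs at least one allele call")
  if (!is.na(n_pools) && !is.na(negative_pools) && negative_pools > n_pools)
    stop("negative_pools cannot exceed n_pools")
  structure(list(line_id = as.character(line_id),
                 timepoints = lapply(timepoints, as.integer),
                 n_pools = as.integer(n_pools),
                 negative_pools = as.integer(negative_pools)),
            class = "sppcr_dataset")
}

sppcr_alleles_at <- function(ds, day) {
  key <- as.character(as.numeric(day))
  a <- ds$timepoints[[key]]
  if (is.null(a)) stop("no SP-PCR data at day ", day, " for line ", ds$line_id)
  a
}

#' Compare SP-PCR allele distributions between two timepoints
#'
#' Runs the rank-sum test on the raw single-molecule allele lists, classifies
#' later-day alleles against the day-0 range, and tabulates a per-repeat
#' histogram of both days. The report is deterministic.
#'
#' @param ds An [sppcr_dataset()].
#' @param day_a,day_b Days present in the dataset (`day_a` is the baseline for
#'   classification).
#' @param margin Passed to [classify_alleles()].
#' @param modal_shift Integer offset added to the `day_b` alleles before
#'   comparison, for aligning assays with a known constant calling offset
#'   (e.g. `-2` is the left shift nested PCR imposes on the modal repeat
#'   number). Applied explicitly, never silently. Default 0.
#' @param alternative Passed to [rank_sum_test()].
#' @return An `sppcr_comparison`: list with `rank_sum`, `classification`, and
#'   `histogram` (data frame: `repeat_no`, `count_a`, `count_b`).
#' @export
compare_timepoints <- function(ds, day_a, day_b, margin = 0L, modal_shift = 0L,
                               alternative = "two_sided") {
  stopifnot(inherits(ds, "sppcr_dataset"))
  a <- sppcr_alleles_at(ds, day_a)
  b <- sppcr_alleles_at(ds, day_b) + as.integer(modal_shift)
  rng <- range(c(a, b))
  bins <- seq(rng[1L], rng[2L])
  structure(list(
    line_id = ds$line_id,
    day_a = day_a, day_b = day_b, modal_shift = as.integer(modal_shift),
    rank_sum = rank_sum_test(a, b, alternative = alternative),
    classification = classify_alleles(a, b, margin = margin),
    histogram = data.frame(repeat_no = bins,
                           count_a = as.integer(tabulate(a - rng[1L] + 1L, length(bins))),
                           count_b = as.integer(tabulate(b - rng[1L] + 1L, length(bins))))
  ), class = "sppcr_comparison")
}

#' @export
print.sppcr_comparison <- function(x, ...) {
  cl <- x$classification
  cat(sprintf("SP-PCR comparison, line %s: day %g vs day %g%s\n", x$line_id,
              x$day_a, x$day_b,
              if (x$modal_shift != 0) sprintf(" (day-%g alleles shifted %+d)", x$day_b, x$modal_shift) else ""))
  print(x$rank_sum)
  cat(sprintf("  expanded %d, contracted %d, within day-0 range %d (range %d-%d, margin %d)\n",
              cl$expanded, cl$contracted, cl$within_range,
              cl$day0_range["min"], cl$day0_range["max"], cl$margin))
  invisible(x)
}

#' Read an SP-PCR allele table
#'
#' Tab-separated columns `day`, `pool_id`, `repeat_no`: one row per amplified
#' molecule. An optional `line` column allows several lines per file; pass
#' `line_id` to select one.
#'
#' @param path Path to the TSV.
#' @param line_id Line identifier for the resulting dataset; if the table has
#'   a `line` column, only that line's rows are kept.
#' @return An [sppcr_dataset()] (pool bookkeeping fields left NA).
#' @export
read_sppcr_table <- function(path, line_id = NA_character_) {
  if (!file.exists(path)) stop("SP-PCR table not found: ", path)
  df <- utils::read.delim(path, comment.char = "#")
  need <- c("day", "pool_id", "repeat_no")
  if (!all(need %in% names(df)))
    stop("SP-PCR table must have columns: ", paste(need, collapse = ", "))
  if ("line" %in% names(df) && !is.na(line_id)) {
    df <- df[df$line == line_id, , drop = FALSE]
    if (nrow(df) == 0L) stop("no rows for line ", line_id, " in ", path)
  }
  tp <- split(as.integer(df$repeat_no), as.character(as.numeric(df$day)))
  sppcr_dataset(line_id, tp)
}

#' Write an SP-PCR allele table
#'
#' @param ds An [sppcr_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sppcr_table <- function(ds, path) {
  stopifnot(inherits(ds, "sppcr_dataset"))
  rows <- do.call(rbind, lapply(names(ds$timepoints), function(d) {
    a <- ds$timepoints[[d]]
    data.frame(day = as.numeric(d), pool_id = seq_along(a), repeat_no = a)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
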