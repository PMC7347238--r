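#' Construct a fragment-analysis peak table
#'
#' A peak table is the tabular output of capillary-electrophoresis genotyping
#' software: one row per called peak, with the fragment size in base pairs and
#' the peak height in relative fluorescence units (RFU).
#'
#' @param size_bp Numeric vector of fragment sizes in base pairs (positive).
#' @param height Numeric vector of peak heights in RFU (non-negative, finite).
#' @param sample_id Optional sample identifier.
#' @return A `peak_table`: a data frame with columns `size_bp` and `height`,
#'   sorted by increasing size, with a `sample_id` attribute.
#' @examples
#' peak_table(c(904.1, 901.0), c(300, 500), sample_id = "day0")
#' @export
peak_table <- function(size_bp, height, sample_id = NA_character_) {
  size_bp <- as.numeric(size_bp)
  height <- as.numeric(height)
  if (length(size_bp) != length(height))
    stop("size_bp and height must have the same length")
  if (length(size_bp) == 0L) stop("no parsable rows: a peak table needs at least one peak")
  if (anyNA(size_bp) || anyNA(height) || any(!is.finite(size_bp)) || any(!is.finite(height)))
    stop("sizes and heights must be finite and non-missing")
  if (any(size_bp <= 0)) stop("fragment sizes must be positive")
  if (any(height < 0)) stop("negative heights are not allowed")
  if (all(height == 0)) stop("unusable sample: no peak with positive height")
  ord <- order(size_bp)
  out <- data.frame(size_bp = size_bp[ord], height = height[ord])
  attr(out, "sample_id") <- as.character(sample_id)
  class(out) <- c("peak_table", "data.frame")
  out
}

#' Read a peak table from delimited text
#'
#' Accepts the comma- or tab-delimited exports typical of genotyping software:
#' one header line naming a size column and a height column (matched
#' case-insensitively on the substrings "size" and "height"), then one row per
#' peak. Rows are sorted by size on load; a malformed row aborts the read with
#' its row number. Lines starting with `#` are ignored.
#'
#' @param path Path to the delimited file.
#' @param sample_id Sample identifier; defaults to the file name without
#'   extension.
#' @param delim Field delimiter. `NULL` (default) sniffs tab vs comma from the
#'   header line.
#' @return A [peak_table()].
#' @export
read_peak_table <- function(path, sample_id = NULL, delim = NULL) {
  if (!file.exists(path)) stop("peak table file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L) stop("no parsable rows in ", path)
  if (is.null(delim)) delim <- if (grepl("\t", lines[[1L]], fixed = TRUE)) "\t" else ","
  fields <- strsplit(lines, delim, fixed = TRUE)
  header <- tolower(trimws(fields[[1L]]))
  size_col <- grep("size", header)
  height_col <- grep("height", header)
  if (length(size_col) != 1L || length(height_col) != 1L)
    stop("header must name exactly one size and one height column; got: ",
         paste(header, collapse = ", "))
  rows <- fields[-1L]
  if (length(rows) == 0L) stop("no parsable rows in ", path)
  n <- length(rows)
  size_bp <- numeric(n)
  height <- numeric(n)
  for (i in seq_len(n)) {
    f <- rows[[i]]
    if (length(f) < max(size_col, height_col))
      stop(sprintf("row %d of %s: expected at least %d fields, got %d",
                   i + 1L, path, max(size_col, height_col), length(f)))
    s <- suppressWarnings(as.numeric(trimws(f[size_col])))
    h <- suppressWarnings(as.numeric(trimws(f[height_col])))
    if (is.na(s) || is.na(h))
      stop(sprintf("row %d of %s: could not parse (size, height) from '%s'",
                   i + 1L, path, paste(f, collapse = delim)))
    if (h < 0)
      stop(sprintf("row %d of %s: negative height %g", i + 1L, path, h))
    size_bp[i] <- s
    height[i] <- h
  }
  if (is.null(sample_id)) sample_id <- sub("\\.[^.]*$", "", basename(path))
  peak_table(size_bp, height, sample_id = sample_id)
}

#' Write a peak table as CSV
#'
#' @param table A [peak_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(table, path) {
  stopifnot(inherits(table, "peak_table"))
  lines <- c("size,height",
             sprintf("%.17g,%.17g", table$size_bp, table$height))
  writeLines(lines, path)
  invisible(path)
}

#' Calibration from fragment size to repeat number
#'
#' Maps fragment sizes (bp) to repeat numbers via
#' `repeat_number = (size_bp - flank_bp) / repeat_unit_bp`, where `flank_bp`
#' is the combined non-repeat length of the amplicon. The flank is never
#' guessed: supply it directly, or supply an `anchor` — a sample of known
#' repeat number (for instance the day-0 line of stated size) — from which
#' `flank_bp = size_bp - repeat_number * repeat_unit_bp` is solved.
#'
#' @param repeat_unit_bp Length of the repeat unit in bp (3 for CGG).
#' @param flank_bp Combined non-repeat amplicon length in bp (non-negative).
#' @param anchor Alternative to `flank_bp`: a list or named vector with
#'   `size_bp` and `repeat_number`.
#' @return A `calibration_model` object.
#' @examples
#' calibration_model(repeat_unit_bp = 3, flank_bp = 100)
#' calibration_model(anchor = list(size_bp = 931, repeat_number = 277))
#' @export
calibration_model <- function(repeat_unit_bp = 3L, flank_bp = NULL, anchor = NULL) {
  repeat_unit_bp <- as.integer(repeat_unit_bp)
  if (is.na(repeat_unit_bp) || repeat_unit_bp < 1L)
    stop("repeat_unit_bp must be a positive integer")
  if (is.null(flank_bp) == is.null(anchor))
    stop("supply exactly one of flank_bp or anchor")
  if (!is.null(anchor)) {
    anchor <- as.list(anchor)
    flank_bp <- anchor$size_bp - anchor$repeat_number * repeat_unit_bp
    if (is.na(flank_bp) || flank_bp < 0)
      stop("anchor implies a negative flank length; check size and repeat number")
  }
  flank_bp <- as.numeric(flank_bp)
  if (is.na(flank_bp) || flank_bp < 0) stop("flank_bp must be non-negative")
  structure(list(repeat_unit_bp = repeat_unit_bp, flank_bp = flank_bp),
            class = "calibration_model")
}

#' Convert fragment sizes to repeat numbers
#'
#' Applies the calibration and rounds half away from zero (so 277.5 -> 278),
#' a deterministic rule independent of platform rounding modes.
#'
#' @param size_bp Numeric vector of fragment sizes (bp), each at least
#'   `calib$flank_bp`.
#' @param calib A [calibration_model()].
#' @return Integer vector of repeat numbers.
#' @examples
#' size_to_repeat(931, calibration_model(3, flank_bp = 100))  # 277
#' @export
size_to_repeat <- function(size_bp, calib) {
  stopifnot(inherits(calib, "calibration_model"))
  size_bp <- as.numeric(size_bp)
  if (any(size_bp < calib$flank_bp))
    stop("fragment size smaller than the flank length (", calib$flank_bp, " bp)")
  x <- (size_bp - calib$flank_bp) / calib$repeat_unit_bp
  as.integer(floor(x + 0.5))  # x >= 0, so this is round-half-away-from-zero
}

#' Construct a repeat profile
#'
#' A repeat profile is one sample's peak spectrum expressed in repeat units:
#' a map from integer repeat number to peak height. Duplicate repeat numbers
#' are summed; zero-height bins are dropped.
#'
#' @param repeats Integer vector of repeat numbers (non-negative).
#' @param heights Numeric vector of heights (non-negative, finite).
#' @param sample_id Optional sample identifier.
#' @param day Optional day in culture (non-negative).
#' @return A `repeat_profile`: a data frame with columns `repeat_no` (integer,
#'   strictly increasing) and `height`, plus `sample_id` and `day` attributes.
#' @export
repeat_profile <- function(repeats, heights, sample_id = NA_character_, day = NA_real_) {
  if (length(repeats) != length(heights))
    stop("repeats and heights must have the same length")
  if (length(repeats) == 0L) stop("a repeat profile needs at least one bin")
  if (any(repeats != round(repeats)) || any(repeats < 0))
    stop("repeat numbers must be non-negative integers")
  heights <- as.numeric(heights)
  if (anyNA(heights) || any(!is.finite(heights)) || any(heights < 0))
    stop("heights must be finite and non-negative")
  agg <- rowsum(heights, group = as.integer(repeats))
  repeat_no <- as.integer(rownames(agg))
  height <- as.numeric(agg[, 1L])
  keep <- height > 0
  if (!any(keep)) stop("a repeat profile needs at least one bin with positive height")
  out <- data.frame(repeat_no = repeat_no[keep], height = height[keep])
  attr(out, "sample_id") <- as.character(sample_id)
  attr(out, "day") <- as.numeric(day)
  class(out) <- c("repeat_profile", "data.frame")
  out
}

#' Bin a peak table into a repeat profile
#'
#' Converts each peak's size to a repeat number under the calibration and sums
#' the heights of peaks that map to the same repeat number. Total height is
#' conserved (zero-height peaks carry no mass).
#'
#' @param table A [peak_table()].
#' @param calib A [calibration_model()].
#' @param day Optional day in culture attached to the profile.
#' @return A [repeat_profile()].
#' @export
bin_to_profile <- function(table, calib, day = NA_real_) {
  stopifnot(inherits(table, "peak_table"))
  repeats <- size_to_repeat(table$size_bp, calib)
  repeat_profile(repeats, table$height,
                 sample_id = attr(table, "sample_id"), day = day)
}

#' Write a repeat profile as TSV
#'
#' Columns `repeat` and `height`; `sample_id` and `day` are stored in `#`
#' comment lines. Heights are written with 17 significant digits so that
#' [read_profile()] restores them bit-exactly.
#'
#' @param profile A [repeat_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "repeat_profile"))
  meta <- character(0)
  sid <- attr(profile, "sample_id")
  day <- attr(profile, "day")
  if (!is.na(sid)) meta <- c(meta, paste0("# sample_id: ", sid))
  if (!is.na(day)) meta <- c(meta, sprintf("# day: %.17g", day))
  lines <- c(meta, "repeat\theight",
             sprintf("%d\t%.17g", profile$repeat_no, profile$height))
  writeLines(lines, path)
  invisible(path)
}

#' Read a repeat profile written by [write_profile()]
#'
#' @param path Path to the profile TSV.
#' @return A [repeat_profile()].
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) stop("profile file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  sid <- NA_character_
  day <- NA_real_
  m <- grep("^# sample_id: ", lines)
  if (length(m)) sid <- sub("^# sample_id: ", "", lines[m[1L]])
  m <- grep("^# day: ", lines)
  if (length(m)) day <- as.numeric(sub("^# day: ", "", lines[m[1L]]))
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) < 2L) stop("no parsable rows in ", path)
  fields <- strsplit(lines[-1L], "\t", fixed = TRUE)
  repeats <- vapply(fields, function(f) as.integer(f[1L]), integer(1))
  heights <- vapply(fields, function(f) as.numeric(f[2L]), numeric(1))
  repeat_profile(repeats, heights, sample_id = sid, day = day)
}

#' @export
print.repeat_profile <- function(x, ...) {
  sid <- attr(x, "sample_id")
  day <- attr(x, "day")
  cat("Repeat profile",
      if (!is.na(sid)) paste0("'", sid, "'") else "",
      if (!is.na(day)) sprintf("(day %g)", day) else "", "\n")
  cat(sprintf("  %d bins spanning repeats %d-%d; modal allele %d\n",
              nrow(x), min(x$repeat_no), max(x$repeat_no), call_modal_allele(x)))
  invisible(x)
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("Calibration: repeat unit %d bp, flank %g bp\n",
              x$repeat_unit_bp, x$flank_bp))
  invisible(x)
}
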