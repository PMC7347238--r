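# End-to-end wiring: manifest -> per-line instability report, plus a
# self-contained fixture generator used by the tests and examples.

#' Read a sample manifest
#'
#' A manifest maps sample files to cell line, genotype and day in culture.
#' JSON (array of records) and YAML (list of records) are detected by file
#' extension; each record needs `sample_id`, `file`, `line`, `genotype`,
#' `day`. Relative file paths are resolved against the manifest's directory.
#'
#' @param path Path to a `.json`, `.yaml`/`.yml` manifest.
#' @return A data frame with one row per sample.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  ext <- tolower(sub(".*\\.", "", path))
  recs <- switch(ext,
    json = jsonlite::fromJSON(path, simplifyDataFrame = TRUE),
    yaml = ,
    yml = do.call(rbind, lapply(yaml::read_yaml(path), as.data.frame)),
    stop("unsupported manifest format: .", ext, " (use .json or .yaml)"))
  recs <- as.data.frame(recs)
  need <- c("sample_id", "file", "line", "genotype", "day")
  if (nrow(recs) == 0L) stop("manifest is empty")
  if (!all(need %in% names(recs)))
    stop("manifest must provide fields: ", paste(need, collapse = ", "))
  recs$day <- as.numeric(recs$day)
  recs$file <- ifelse(grepl("^(/|[A-Za-z]:)", recs$file), recs$file,
                      file.path(dirname(path), recs$file))
  recs[need]
}

#' Write a sample manifest as JSON
#'
#' @param manifest Data frame with columns `sample_id`, `file`, `line`,
#'   `genotype`, `day`.
#' @param path Output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = FALSE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

load_sample_profile <- function(file, calibration, day) {
  header <- tolower(readLines(file, n = 5L, warn = FALSE))
  header <- header[!grepl("^\\s*#", header)][1L]
  if (grepl("repeat", header)) {
    p <- read_profile(file)
    attr(p, "day") <- as.numeric(day)
    p
  } else {
    if (is.null(calibration))
      stop("sample file ", file, " is a peak table; a calibration_model is required")
    bin_to_profile(read_peak_table(file), calibration, day = day)
  }
}

#' Run the instability pipeline over a manifest
#'
#' For every cell line in the manifest, loads its samples (peak tables are
#' converted to repeat profiles under `calibration`; repeat-profile TSVs are
#' read directly), calls modal alleles, and computes per-day repeat gain and
#' Expansion Index change relative to the line's earliest sample. The result
#' is one row per (line, day): the same layout as a per-line instability
#' summary table.
#'
#' @param manifest Data frame as returned by [read_manifest()], or a path to
#'   a manifest file.
#' @param calibration A [calibration_model()], required when any sample file
#'   is a raw peak table.
#' @param threshold_fraction,window Passed to [compute_expansion_index()].
#' @param reference,reference_repeat Reference policy for the EI, as in
#'   [delta_expansion_index()].
#' @return A data frame with columns `line`, `genotype`, `day`, `repeat_no`
#'   (modal allele), `delta_repeats`, `ei`, `delta_ei`, and `sample_id`. The
#'   resolved parameters are attached as the `"config"` attribute.
#' @export
run_pipeline <- function(manifest, calibration = NULL,
                         threshold_fraction = 0.10,
                         window = "modal_and_above",
                         reference = c("day0_modal", "fixed"),
                         reference_repeat = NULL) {
  reference <- match.arg(reference)
  if (is.character(manifest) && length(manifest) == 1L)
    manifest <- read_manifest(manifest)
  if (!is.data.frame(manifest) || nrow(manifest) == 0L)
    stop("manifest is empty")
  missing_files <- manifest$file[!file.exists(manifest$file)]
  if (length(missing_files))
    stop("manifest refers to missing files: ", paste(missing_files, collapse = ", "))

  rows <- lapply(split(manifest, manifest$line), function(m) {
    m <- m[order(m$day), ]
    profiles <- Map(load_sample_profile, m$file, list(calibration), m$day)
    ref <- switch(reference,
      day0_modal = call_modal_allele(profiles[[1L]]),
      fixed = as.integer(reference_repeat))
    modal <- vapply(profiles, call_modal_allele, integer(1))
    ei <- vapply(profiles, function(p)
      compute_expansion_index(p, reference_repeat = ref,
                              threshold_fraction = threshold_fraction,
                              window = window)$expansion_index, numeric(1))
    data.frame(line = m$line, genotype = m$genotype, day = m$day,
               repeat_no = modal,
               delta_repeats = modal - modal[1L],
               ei = ei,
               delta_ei = ei - ei[1L],
               sample_id = m$sample_id)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (any(out$day > 52))
    warning("samples beyond 52 days in culture: allele heterogeneity may make modal calls unreliable",
            call. = FALSE)
  attr(out, "config") <- list(threshold_fraction = threshold_fraction,
                              window = window, reference = reference,
                              reference_repeat = reference_repeat)
  out
}

#' Generate a self-contained synthetic dataset on disk
#'
#' Simulates a wild-type and an Mlh3-null line under the genotype presets,
#' renders stuttered traces, and writes: per-sample peak-table CSVs (fragment
#' sizes derived from the calibration), a JSON manifest, an SP-PCR allele TSV
#' for both lines (day 0 vs day 68), and a ground-truth JSON recording the
#' simulation parameters and true modal gains. Output is reproducible
#' bit-exactly from `seed`.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param n_cells Cells per simulated population.
#' @param calibration Calibration used to synthesize fragment sizes.
#' @return Invisibly, a list with `manifest` (path), `sppcr` (path),
#'   `ground_truth` (path).
#' @export
make_fixtures <- function(dir, seed = 1L, n_cells = 4000L,
                          calibration = calibration_model(3L, flank_bp = 120)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)
  specs <- list(
    list(name = "WT", line = "WT_1", start = 277L,
         sample_days = c(0, 40, 52), seed_off = 0L),
    list(name = "Mlh3_null", line = "Mlh3_1", start = 280L,
         sample_days = c(0, 52, 68), seed_off = 1000L))
  manifest <- NULL
  truth <- list(seed = seed, n_cells = n_cells, lines = list())
  sppcr_rows <- NULL
  for (sp in specs) {
    cfg <- genotype_preset(sp$name, n_cells = n_cells, start_repeat = sp$start,
                           sample_days = sp$sample_days,
                           duration_days = max(sp$sample_days),
                           seed = seed + sp$seed_off)
    states <- simulate_population(cfg)
    stut <- stutter_model(height_noise_cv = 0.05)
    for (i in seq_along(states)) {
      st <- states[[i]]
      sid <- sprintf("%s_d%02d", sp$line, as.integer(st$day))
      prof <- render_trace(st, stut, seed = cfg$seed + 7L * i, sample_id = sid)
      sizes <- calibration$flank_bp + calibration$repeat_unit_bp * prof$repeat_no
      f <- paste0(sid, ".csv")
      write_peak_table(peak_table(sizes, prof$height, sample_id = sid),
                       file.path(dir, f))
      manifest <- rbind(manifest,
                        data.frame(sample_id = sid, file = f, line = sp$line,
                                   genotype = sp$name, day = st$day))
    }
    # limiting-dilution sampling at the first and last day
    for (st in states[c(1L, length(states))]) {
      sm <- sample_sp_pcr(st, mean_molecules_per_pool = 1.5, n_pools = 60L,
                          modal_shift = -2L, seed = cfg$seed + 31L + as.integer(st$day))
      if (length(sm$alleles))
        sppcr_rows <- rbind(sppcr_rows,
                            data.frame(line = sp$line, day = st$day,
                                       pool_id = sm$pool_id, repeat_no = sm$alleles))
    }
    truth$lines[[sp$line]] <- list(
      genotype = sp$name, start_repeat = sp$start,
      expansion_rate = cfg$expansion_rate,
      mean_step = sum(as.integer(names(cfg$step_probs)) * cfg$step_probs),
      contraction_rate = cfg$contraction_rate,
      sample_days = cfg$sample_days,
      true_modal = vapply(states, function(s)
        as.integer(names(which.max(table(s$alleles)))), integer(1)))
  }
  manifest_path <- file.path(dir, "manifest.json")
  write_manifest(manifest, manifest_path)
  sppcr_path <- file.path(dir, "sppcr.tsv")
  utils::write.table(sppcr_rows, sppcr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth_path <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(manifest = manifest_path, sppcr = sppcr_path,
                 ground_truth = truth_path))
}
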