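#' Pipeline configuration from files on disk
#'
#' Validates that every referenced input exists at load time (a missing
#' reference is a configuration-time error: no partial outputs). The
#' file-based route carries no read stacks, so the same-read co-variant
#' triage criterion degrades to not-evaluable (conservative).
#'
#' @param panel_bed,panel_fasta panel intervals and per-region reference.
#' @param control_vcfs,patient_vcfs character vectors of VCF paths.
#' @param depth_tsvs named character vector of per-sample depth TSVs
#'   (optional).
#' @param seed integer seed recorded in outputs.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(panel_bed, panel_fasta, control_vcfs,
                            patient_vcfs, depth_tsvs = NULL, seed = 1L) {
  paths <- c(panel_bed, panel_fasta, control_vcfs, patient_vcfs, depth_tsvs)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  structure(list(panel_bed = panel_bed, panel_fasta = panel_fasta,
                 control_vcfs = control_vcfs, patient_vcfs = patient_vcfs,
                 depth_tsvs = depth_tsvs, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a run bundle written by [write_run_bundle()] (or equivalent files)
#'
#' @param config a [pipeline_config()].
#' @return list shaped like a [simulate_run()] bundle (without stacks).
#' @export
load_run_bundle <- function(config) {
  panel <- list(regions = read_regions(config$panel_bed),
                reference = read_panel_fasta(config$panel_fasta))
  read_all <- function(paths) {
    out <- list()
    for (p in paths) {
      cs <- read_variants(p)
      sid <- unique(cs$sample_id)
      if (length(sid) != 1L || is.na(sid))
        sid <- sub("\\.vcf$", "", basename(p))
      out[[sid]] <- cs
    }
    out
  }
  ctl <- read_all(config$control_vcfs)
  pat <- read_all(config$patient_vcfs)
  profiles <- NULL
  if (!is.null(config$depth_tsvs)) {
    profiles <- lapply(config$depth_tsvs, read_depth_profiles)
    if (is.null(names(profiles)))
      names(profiles) <- sub("_depth\\.tsv$", "",
                             basename(config$depth_tsvs))
  }
  samples <- data.frame(
    sample_id = c(names(pat), names(ctl)),
    run_id = c(vapply(pat, function(x) unique(x$run_id)[1L], character(1)),
               vapply(ctl, function(x) unique(x$run_id)[1L], character(1))),
    role = c(rep("patient", length(pat)), rep("control", length(ctl))),
    stringsAsFactors = FALSE)
  list(config = config, panel = panel, samples = samples,
       profiles = profiles, stacks = NULL, callsets = c(pat, ctl),
       manifest = NULL)
}

#' Run the full downstream pipeline over a run bundle
#'
#' Stage order: background-filter (blacklist built from the control call
#' sets, subtracted from every patient), triage of the surviving calls
#' (controls plus same-run patients as the cohort), and the per-patient
#' coverage report. Deterministic: no stage uses randomness.
#'
#' @param bundle a [simulate_run()] bundle or [load_run_bundle()] result.
#' @param thresholds a [triage_thresholds()].
#' @param hotspots optional hotspot `data.frame` for the coverage report.
#' @param out_dir optional directory; when given, filtered VCFs, triage
#'   TSVs and coverage reports are written there.
#' @return list of class `pipeline_result`: `blacklist` and per-patient
#'   entries `kept`, `removed`, `verdicts`, `coverage`.
#' @export
run_pipeline <- function(bundle, thresholds = triage_thresholds(),
                         hotspots = NULL, out_dir = NULL) {
  ctl_ids <- bundle$samples$sample_id[bundle$samples$role == "control"]
  pat_ids <- bundle$samples$sample_id[bundle$samples$role == "patient"]
  controls <- bundle$callsets[ctl_ids]
  bl <- build_blacklist(controls)
  patients <- list()
  for (p in pat_ids) {
    run_of_p <- bundle$samples$run_id[bundle$samples$sample_id == p]
    mates <- bundle$samples$sample_id[
      bundle$samples$run_id %in% run_of_p & bundle$samples$sample_id != p]
    split_calls <- apply_blacklist(bundle$callsets[[p]], bl)
    verdicts <- triage_variants(
      split_calls$kept, thresholds, panel = bundle$panel,
      stacks = if (!is.null(bundle$stacks)) bundle$stacks[[p]] else NULL,
      controls = controls, runmates = bundle$callsets[mates])
    coverage <- NULL
    if (!is.null(bundle$profiles) && p %in% names(bundle$profiles)) {
      stats <- panel_region_stats(bundle$profiles[[p]],
                                  bundle$panel$regions)
      coverage <- coverage_report(stats, bundle$panel$regions, hotspots)
    }
    patients[[p]] <- list(kept = split_calls$kept,
                          removed = split_calls$removed,
                          verdicts = verdicts, coverage = coverage)
  }
  res <- structure(list(blacklist = bl, patients = patients),
                   class = "pipeline_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_blacklist(bl, file.path(out_dir, "blacklist.bed"))
    for (p in names(patients)) {
      write_variants(patients[[p]]$kept,
                     file.path(out_dir, paste0(p, "_filtered.vcf")))
      write_triage(patients[[p]]$verdicts,
                   file.path(out_dir, paste0(p, "_triage.tsv")))
      if (!is.null(patients[[p]]$coverage))
        write_coverage_report(patients[[p]]$coverage,
                              file.path(out_dir, paste0(p, "_coverage.tsv")))
    }
  }
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result:", nrow(x$blacklist), "blacklist entries,",
      length(x$patients), "patients\n")
  for (p in names(x$patients)) {
    v <- x$patients[[p]]$verdicts
    cat("  ", p, ": ", nrow(v), " triaged (",
        sum(v$class == "HIGH_CONFIDENCE"), " high-confidence), ",
        nrow(x$patients[[p]]$removed), " blacklist-removed\n", sep = "")
  }
  invisible(x)
}
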