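#' Configuration for the synthetic panel/run generator
#'
#' The generator emulates the statistical structure of amplicon-capture
#' panel data: heavy-tailed capture non-uniformity (per-region mean depth
#' drawn log-normal), a small fraction of systematically failing regions
#' (mean depth < 20 with partial zero-coverage stretches), germline
#' variants at VAF 0.5/1.0, a low-fraction somatic variant (3% at 257x),
#' recurrent control-cohort artifacts, run-wide artifacts, and
#' homopolymer-adjacent artifacts. A fixed seed yields byte-identical
#' output.
#'
#' @param seed integer RNG seed.
#' @param n_regions number of panel target regions.
#' @param region_length_range min/max region length (bases).
#' @param depth_lognormal_mu,depth_lognormal_sigma log-scale mean and sd of
#'   the per-region mean-depth law (defaults give mean depth around 300,
#'   matching routine run metrics).
#' @param fraction_failing_regions probability that a region is a
#'   systematic failure (default 0.018, i.e. ~1.8% of regions).
#' @param per_base_error_rate per-base sequencing error rate (default
#'   0.01).
#' @param planted_variants optional `data.frame` of extra variants
#'   (`region_id`, `offset` 0-based anchor, `ref`, `alt`, `vaf`) planted in
#'   every patient stack of that region.
#' @param homopolymer_spec optional `data.frame` (`region_id`, `offset`,
#'   `base`, `run_length`) of homopolymer runs embedded verbatim in the
#'   reference.
#' @param n_controls healthy-control samples for background filtering
#'   (default 11).
#' @param control_artifact_sharing integer vector: one artifact per entry,
#'   shared by that many controls (entries >= 2 are blacklist-expected).
#' @param n_patients,n_clean_per_patient patients per run and clean
#'   germline SNVs planted per patient.
#' @param clean_hom_fraction fraction of clean variants planted homozygous
#'   (VAF 1.0) rather than heterozygous (VAF 0.5).
#' @param n_homopolymer_artifacts,n_runwide_artifacts artifact counts.
#' @param lowvaf_vaf,lowvaf_depth the low-fraction somatic case (depth is
#'   forced for its region); `include_lowvaf = FALSE` drops it.
#' @return validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, n_regions = 60L,
                              region_length_range = c(150L, 300L),
                              depth_lognormal_mu = log(300),
                              depth_lognormal_sigma = 0.5,
                              fraction_failing_regions = 0.018,
                              per_base_error_rate = 0.01,
                              planted_variants = NULL,
                              homopolymer_spec = NULL,
                              n_controls = 11L,
                              control_artifact_sharing = c(2L, 2L, 3L, 1L),
                              n_patients = 6L,
                              n_clean_per_patient = 35L,
                              clean_hom_fraction = 0.1,
                              n_homopolymer_artifacts = 4L,
                              n_runwide_artifacts = 4L,
                              lowvaf_vaf = 0.03, lowvaf_depth = 257L,
                              include_lowvaf = TRUE) {
  cfg <- list(seed = as.integer(seed), n_regions = as.integer(n_regions),
              region_length_range = as.integer(region_length_range),
              depth_lognormal_mu = depth_lognormal_mu,
              depth_lognormal_sigma = depth_lognormal_sigma,
              fraction_failing_regions = fraction_failing_regions,
              per_base_error_rate = per_base_error_rate,
              planted_variants = planted_variants,
              homopolymer_spec = homopolymer_spec,
              n_controls = as.integer(n_controls),
              control_artifact_sharing = as.integer(control_artifact_sharing),
              n_patients = as.integer(n_patients),
              n_clean_per_patient = as.integer(n_clean_per_patient),
              clean_hom_fraction = clean_hom_fraction,
              n_homopolymer_artifacts = as.integer(n_homopolymer_artifacts),
              n_runwide_artifacts = as.integer(n_runwide_artifacts),
              lowvaf_vaf = lowvaf_vaf, lowvaf_depth = as.integer(lowvaf_depth),
              include_lowvaf = isTRUE(include_lowvaf))
  if (cfg$n_regions < 1L) stop("n_regions must be >= 1")
  if (cfg$depth_lognormal_sigma < 0) stop("sigma must be >= 0")
  fr <- c(cfg$fraction_failing_regions, cfg$per_base_error_rate,
          cfg$clean_hom_fraction, cfg$lowvaf_vaf)
  if (any(fr < 0 | fr > 1)) stop("all fractions must lie in [0, 1]")
  if (!is.null(cfg$planted_variants) &&
      any(cfg$planted_variants$vaf < 0 | cfg$planted_variants$vaf > 1))
    stop("planted VAFs must lie in [0, 1]")
  if (cfg$n_controls < 0L) stop("n_controls must be >= 0")
  class(cfg) <- "simulation_config"
  cfg
}

derive_seed <- function(seed, k) as.integer((seed + k) %% 2147483587L)

#' Simulate a panel: reference windows and target regions
#'
#' Regions are laid out on one contig with inter-region gaps; each gets a
#' uniform-random reference sequence; genes are assigned in blocks of five
#' regions (panel designs carry several exons per gene). Homopolymer runs
#' from `config$homopolymer_spec` are embedded verbatim at their stated
#' offsets; a run exceeding its region is a configuration error.
#'
#' @param config a [simulation_config()].
#' @return list with `regions` (see [target_regions()]) and `reference`
#'   (named character vector of per-region reference strings).
#' @export
simulate_panel <- function(config) {
  set.seed(derive_seed(config$seed, 0L))
  n <- config$n_regions
  len <- sample(seq(config$region_length_range[1L],
                    config$region_length_range[2L]), n, replace = TRUE)
  gap <- 100L
  start <- cumsum(c(1000L, utils::head(len, -1L) + gap))
  regions <- target_regions(
    region_id = sprintf("region_%03d", seq_len(n)),
    gene = sprintf("GENE%03d", (seq_len(n) - 1L) %/% 5L + 1L),
    chrom = "chr1", start = start, end = start + len)
  regions <- regions[order(regions$start), , drop = FALSE]
  reference <- vapply(len, function(l)
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = ""),
    character(1))
  names(reference) <- sprintf("region_%03d", seq_len(n))
  hp <- config$homopolymer_spec
  if (!is.null(hp)) {
    for (i in seq_len(nrow(hp))) {
      id <- hp$region_id[i]
      l <- nchar(reference[[id]])
      if (hp$offset[i] < 0L || hp$offset[i] + hp$run_length[i] > l)
        stop("homopolymer run exceeds region bounds in ", id)
      substr(reference[[id]], hp$offset[i] + 1L,
             hp$offset[i] + hp$run_length[i]) <-
        strrep(hp$base[i], hp$run_length[i])
    }
  }
  list(regions = regions, reference = reference)
}

#' Write a panel's reference as FASTA (one record per region)
#'
#' @param panel a [simulate_panel()] result.
#' @param path FASTA file.
#' @return `path`, invisibly.
#' @export
write_panel_fasta <- function(panel, path) {
  x <- Biostrings::DNAStringSet(panel$reference)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read per-region reference windows from FASTA
#'
#' @param path FASTA file with one record per region, named by region id.
#' @return named character vector.
#' @export
read_panel_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Simulate per-base depth profiles with capture non-uniformity
#'
#' Per-region mean depth is log-normal (heavy-tailed, as capture
#' efficiency is); per-base depths are Poisson around the region mean.
#' With probability `fraction_failing_regions` a region is a systematic
#' failure: mean depth forced below 20 and a contiguous 15-50% stretch of
#' the region set to zero coverage.
#'
#' @param config a [simulation_config()].
#' @param regions region `data.frame`.
#' @param seed RNG seed (defaults to a stream derived from the config
#'   seed).
#' @param force_ok region ids exempted from failure.
#' @param force_mean named numeric vector pinning specific regions' mean
#'   depth.
#' @return named list of integer depth vectors; attribute `failing` holds
#'   the failed region ids.
#' @export
simulate_depth_profiles <- function(config, regions,
                                    seed = derive_seed(config$seed, 1L),
                                    force_ok = character(),
                                    force_mean = NULL) {
  if (nrow(regions) == 0L) stop("regions must be nonempty")
  if (config$depth_lognormal_sigma < 0) stop("sigma must be >= 0")
  set.seed(seed)
  n <- nrow(regions)
  means <- stats::rlnorm(n, config$depth_lognormal_mu,
                         config$depth_lognormal_sigma)
  failing <- stats::runif(n) < config$fraction_failing_regions
  failing[regions$region_id %in% force_ok] <- FALSE
  if (!is.null(force_mean)) {
    hit <- match(names(force_mean), regions$region_id)
    means[hit[!is.na(hit)]] <- force_mean[!is.na(hit)]
    failing[hit[!is.na(hit)]] <- FALSE
  }
  out <- vector("list", n)
  for (i in seq_len(n)) {
    l <- regions$end[i] - regions$start[i]
    if (failing[i]) {
      m <- stats::runif(1, 2, 18)
      d <- stats::rpois(l, m)
      frac <- stats::runif(1, 0.15, 0.5)
      zlen <- max(1L, floor(frac * l))
      z0 <- sample.int(l - zlen + 1L, 1L)
      d[z0:(z0 + zlen - 1L)] <- 0L
    } else {
      d <- stats::rpois(l, means[i])
    }
    out[[i]] <- as.integer(d)
  }
  names(out) <- regions$region_id
  structure(out, failing = regions$region_id[failing])
}

#' Simulate a columnar read stack over one region
#'
#' Reads span the whole region window; the number of reads is the rounded
#' mean of the region's depth profile (per-base depth heterogeneity lives
#' in the depth profile, not the stack). At each planted variant the
#' alt-supporting read count is Binomial(n_reads, vaf); all other
#' positions carry independent substitution errors at `error_rate`;
#' strands are Bernoulli(`strand_prob`).
#'
#' @param region one-row region `data.frame`.
#' @param ref_seq reference string of the region.
#' @param profile integer depth vector of the region.
#' @param planted `data.frame` with `offset` (0-based anchor within the
#'   region), `ref`, `alt`, `vaf`; or `NULL`.
#' @param error_rate per-base substitution error rate.
#' @param seed optional seed (`NULL` continues the current RNG stream).
#' @param strand_prob probability a read is forward-strand.
#' @param sample_id,run_id provenance for emitted calls.
#' @return a [read_stack()].
#' @export
simulate_read_stack <- function(region, ref_seq, profile, planted = NULL,
                                error_rate = 0.01, seed = NULL,
                                strand_prob = 0.5,
                                sample_id = NA_character_,
                                run_id = NA_character_) {
  if (!is.null(seed)) set.seed(seed)
  refv <- strsplit(toupper(ref_seq), "", fixed = TRUE)[[1]]
  w <- length(refv)
  n_reads <- max(0L, as.integer(round(mean(profile))))
  if (!is.null(planted) && nrow(planted)) {
    if (any(planted$vaf < 0 | planted$vaf > 1))
      stop("planted VAFs must lie in [0, 1]")
    foot_last <- planted$offset + nchar(planted$ref)
    if (any(planted$offset < 0L) || any(foot_last > w))
      stop("planted position outside the region window")
  }
  if (n_reads == 0L) {
    return(read_stack(region$chrom, region$start, ref_seq,
                      matrix(character(0), 0L, w), character(0),
                      sample_id = sample_id, run_id = run_id))
  }
  obs <- matrix(rep(refv, each = n_reads), nrow = n_reads, ncol = w)
  planted_cols <- integer(0)
  if (!is.null(planted) && nrow(planted)) {
    planted_cols <- unlist(lapply(seq_len(nrow(planted)), function(i)
      seq(planted$offset[i] + 1L, length.out = nchar(planted$ref[i]))))
  }
  err_cols <- setdiff(seq_len(w), planted_cols)
  if (error_rate > 0 && length(err_cols)) {
    ncell <- n_reads * length(err_cols)
    hit <- which(stats::runif(ncell) < error_rate)
    if (length(hit)) {
      rowi <- ((hit - 1L) %% n_reads) + 1L
      coli <- err_cols[((hit - 1L) %/% n_reads) + 1L]
      alt_of <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                     G = c("A", "C", "T"), T = c("A", "C", "G"))
      pick <- sample.int(3L, length(hit), replace = TRUE)
      for (k in seq_along(hit))
        obs[rowi[k], coli[k]] <- alt_of[[refv[coli[k]]]][pick[k]]
    }
  }
  if (!is.null(planted) && nrow(planted)) {
    for (i in seq_len(nrow(planted))) {
      n_alt <- stats::rbinom(1L, n_reads, planted$vaf[i])
      if (n_alt == 0L) next
      rows <- sample.int(n_reads, n_alt)
      a <- toupper(planted$alt[i]); r <- toupper(planted$ref[i])
      off1 <- planted$offset[i] + 1L
      if (nchar(r) == 1L && nchar(a) == 1L) {
        obs[rows, off1] <- a
      } else if (nchar(r) > nchar(a)) {       # deletion, anchored
        obs[rows, (off1 + 1L):(off1 + nchar(r) - 1L)] <- "-"
      } else {                                # insertion, anchored
        obs[rows, off1] <- paste0(refv[off1], "+", substring(a, 2L))
      }
    }
  }
  strand <- sample(c("+", "-"), n_reads, replace = TRUE,
                   prob = c(strand_prob, 1 - strand_prob))
  read_stack(region$chrom, region$start, ref_seq, obs, strand,
             sample_id = sample_id, run_id = run_id)
}

# 0-based anchor offsets within a region at which an SNV would pass the
# sequence-context criterion (with an edge margin so the scan window fits).
context_safe_offsets <- function(ref_seq, thresholds = triage_thresholds(),
                                 margin = 16L) {
  l <- nchar(ref_seq)
  cand <- seq.int(margin, l - margin - 1L)
  ok <- vapply(cand, function(o)
    check_context(o + 1L, 1L, ref_seq, 1L, thresholds) == "pass",
    logical(1))
  cand[ok]
}

other_base <- function(b) {
  vapply(b, function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1L),
         character(1), USE.NAMES = FALSE)
}

#' Simulate a complete multi-sample run bundle
#'
#' Generates a panel, per-sample depth profiles, per-sample read stacks,
#' and per-sample call sets for a cohort of healthy controls (their own
#' run) and patients sharing one run, with planted events of known intent:
#'
#' * clean germline SNVs (VAF 0.5, a fraction homozygous at 1.0), one per
#'   region per patient, at context-safe positions — intended
#'   `HIGH_CONFIDENCE`;
#' * homopolymer-adjacent artifact SNVs — intended `NEEDS_CONFIRMATION`
#'   (context criterion);
#' * run-wide artifacts planted in every patient of the run — intended
#'   `NEEDS_CONFIRMATION` (run-mate criterion);
#' * control-cohort artifacts shared by the configured numbers of controls
#'   and planted in one patient each — shared by more than one control
#'   means blacklist-expected (removed before triage), a single-control
#'   artifact fails only the wild-type-control criterion;
#' * optionally one low-fraction somatic variant (3% VAF at forced depth
#'   257) — not called under the default allele-frequency cutoff.
#'
#' All planted keys are annotated `predicted_deleterious` in every call
#' set (the flag is an input annotation in this toolkit). The truth
#' manifest enumerates every planted event with its intended outcome, so
#' downstream evaluation never re-derives intent from data.
#'
#' @param config a [simulation_config()].
#' @param settings [caller_settings()] used to produce the per-sample call
#'   sets.
#' @return list of class `run_bundle`: `config`, `panel`, `samples`
#'   (data.frame with `sample_id`, `run_id`, `role`), `profiles` (named by
#'   sample), `stacks` (patients only, `stacks[[sample]][[region_id]]`),
#'   `callsets` (named by sample), `manifest` (one row per planted event).
#' @export
simulate_run <- function(config, settings = caller_settings()) {
  panel0 <- simulate_panel(config)
  regions <- panel0$regions
  n <- nrow(regions)
  set.seed(derive_seed(config$seed, 2L))

  n_hp <- min(config$n_homopolymer_artifacts, max(0L, n - 2L))
  n_rw <- config$n_runwide_artifacts
  n_ctl_art <- length(config$control_artifact_sharing)
  n_special <- n_hp + n_rw + n_ctl_art + as.integer(config$include_lowvaf)
  if (n_special > n)
    stop("config plants more artifact regions (", n_special,
         ") than regions (", n, ")")
  special <- sample(regions$region_id, n_special)
  hp_regions <- utils::head(special, n_hp)
  rw_regions <- special[seq_len(n_rw) + n_hp]
  ctl_regions <- special[seq_len(n_ctl_art) + n_hp + n_rw]
  lowvaf_region <- if (config$include_lowvaf) special[n_special] else NULL
  clean_pool <- setdiff(regions$region_id, special)

  # homopolymer runs embedded mid-region; panel rebuilt with them in place
  hp_spec <- NULL
  if (n_hp > 0L) {
    lens <- regions$end[match(hp_regions, regions$region_id)] -
      regions$start[match(hp_regions, regions$region_id)]
    hp_spec <- data.frame(
      region_id = hp_regions,
      offset = as.integer(lens %/% 2L),
      base = sample(c("A", "C", "G", "T"), n_hp, replace = TRUE),
      run_length = sample(6:8, n_hp, replace = TRUE),
      stringsAsFactors = FALSE)
  }
  cfg2 <- config
  cfg2$homopolymer_spec <- if (is.null(config$homopolymer_spec)) hp_spec else
    rbind(config$homopolymer_spec, hp_spec)
  panel <- simulate_panel(cfg2)
  set.seed(derive_seed(config$seed, 3L))

  patients <- sprintf("P%02d", seq_len(config$n_patients))
  controls <- sprintf("C%02d", seq_len(config$n_controls))
  samples <- data.frame(
    sample_id = c(patients, controls),
    run_id = c(rep("RUN1", length(patients)), rep("RUN0", length(controls))),
    role = c(rep("patient", length(patients)),
             rep("control", length(controls))),
    stringsAsFactors = FALSE)

  rregion <- function(id) panel$regions[panel$regions$region_id == id, ,
                                        drop = FALSE]
  safe <- lapply(panel$reference, context_safe_offsets)
  used <- lapply(panel$reference, function(x) integer(0))
  take_offset <- function(id) {
    avail <- setdiff(safe[[id]], used[[id]])
    if (length(avail) == 0L) stop("no context-safe offsets left in ", id)
    o <- if (length(avail) == 1L) avail else sample(avail, 1L)
    used[[id]] <<- c(used[[id]], o)
    o
  }
  ref_at <- function(id, off) substr(panel$reference[[id]], off + 1L,
                                     off + 1L)
  plant_row <- function(kind, id, off, vaf, sample_ids,
                        expected, blacklist_expected = FALSE) {
    r <- ref_at(id, off)
    reg <- rregion(id)
    data.frame(kind = kind, region_id = id,
               chrom = reg$chrom, pos = reg$start + off + 1L,
               ref = r, alt = other_base(r), vaf = vaf,
               samples = paste(sample_ids, collapse = ","),
               expected_triage = expected,
               blacklist_expected = blacklist_expected,
               stringsAsFactors = FALSE)
  }

  manifest <- list()
  # clean germline SNVs
  for (p in patients) {
    ids <- sample(clean_pool, min(config$n_clean_per_patient,
                                  length(clean_pool)))
    for (id in ids) {
      hom <- stats::runif(1) < config$clean_hom_fraction
      manifest[[length(manifest) + 1L]] <-
        plant_row(if (hom) "clean_hom" else "clean_het", id,
                  take_offset(id), if (hom) 1.0 else 0.5, p,
                  "HIGH_CONFIDENCE")
    }
  }
  # homopolymer-adjacent artifacts (anchor right after the embedded run)
  if (n_hp > 0L) {
    for (k in seq_len(n_hp)) {
      id <- hp_spec$region_id[k]
      off <- hp_spec$offset[k] + hp_spec$run_length[k]  # base 3' of the run
      manifest[[length(manifest) + 1L]] <-
        plant_row("homopolymer_artifact", id, off, 0.45,
                  patients[(k - 1L) %% length(patients) + 1L],
                  "NEEDS_CONFIRMATION")
    }
  }
  # run-wide artifacts: present in every patient of the run
  for (k in seq_along(rw_regions)) {
    id <- rw_regions[k]
    manifest[[length(manifest) + 1L]] <-
      plant_row("runwide_artifact", id, take_offset(id), 0.5, patients,
                "NEEDS_CONFIRMATION")
  }
  # control-cohort artifacts
  for (k in seq_along(config$control_artifact_sharing)) {
    m <- config$control_artifact_sharing[k]
    id <- ctl_regions[k]
    carriers <- utils::head(controls, m)
    host <- patients[(k - 1L) %% length(patients) + 1L]
    shared <- m > 1L
    manifest[[length(manifest) + 1L]] <-
      plant_row(if (shared) "control_artifact_shared" else
        "control_artifact_single", id, take_offset(id), 0.5,
        c(host, carriers),
        if (shared) "BLACKLIST_REMOVED" else "NEEDS_CONFIRMATION",
        blacklist_expected = shared)
  }
  # low-fraction somatic variant
  if (config$include_lowvaf) {
    manifest[[length(manifest) + 1L]] <-
      plant_row("somatic_lowvaf", lowvaf_region, take_offset(lowvaf_region),
                config$lowvaf_vaf, patients[1L], "NOT_CALLED")
  }
  # user-specified extra plants, in every patient
  if (!is.null(config$planted_variants)) {
    pv <- config$planted_variants
    for (i in seq_len(nrow(pv))) {
      reg <- rregion(pv$region_id[i])
      manifest[[length(manifest) + 1L]] <- data.frame(
        kind = "user", region_id = pv$region_id[i], chrom = reg$chrom,
        pos = reg$start + pv$offset[i] + 1L, ref = pv$ref[i],
        alt = pv$alt[i], vaf = pv$vaf[i],
        samples = paste(patients, collapse = ","),
        expected_triage = NA_character_, blacklist_expected = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, manifest)
  manifest$key <- variant_key(manifest)

  # per-sample depth profiles, stacks and call sets
  force_mean <- NULL
  if (config$include_lowvaf) {
    force_mean <- stats::setNames(as.numeric(config$lowvaf_depth),
                                  lowvaf_region)
  }
  profiles <- list(); callsets <- list(); stacks <- list()
  for (si in seq_len(nrow(samples))) {
    s <- samples$sample_id[si]
    prof <- simulate_depth_profiles(
      config, panel$regions, seed = derive_seed(config$seed, 100L + si),
      force_ok = special, force_mean = force_mean)
    profiles[[s]] <- prof
    set.seed(derive_seed(config$seed, 10000L + si))
    mine <- manifest[vapply(strsplit(manifest$samples, ",", fixed = TRUE),
                            function(x) s %in% x, logical(1)), ,
                     drop = FALSE]
    calls <- list()
    sample_stacks <- list()
    for (ri in seq_len(nrow(panel$regions))) {
      id <- panel$regions$region_id[ri]
      reg <- panel$regions[ri, , drop = FALSE]
      pl <- mine[mine$region_id == id, , drop = FALSE]
      planted <- if (nrow(pl)) data.frame(
        offset = pl$pos - reg$start - 1L, ref = pl$ref, alt = pl$alt,
        vaf = pl$vaf, stringsAsFactors = FALSE) else NULL
      st <- simulate_read_stack(reg, panel$reference[[id]], prof[[id]],
                                planted, config$per_base_error_rate,
                                sample_id = s, run_id = samples$run_id[si])
      calls[[ri]] <- call_variants(st, settings)
      if (samples$role[si] == "patient") sample_stacks[[id]] <- st
    }
    cs <- do.call(rbind, calls)
    cs$predicted_deleterious <- variant_key(cs) %in% manifest$key
    callsets[[s]] <- cs
    if (samples$role[si] == "patient") stacks[[s]] <- sample_stacks
  }

  structure(list(config = config, panel = panel, samples = samples,
                 profiles = profiles, stacks = stacks, callsets = callsets,
                 manifest = manifest),
            class = "run_bundle")
}

#' @export
print.run_bundle <- function(x, ...) {
  cat("run_bundle:", nrow(x$panel$regions), "regions,",
      sum(x$samples$role == "patient"), "patients,",
      sum(x$samples$role == "control"), "controls,",
      nrow(x$manifest), "planted events\n")
  invisible(x)
}

#' Write a run bundle to disk as standard formats
#'
#' FASTA reference, BED regions, one VCF per sample, per-sample depth TSVs
#' and the TSV truth manifest.
#'
#' @param bundle a [simulate_run()] bundle.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_panel_fasta(bundle$panel, file.path(dir, "panel.fasta"))
  write_regions(bundle$panel$regions, file.path(dir, "panel.bed"))
  for (s in names(bundle$callsets))
    write_variants(bundle$callsets[[s]], file.path(dir, paste0(s, ".vcf")),
                   sample_id = s,
                   run_id = bundle$samples$run_id[
                     bundle$samples$sample_id == s])
  for (s in names(bundle$profiles))
    write_depth_profiles(bundle$profiles[[s]],
                         file.path(dir, paste0(s, "_depth.tsv")))
  utils::write.table(bundle$manifest, file.path(dir, "truth_manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
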