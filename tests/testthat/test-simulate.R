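small_cfg <- function(seed = 11) {
  simulation_config(
    seed = seed, n_regions = 12L, region_length_range = c(100L, 140L),
    depth_lognormal_mu = log(150), depth_lognormal_sigma = 0.3,
    fraction_failing_regions = 0, n_controls = 3L,
    control_artifact_sharing = c(2L, 1L), n_patients = 2L,
    n_clean_per_patient = 4L, n_homopolymer_artifacts = 1L,
    n_runwide_artifacts = 1L)
}

test_that("panel simulation is seed-deterministic and embeds homopolymer runs verbatim", {
  hp <- data.frame(region_id = "region_001", offset = 10L, base = "A",
                   run_length = 6L, stringsAsFactors = FALSE)
  cfg <- simulation_config(seed = 4, n_regions = 3,
                           region_length_range = c(80L, 100L),
                           homopolymer_spec = hp)
  p1 <- simulate_panel(cfg)
  p2 <- simulate_panel(cfg)
  expect_identical(p1, p2)
  expect_equal(substr(p1$reference[["region_001"]], 11, 16), "AAAAAA")
  # FASTA write/read round trip
  f <- withr::local_tempfile(fileext = ".fasta")
  write_panel_fasta(p1, f)
  expect_equal(read_panel_fasta(f), p1$reference)
  # run exceeding region bounds is a config error
  hp_bad <- data.frame(region_id = "region_001", offset = 95L, base = "A",
                       run_length = 10L, stringsAsFactors = FALSE)
  cfg_bad <- simulation_config(seed = 4, n_regions = 3,
                               region_length_range = c(80L, 100L),
                               homopolymer_spec = hp_bad)
  expect_error(simulate_panel(cfg_bad), "exceeds region bounds")
})

test_that("a 100-region panel yields 100 unique region records", {
  cfg <- simulation_config(seed = 6, n_regions = 100,
                           region_length_range = c(50L, 60L))
  p <- simulate_panel(cfg)
  expect_equal(nrow(p$regions), 100L)
  expect_false(anyDuplicated(p$regions$region_id) > 0)
  f <- withr::local_tempfile(fileext = ".bed")
  write_regions(p$regions, f)
  expect_equal(nrow(read_regions(f)), 100L)
})

test_that("failing-region fraction matches the configured rate at panel scale", {
  cfg <- simulation_config(seed = 8, n_regions = 2455,
                           region_length_range = c(60L, 80L),
                           fraction_failing_regions = 0.018)
  regions <- simulate_panel(cfg)$regions
  prof <- simulate_depth_profiles(cfg, regions)
  failing <- attr(prof, "failing")
  # binomial(2455, 0.018): expect ~45, allow a generous central band
  expect_gt(length(failing), qbinom(0.0005, 2455, 0.018))
  expect_lt(length(failing), qbinom(0.9995, 2455, 0.018))
  # forced failures really are failures under the coverage rules
  st <- panel_region_stats(prof[failing], regions)
  expect_true(all(st$unreliable))
  # zero fraction with a tight distribution yields zero failing regions
  cfg0 <- simulation_config(seed = 8, n_regions = 50,
                            region_length_range = c(60L, 80L),
                            depth_lognormal_mu = log(300),
                            depth_lognormal_sigma = 0,
                            fraction_failing_regions = 0)
  p0 <- simulate_depth_profiles(cfg0, simulate_panel(cfg0)$regions)
  expect_length(attr(p0, "failing"), 0)
  expect_true(all(vapply(p0, mean, numeric(1)) > 20))
})

test_that("planted alt-read counts are binomial with the configured VAF", {
  reg <- target_regions("r", "G", "chr1", 0L, 20L)
  refseq <- paste(rep("ACGTC", 4), collapse = "")
  rb <- substr(refseq, 11, 11)
  alt <- setdiff(c("A", "C", "G", "T"), rb)[1]
  set.seed(123)
  alts <- vapply(1:1000, function(i) {
    st <- simulate_read_stack(reg, refseq, rep(257L, 20),
                              data.frame(offset = 10L, ref = rb, alt = alt,
                                         vaf = 0.03),
                              error_rate = 0)
    sum(st$obs[, 11] == alt)
  }, numeric(1))
  expect_equal(mean(alts), 257 * 0.03, tolerance = 0.3 / (257 * 0.03))
})

test_that("degenerate stack configurations behave by definition", {
  reg <- target_regions("r", "G", "chr1", 0L, 10L)
  refseq <- "ACGTACGTAC"
  rb <- substr(refseq, 5, 5)
  st <- simulate_read_stack(reg, refseq, rep(30L, 10),
                            data.frame(offset = 4L, ref = rb, alt = "T",
                                       vaf = 1),
                            error_rate = 0, seed = 1)
  expect_true(all(st$obs[, 5] == "T"))          # VAF 1, no error: all alt
  st0 <- simulate_read_stack(reg, refseq, rep(30L, 10), NULL,
                             error_rate = 0, seed = 1)
  for (j in 1:10)
    expect_true(all(st0$obs[, j] == substr(refseq, j, j)))
  expect_error(
    simulate_read_stack(reg, refseq, rep(30L, 10),
                        data.frame(offset = 9L, ref = "AC", alt = "A",
                                   vaf = 0.5)),
    "outside the region")
})

test_that("run bundles are seed-deterministic and manifest marks blacklist expectations", {
  b1 <- simulate_run(small_cfg())
  b2 <- simulate_run(small_cfg())
  expect_identical(b1$manifest, b2$manifest)
  expect_identical(lapply(b1$callsets, variant_key),
                   lapply(b2$callsets, variant_key))
  m <- b1$manifest
  shared <- m[m$kind == "control_artifact_shared", ]
  single <- m[m$kind == "control_artifact_single", ]
  expect_true(all(shared$blacklist_expected))
  expect_false(any(single$blacklist_expected))
  # the shared artifact is planted in 2 controls, the single in 1
  expect_equal(lengths(strsplit(shared$samples, ",")), 3)  # host + 2 controls
  expect_equal(lengths(strsplit(single$samples, ",")), 2)  # host + 1 control
  # zero artifacts configured -> empty expected blacklist
  cfg0 <- simulation_config(
    seed = 3, n_regions = 6L, region_length_range = c(100L, 120L),
    fraction_failing_regions = 0, n_controls = 2L,
    control_artifact_sharing = integer(0), n_patients = 1L,
    n_clean_per_patient = 2L, n_homopolymer_artifacts = 0L,
    n_runwide_artifacts = 0L, include_lowvaf = FALSE)
  b0 <- simulate_run(cfg0)
  expect_equal(sum(b0$manifest$blacklist_expected), 0L)
})

test_that("the caller recovers planted VAF-0.5 variants at depth >= 100 in >= 99% of replicates", {
  reg <- target_regions("r", "G", "chr1", 0L, 25L)
  refseq <- paste(rep("ACGTG", 5), collapse = "")
  rb <- substr(refseq, 13, 13)
  alt <- setdiff(c("A", "C", "G", "T"), rb)[1]
  set.seed(2024)
  hits <- vapply(1:200, function(i) {
    st <- simulate_read_stack(reg, refseq, rep(120L, 25),
                              data.frame(offset = 12L, ref = rb, alt = alt,
                                         vaf = 0.5),
                              error_rate = 0.01, sample_id = "P",
                              run_id = "R")
    calls <- call_variants(st)
    any(calls$pos == 13L & calls$alt == alt)
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})
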