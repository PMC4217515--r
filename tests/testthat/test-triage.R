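# 21-mer of period 4 (unit above the repeat-unit maximum) with no
# homopolymer run: clean context for a centred SNV.
clean_window <- "ACGTACGTACGTACGTACGTA"

snv <- function(pos, q = 50, depth = 100L, vaf = NULL, alt_f = 25L,
                alt_r = 25L, ref = "G", alt = "A", chrom = "chr1") {
  variant_calls("P01", "RUN1", chrom, pos, ref, alt, quality = q,
                depth = depth, alt_fwd = alt_f, alt_rev = alt_r, vaf = vaf)
}

test_that("homopolymer-adjacent and repeat-adjacent variants fail the context check", {
  # SNV immediately 3' of an AAAAA run
  w <- "GCTGGCTGGCAAAAAGCTGGCTGGCTG"
  expect_equal(check_context(16, 1, w, 1), "fail")
  # inside the run itself
  expect_equal(check_context(13, 1, w, 1), "fail")
  # two bases away from the run: beyond "immediately adjacent"
  expect_equal(check_context(18, 1, w, 1), "pass")
  # short tandem repeat (unit 2, span 10) abutting the variant
  w2 <- "GCCTGAGTCATATATATATGCCTGAGTCA"
  expect_equal(check_context(20, 1, w2, 1), "fail")
  # period-4 context passes (unit above the maximum, no runs)
  expect_equal(check_context(11, 1, clean_window, 1), "pass")
  # window too small to scan
  expect_equal(check_context(3, 1, "ACGTT", 1), "not_evaluable")
})

test_that("co-variant check fails on shared second alleles, tolerates lone errors", {
  n <- 20L
  refv <- strsplit(clean_window, "", fixed = TRUE)[[1]]
  mk <- function(edit) {
    obs <- matrix(rep(refv, each = n), nrow = n)
    obs[1:8, 11] <- "A"           # alt reads (ref at col 11 is G)
    edit(obs)
  }
  v <- snv(11, vaf = 0.4)
  st_clean <- read_stack("chr1", 0L, clean_window,
                         mk(identity), rep(c("+", "-"), 10))
  expect_equal(check_read_covariants(v, st_clean), "pass")
  # every alt read carries a second shared mismatch -> fail
  st_hap <- read_stack("chr1", 0L, clean_window,
                       mk(function(o) { o[1:8, 5] <- "C"; o }),
                       rep(c("+", "-"), 10))
  expect_equal(check_read_covariants(v, st_hap), "fail")
  # a mismatch on a single alt read is sequencing error -> ignored
  st_err <- read_stack("chr1", 0L, clean_window,
                       mk(function(o) { o[3, 7] <- "T"; o }),
                       rep(c("+", "-"), 10))
  expect_equal(check_read_covariants(v, st_err), "pass")
  # no alt-read observations -> not evaluable
  v9 <- snv(11, alt = "T", vaf = 0.4)
  expect_equal(check_read_covariants(v9, st_clean), "not_evaluable")
  # no stack at all -> not evaluable
  expect_equal(check_read_covariants(v, NULL), "not_evaluable")
})

test_that("cohort check fails on any control or run-mate occurrence", {
  v <- snv(11)
  other <- snv(12)
  expect_equal(check_cohort(v, list(), list()),
               list(controls = "pass", runmates = "pass"))
  expect_equal(check_cohort(v, list(), list(v))$runmates, "fail")
  expect_equal(check_cohort(v, list(v), list())$controls, "fail")
  expect_equal(check_cohort(v, list(other), list(other)),
               list(controls = "pass", runmates = "pass"))
})

test_that("any INDEL needs confirmation regardless of other criteria", {
  ind <- variant_calls("P01", "RUN1", "chr1", 11L, "GT", "G", quality = 90,
                       depth = 500L, alt_fwd = 120L, alt_rev = 130L)
  verdict <- classify_variant(ind, window = clean_window, window_start = 1L)
  expect_equal(verdict$class, "NEEDS_CONFIRMATION")
  expect_true(grepl("snv_type", verdict$reasons))
})

test_that("exact-boundary SNV (q 30, depth 20, VAF 0.25) is high confidence", {
  n <- 20L
  st <- clean_stack(clean_window, n, 11, "A", 5)
  v <- snv(11, q = 30, depth = 20L, alt_f = 3L, alt_r = 2L)
  expect_equal(v$vaf, 0.25)
  verdict <- classify_variant(v, window = clean_window, window_start = 1L,
                              stack = st)
  expect_equal(verdict$class, "HIGH_CONFIDENCE")
  expect_equal(verdict$reasons, "")
  # one unit below any numeric boundary drops it
  for (tweak in list(snv(11, q = 29.9, depth = 20L, alt_f = 3L, alt_r = 2L),
                     snv(11, q = 30, depth = 19L, alt_f = 3L, alt_r = 2L),
                     snv(11, q = 30, depth = 20L, vaf = 0.249,
                         alt_f = 3L, alt_r = 2L))) {
    expect_equal(classify_variant(tweak, window = clean_window,
                                  window_start = 1L, stack = st)$class,
                 "NEEDS_CONFIRMATION")
  }
})

test_that("a 3%-VAF call at depth 257 needs confirmation and is flagged somatic-suspect", {
  v <- snv(11, q = 35, depth = 257L, alt_f = 4L, alt_r = 4L)
  st <- clean_stack(clean_window, 257L, 11, "A", 8)
  verdict <- classify_variant(v, window = clean_window, window_start = 1L,
                              stack = st)
  expect_equal(verdict$class, "NEEDS_CONFIRMATION")
  expect_true(grepl("vaf", verdict$reasons))
  expect_true(verdict$somatic_suspect)
  # low VAF with too few alt reads is not somatic-suspect
  v2 <- snv(11, q = 35, depth = 257L, alt_f = 1L, alt_r = 1L)
  expect_false(classify_variant(v2, window = clean_window,
                                window_start = 1L)$somatic_suspect)
})

test_that("missing context degrades to not-evaluable and blocks high confidence", {
  v <- snv(11)
  verdict <- classify_variant(v)   # no window, no stack
  expect_equal(verdict$class, "NEEDS_CONFIRMATION")
  expect_equal(verdict$context, "not_evaluable")
  expect_equal(verdict$no_read_covariants, "not_evaluable")
  expect_true(grepl("context", verdict$reasons))
  expect_true(grepl("no_read_covariants", verdict$reasons))
})

test_that("verdict reasons name exactly the non-passing criteria", {
  st <- clean_stack(clean_window, 100L, 11, "A", 40)
  v <- snv(11, q = 10, depth = 100L, alt_f = 10L, alt_r = 10L)  # q + vaf fail
  verdict <- classify_variant(v, window = clean_window, window_start = 1L,
                              stack = st)
  got <- sort(strsplit(verdict$reasons, ",")[[1]])
  crits <- c("q_score", "depth", "vaf", "not_in_controls",
             "not_in_runmates", "no_read_covariants", "context", "snv_type")
  non_pass <- crits[vapply(crits, function(cn) verdict[[cn]] != "pass",
                           logical(1))]
  expect_equal(got, sort(non_pass))
  expect_equal(got, c("q_score", "vaf"))
})

test_that("the high-confidence set never grows when thresholds tighten", {
  set.seed(55)
  n_var <- 18L
  vars <- list(); stacks <- list()
  for (i in seq_len(n_var)) {
    nr <- 40L
    n_alt <- sample(5:40, 1)
    vars[[i]] <- snv(11, q = runif(1, 5, 80), depth = nr,
                     alt_f = n_alt %/% 2L, alt_r = n_alt - n_alt %/% 2L)
    stacks[[i]] <- clean_stack(clean_window, nr, 11, "A", n_alt)
  }
  for (rep in 1:100) {
    base <- triage_thresholds(min_q = runif(1, 10, 60),
                              min_depth = sample(10:60, 1),
                              min_vaf = runif(1, 0.05, 0.6))
    tight <- triage_thresholds(min_q = base$min_q + runif(1, 0, 20),
                               min_depth = base$min_depth + sample(0:20, 1),
                               min_vaf = min(1, base$min_vaf +
                                               runif(1, 0, 0.3)))
    hc <- function(th) which(vapply(seq_len(n_var), function(i)
      classify_variant(vars[[i]], th, window = clean_window,
                       window_start = 1L,
                       stack = stacks[[i]])$class == "HIGH_CONFIDENCE",
      logical(1)))
    expect_true(all(hc(tight) %in% hc(base)))
  }
})
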