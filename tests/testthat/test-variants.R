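test_that("variant tables validate their invariants", {
  v <- variant_calls("S", "R", "chr1", 10L, "A", "G", quality = 30,
                     depth = 100L, alt_fwd = 25L, alt_rev = 26L)
  expect_equal(v$variant_type, "SNV")
  expect_equal(v$vaf, 51 / 100)  # auto-derived from strand counts
  expect_error(variant_calls("S", "R", "chr1", 10L, "A", "A"), "differ")
  expect_error(variant_calls("S", "R", "chr1", 10L, "A", "G", depth = 10L,
                             alt_fwd = 8L, alt_rev = 8L), "exceed")
  expect_error(variant_calls("S", "R", "chr1", 10L, "", "G"), "non-empty")
  # missing strand counts are tolerated and flagged, not fatal
  v2 <- variant_calls("S", "R", "chr1", 10L, "A", "G", depth = 50L,
                      vaf = 0.4)
  expect_false(v2$strand_known)
})

test_that("variant type classification covers all shapes", {
  expect_equal(classify_variant_type(c("A", "A", "AT", "AT"),
                                     c("G", "AT", "A", "GC")),
               c("SNV", "INS", "DEL", "MNV"))
})

test_that("SNVs pass through normalization unchanged", {
  nv <- normalize_variant(5, "G", "A", "ACGTGCA", 1)
  expect_equal(nv, list(pos = 5L, ref = "G", alt = "A"))
})

test_that("deletion in a short run left-aligns to the anchored leftmost form", {
  # context CAA, deleting one A: every representation of the event reduces
  # to the same anchored key at the run's left edge
  nv <- normalize_variant(3, "A", "", "CAA", 1)
  expect_equal(nv, list(pos = 1L, ref = "CA", alt = "C"))
  nv2 <- normalize_variant(2, "AA", "A", "CAA", 1)
  expect_equal(nv2, nv)
})

test_that("normalization maps whole INDEL equivalence classes to one key and is idempotent", {
  cases <- list(
    list(pos = 3, ref = "A", alt = "", window = "CAA"),
    list(pos = 5, ref = "T", alt = "TT", window = "GTTTT"),
    list(pos = 4, ref = "T", alt = "", window = "GTTTTACG"),
    list(pos = 5, ref = "CACA", alt = "CA", window = "GGCACACACAGT"),
    list(pos = 3, ref = "G", alt = "GATAT", window = "CTGATATATATGC"),
    list(pos = 7, ref = "C", alt = "T", window = "AAGGCTCAGGT")
  )
  for (cs in cases) {
    reps <- enumerate_equivalents(cs$pos, cs$ref, cs$alt, cs$window)
    expect_gt(length(reps), 0)
    keys <- vapply(reps, function(r) {
      nv <- normalize_variant(r$pos, r$ref, r$alt, cs$window, 1)
      paste(nv$pos, nv$ref, nv$alt)
    }, character(1))
    expect_length(unique(keys), 1)
    # canonical form is itself a member of the class
    nv <- normalize_variant(cs$pos, cs$ref, cs$alt, cs$window, 1)
    expect_equal(apply_variant(nv$pos, nv$ref, nv$alt, cs$window),
                 apply_variant(cs$pos, cs$ref, cs$alt, cs$window))
    # idempotent
    nv2 <- normalize_variant(nv$pos, nv$ref, nv$alt, cs$window, 1)
    expect_equal(nv2, nv)
    # left-aligned: no equivalent representation of the same allele shape
    # sits strictly left of the canonical one
    lefter <- Filter(function(r)
      nchar(r$ref) == nchar(nv$ref) && nchar(r$alt) == nchar(nv$alt) &&
        r$pos < nv$pos, reps)
    expect_length(lefter, 0)
  }
})

test_that("normalization rejects a reference mismatch with position context", {
  expect_error(normalize_variant(3, "T", "A", "ACGTT", 1),
               "mismatch at pos 3")
})

test_that("VCF write/read round-trips records, keys and provenance", {
  v <- variant_calls("S1", "R1", "chr1", c(100L, 200L), c("A", "CT"),
                     c("G", "C"), quality = c(50, 40), depth = c(120L, 80L),
                     alt_fwd = c(30L, 20L), alt_rev = c(31L, 22L),
                     predicted_deleterious = c(TRUE, FALSE))
  f <- withr::local_tempfile(fileext = ".vcf")
  write_variants(v, f)
  v2 <- read_variants(f)
  expect_equal(variant_key(v2), variant_key(v))
  expect_equal(v2$sample_id, v$sample_id)
  expect_equal(v2$run_id, v$run_id)
  expect_equal(v2$depth, v$depth)
  expect_equal(v2$alt_fwd, v$alt_fwd)
  expect_equal(v2$predicted_deleterious, v$predicted_deleterious)
  # second round trip is byte-stable on keys
  f2 <- withr::local_tempfile(fileext = ".vcf")
  write_variants(v2, f2)
  expect_equal(variant_key(read_variants(f2)), variant_key(v))
})

test_that("a single biallelic SNV record reads as one SNV call", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2", "##sample_id=S9", "##run_id=RX",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr3\t77\t.\tG\tA\t60\tPASS\tDP=55;AF=0.5;SAF=14;SAR=13;DEL=0"),
             f)
  v <- read_variants(f)
  expect_equal(nrow(v), 1L)
  expect_equal(v$variant_type, "SNV")
  expect_equal(v$sample_id, "S9")
})

test_that("multi-allelic records split into per-allele rows sharing the locus", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr2\t50\t.\tA\tC,G\t99\tPASS\tDP=100;AF=0.2,0.3;SAF=10,15;SAR=10,15;DEL=1,0"),
             f)
  v <- read_variants(f, sample_id = "S", run_id = "R")
  expect_equal(nrow(v), 2L)
  expect_equal(v$chrom, c("chr2", "chr2"))
  expect_equal(v$pos, c(50L, 50L))
  expect_equal(v$alt, c("C", "G"))
  expect_equal(v$vaf, c(0.2, 0.3))
  expect_equal(v$predicted_deleterious, c(TRUE, FALSE))
})

test_that("records without strand tags degrade to strand-unknown, with warning on missing DP", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr2\t50\t.\tA\tC\t99\tPASS\tDP=80;AF=0.5"), f)
  v <- read_variants(f, sample_id = "S", run_id = "R")
  expect_false(v$strand_known)
  expect_equal(v$vaf, 0.5)
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr2\t51\t.\tA\tC\t99\tPASS\tAF=0.5"), f)
  expect_warning(read_variants(f, "S", "R"), "DP")
})
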