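test_that("region statistics follow the strict flag and unreliable rules", {
  s <- region_stats(c(10L, 20L, 30L, 0L), "r1", "G1")
  expect_equal(s$mean_depth, 15)
  expect_equal(s$pct_covered, 75)
  expect_true(s$flagged)
  expect_true(s$unreliable)
  # all-zero profile
  s0 <- region_stats(rep(0L, 10), "r0")
  expect_equal(s0$mean_depth, 0)
  expect_equal(s0$pct_covered, 0)
  expect_true(s0$flagged && s0$unreliable)
  # boundary: mean exactly 20 at full coverage is clean (<20 is strict)
  s20 <- region_stats(rep(20L, 8), "r20")
  expect_false(s20$flagged)
  expect_false(s20$unreliable)
  # mean < 20 but coverage exactly 90%: flagged, not unreliable (<90 strict)
  s90 <- region_stats(c(rep(10L, 9), 0L), "r90")
  expect_equal(s90$pct_covered, 90)
  expect_true(s90$flagged)
  expect_false(s90$unreliable)
  # coverage < 100 alone flags even at deep mean
  sflag <- region_stats(c(rep(500L, 9), 0L), "rf")
  expect_true(sflag$flagged)
  expect_false(sflag$unreliable)
  expect_error(region_stats(integer(0)), "empty")
})

test_that("region statistics agree with a per-base brute-force recount", {
  set.seed(31)
  for (i in 1:300) {
    d <- rpois(sample(5:60, 1), sample(c(0.5, 3, 25, 200), 1))
    md <- sample(1:3, 1)
    s <- region_stats(d, covered_min_depth = md)
    # scalar recount
    tot <- 0; cov <- 0
    for (x in d) { tot <- tot + x; if (x >= md) cov <- cov + 1 }
    expect_equal(s$mean_depth, tot / length(d))
    expect_equal(s$pct_covered, 100 * cov / length(d))
    expect_equal(s$flagged, s$mean_depth < 20 || s$pct_covered < 100)
    expect_equal(s$unreliable, s$mean_depth < 20 && s$pct_covered < 90)
    expect_true(!s$unreliable || s$flagged)   # unreliable implies flagged
  }
})

test_that("panel summary reports the unreliable percentage to one decimal", {
  mk <- function(unrel, n) {
    rbind(
      do.call(rbind, replicate(unrel, region_stats(c(rep(5L, 5), 0L, 0L, 0L, 0L, 0L)),
                               simplify = FALSE)),
      do.call(rbind, replicate(n - unrel, region_stats(rep(300L, 10)),
                               simplify = FALSE)))
  }
  st <- mk(45, 2455)
  ps <- panel_summary(st)
  expect_equal(ps$n_regions, 2455L)
  expect_equal(ps$n_unreliable, 45L)
  expect_equal(ps$pct_unreliable, 1.8)
  # permutation invariance
  ps2 <- panel_summary(st[sample(nrow(st)), ])
  expect_equal(ps2, ps)
  # degenerate panels
  expect_equal(panel_summary(mk(0, 10))$pct_unreliable, 0.0)
  expect_equal(panel_summary(mk(10, 10))$pct_unreliable, 100.0)
})

test_that("gene rollup weights by region length and flags suboptimal genes", {
  regions <- target_regions(c("r1", "r2", "r3", "r4"),
                            c("GENEA", "GENEA", "GENEB", "GENEC"),
                            "chr1", c(0L, 200L, 400L, 600L),
                            c(100L, 300L, 500L, 700L))
  stats <- data.frame(region_id = c("r1", "r2", "r3", "r4"),
                      gene = c("GENEA", "GENEA", "GENEB", "GENEC"),
                      mean_depth = 100, pct_covered = c(100, 80, 89, 82),
                      flagged = FALSE, unreliable = FALSE,
                      stringsAsFactors = FALSE)
  expected <- data.frame(gene = c("GENEA", "GENEB", "GENEC"),
                         expected_pct = c(100, 100, 83))
  g <- gene_rollup(stats, regions, expected)
  # two equal-length regions at 100% and 80% -> 90%
  expect_equal(g$pct_covered[g$gene == "GENEA"], 90)
  # actual 89 vs expected 100: below 90 and gap > 5 -> suboptimal
  expect_true(g$suboptimal[g$gene == "GENEB"])
  # actual 82 vs expected 83: gap <= 5 -> not suboptimal
  expect_false(g$suboptimal[g$gene == "GENEC"])
  # length weighting: make r2 three times longer than r1
  regions2 <- regions
  regions2$end[2] <- 200L + 300L
  g2 <- gene_rollup(stats, regions2, expected)
  expect_equal(g2$pct_covered[g2$gene == "GENEA"],
               (100 * 100 + 80 * 300) / 400)
  # unweighted mode averages regions equally
  g3 <- gene_rollup(stats, regions2, expected, mode = "unweighted")
  expect_equal(g3$pct_covered[g3$gene == "GENEA"], 90)
  # unknown gene collects under the sentinel
  regions$gene[4] <- NA
  stats$gene[4] <- NA
  g4 <- gene_rollup(stats, regions)
  expect_true("<unassigned>" %in% g4$gene)
})

test_that("coverage report lists flagged regions, warns on hotspots, sorts stably", {
  regions <- target_regions(c("rA", "rB", "rC"), c("G2", "G1", "G1"),
                            "chr1", c(0L, 100L, 200L), c(50L, 150L, 250L))
  profiles <- list(rA = rep(300L, 50),
                   rB = c(rep(3L, 30), rep(0L, 20)),
                   rC = c(rep(500L, 49), 0L))
  stats <- panel_region_stats(profiles, regions)
  hot <- data.frame(chrom = "chr1", pos = 120L, name = "HOTSPOT_E525K",
                    stringsAsFactors = FALSE)
  rep1 <- coverage_report(stats, regions, hot)
  expect_equal(rep1$flagged_regions$region_id, c("rB", "rC"))  # by gene,pos
  expect_equal(nrow(rep1$hotspot_warnings), 1L)
  expect_equal(rep1$hotspot_warnings$hotspot, "HOTSPOT_E525K")
  expect_true(rep1$hotspot_warnings$unreliable)
  # deterministic under input permutation
  rep2 <- coverage_report(stats[c(3, 1, 2), ], regions, hot)
  expect_equal(rep2$flagged_regions, rep1$flagged_regions)
  # no flagged regions
  rep0 <- coverage_report(panel_region_stats(list(rA = rep(300L, 50)),
                                             regions), regions)
  expect_equal(nrow(rep0$flagged_regions), 0L)
  expect_output(print(rep0), "No flagged regions")
})
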