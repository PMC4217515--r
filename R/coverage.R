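#' Coverage statistics for one region
#'
#' `mean_depth` is the arithmetic mean of per-base depths; `pct_covered`
#' the percent of bases with depth at least `covered_min_depth` (default 1;
#' the per-base cutoff defining "covered" is a reporting convention and is
#' exposed). Two distinct reporting rules coexist and are never conflated:
#' a region is **flagged** when mean depth < 20 or it is < 100% covered
#' (the clinical-report criterion), and **unreliable** when mean depth < 20
#' and it is < 90% covered (systematic failure). All inequalities strict,
#' as stated; `unreliable` implies `flagged`.
#'
#' @param depths non-negative integer vector of per-base depths (nonempty).
#' @param region_id,gene identifiers carried into the result.
#' @param covered_min_depth per-base depth defining a covered base.
#' @return one-row `data.frame`: `region_id`, `gene`, `mean_depth`,
#'   `pct_covered`, `flagged`, `unreliable`.
#' @export
region_stats <- function(depths, region_id = NA_character_,
                         gene = NA_character_, covered_min_depth = 1L) {
  if (length(depths) == 0L) stop("empty depth profile for region ", region_id)
  if (any(depths < 0)) stop("negative depths in region ", region_id)
  mean_depth <- mean(depths)
  pct_covered <- 100 * sum(depths >= covered_min_depth) / length(depths)
  data.frame(region_id = region_id, gene = gene,
             mean_depth = mean_depth, pct_covered = pct_covered,
             flagged = mean_depth < 20 || pct_covered < 100,
             unreliable = mean_depth < 20 && pct_covered < 90,
             stringsAsFactors = FALSE)
}

#' Coverage statistics for a whole panel
#'
#' @param profiles named list of depth vectors (see [depth_profiles()]).
#' @param regions region `data.frame` supplying the `gene` of each region
#'   (optional).
#' @param covered_min_depth per-base depth defining a covered base.
#' @return `data.frame`, one row per region (see [region_stats()]).
#' @export
panel_region_stats <- function(profiles, regions = NULL,
                               covered_min_depth = 1L) {
  out <- lapply(names(profiles), function(id) {
    gene <- NA_character_
    if (!is.null(regions)) {
      hit <- match(id, regions$region_id)
      if (!is.na(hit)) gene <- regions$gene[hit]
    }
    region_stats(profiles[[id]], id, gene, covered_min_depth)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Panel-level summary of region coverage
#'
#' @param stats region stats `data.frame` (nonempty).
#' @return list: `n_regions`, `n_flagged`, `n_unreliable`, `pct_unreliable`
#'   (percent, reported to 1 decimal).
#' @export
panel_summary <- function(stats) {
  if (nrow(stats) == 0L) stop("no region statistics supplied")
  n <- nrow(stats)
  nf <- sum(stats$flagged)
  nu <- sum(stats$unreliable)
  list(n_regions = n, n_flagged = nf, n_unreliable = nu,
       pct_unreliable = round(100 * nu / n, 1))
}

#' Gene-level coverage rollup
#'
#' Aggregates region percent coverage per gene. The default mode weights
#' each region by its length in bases; `mode = "unweighted"` averages
#' regions equally (matching reports that average per-region figures).
#' When expected per-gene coverage is supplied, genes are flagged
#' `suboptimal` when actual coverage is below 90% **and** more than 5
#' points below expectation.
#'
#' @param stats region stats `data.frame`.
#' @param regions region `data.frame` (supplies lengths and genes).
#' @param expected optional `data.frame` with columns `gene`,
#'   `expected_pct`.
#' @param mode `"length_weighted"` (default) or `"unweighted"`.
#' @param suboptimal_gap points below expectation beyond which a
#'   below-90% gene is suboptimal.
#' @return `data.frame`: `gene`, `pct_covered`, `n_regions`,
#'   `expected_pct`, `suboptimal`. Regions with unknown gene are collected
#'   under the sentinel gene `"<unassigned>"`.
#' @export
gene_rollup <- function(stats, regions, expected = NULL,
                        mode = c("length_weighted", "unweighted"),
                        suboptimal_gap = 5) {
  mode <- match.arg(mode)
  idx <- match(stats$region_id, regions$region_id)
  len <- regions$end[idx] - regions$start[idx]
  gene <- regions$gene[idx]
  gene[is.na(gene)] <- "<unassigned>"
  wt <- if (mode == "length_weighted") len else rep(1, nrow(stats))
  agg <- vapply(split(seq_len(nrow(stats)), gene), function(ii)
    stats::weighted.mean(stats$pct_covered[ii], wt[ii]), numeric(1))
  res <- data.frame(gene = names(agg), pct_covered = unname(agg),
                    n_regions = as.integer(table(gene)[names(agg)]),
                    stringsAsFactors = FALSE)
  if (!is.null(expected)) {
    res$expected_pct <- expected$expected_pct[match(res$gene, expected$gene)]
    res$suboptimal <- !is.na(res$expected_pct) & res$pct_covered < 90 &
      (res$expected_pct - res$pct_covered) > suboptimal_gap
  } else {
    res$expected_pct <- NA_real_
    res$suboptimal <- NA
  }
  res[order(res$gene), , drop = FALSE]
}

#' Clinical coverage report
#'
#' Every flagged and unreliable region must be visible to the reporting
#' clinician: the report lists them with gene, interval, mean depth and
#' percent covered, stable-sorted by `(gene, chrom, start)` for
#' diffability, and prominently warns when a user-supplied hotspot
#' (known mutation site) falls inside a flagged region — a panel cannot
#' exclude a mutation it cannot see.
#'
#' @param stats region stats `data.frame`.
#' @param regions region `data.frame`.
#' @param hotspots optional `data.frame` with columns `chrom`, `pos`
#'   (1-based) and `name`.
#' @return list of class `coverage_report`: `flagged_regions` (data.frame),
#'   `hotspot_warnings` (data.frame), `summary` (see [panel_summary()]).
#' @export
coverage_report <- function(stats, regions, hotspots = NULL) {
  idx <- match(stats$region_id, regions$region_id)
  tab <- data.frame(region_id = stats$region_id,
                    gene = regions$gene[idx],
                    chrom = regions$chrom[idx],
                    start = regions$start[idx],
                    end = regions$end[idx],
                    mean_depth = stats$mean_depth,
                    pct_covered = stats$pct_covered,
                    flagged = stats$flagged,
                    unreliable = stats$unreliable,
                    stringsAsFactors = FALSE)
  flagged <- tab[tab$flagged, , drop = FALSE]
  flagged <- flagged[order(flagged$gene, flagged$chrom, flagged$start), ,
                     drop = FALSE]
  rownames(flagged) <- NULL
  warn <- data.frame(hotspot = character(), region_id = character(),
                     gene = character(), mean_depth = numeric(),
                     pct_covered = numeric(), unreliable = logical(),
                     stringsAsFactors = FALSE)
  if (!is.null(hotspots) && nrow(flagged)) {
    for (i in seq_len(nrow(hotspots))) {
      hit <- which(flagged$chrom == hotspots$chrom[i] &
                   flagged$start < hotspots$pos[i] &
                   flagged$end >= hotspots$pos[i])
      for (j in hit) {
        warn <- rbind(warn, data.frame(
          hotspot = hotspots$name[i], region_id = flagged$region_id[j],
          gene = flagged$gene[j], mean_depth = flagged$mean_depth[j],
          pct_covered = flagged$pct_covered[j],
          unreliable = flagged$unreliable[j], stringsAsFactors = FALSE))
      }
    }
  }
  structure(list(flagged_regions = flagged, hotspot_warnings = warn,
                 summary = panel_summary(stats)),
            class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  s <- x$summary
  cat("Coverage report: ", s$n_regions, " regions, ", s$n_flagged,
      " flagged, ", s$n_unreliable, " unreliable (",
      formatC(s$pct_unreliable, format = "f", digits = 1), "%)\n", sep = "")
  if (nrow(x$hotspot_warnings)) {
    cat("WARNING - known hotspot(s) in poorly covered regions:\n")
    for (i in seq_len(nrow(x$hotspot_warnings)))
      cat("  ", x$hotspot_warnings$hotspot[i], " in ",
          x$hotspot_warnings$region_id[i], " (",
          x$hotspot_warnings$gene[i], "): mean depth ",
          round(x$hotspot_warnings$mean_depth[i], 1), ", ",
          round(x$hotspot_warnings$pct_covered[i], 1), "% covered\n",
          sep = "")
  }
  if (nrow(x$flagged_regions) == 0L) {
    cat("No flagged regions.\n")
  } else {
    cat("Flagged regions:\n")
    print(utils::head(x$flagged_regions, 20))
    if (nrow(x$flagged_regions) > 20) cat("  ...\n")
  }
  invisible(x)
}

#' Write a coverage report as TSV (+ JSON summary)
#'
#' @param report a [coverage_report()].
#' @param path TSV path for the flagged-region table; a `.json` sibling
#'   receives the summary.
#' @return `path`, invisibly.
#' @export
write_coverage_report <- function(report, path) {
  utils::write.table(report$flagged_regions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(report$summary,
                       sub("\\.tsv$", ".json", paste0(path)),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
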