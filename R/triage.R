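#' Thresholds for high-confidence SNV triage
#'
#' Criteria separating calls that are highly likely true positives (no
#' orthogonal Sanger confirmation warranted) from calls requiring
#' confirmation: base-caller Phred q score >= 30, total read depth >= 20,
#' VAF >= 25%, absence from wild-type controls and from other samples in
#' the same run, no co-occurring variants on the alt-carrying reads, no
#' homopolymer/repeat context, and SNV type (all INDELs require
#' confirmation). Thresholds are inclusive at the boundary.
#'
#' The sequence-context and co-variant parameters quantify rules that are
#' qualitative in clinical practice and are therefore exposed:
#' `homopolymer_min_run` (identical bases constituting a run, default 4 —
#' tuned to the semiconductor-sequencing failure mode), `repeat_max_unit` /
#' `repeat_min_span` (tandem repeats of unit <= 3 bp spanning >= 8 bp),
#' `adjacency` ("immediately adjacent" = within 1 base of the variant
#' footprint), and `covariant_min_frac` (a second non-reference allele on
#' the alt reads counts as a co-variant only when carried by at least this
#' fraction of them — random sequencing errors touch ~1% of reads per
#' position, true cis co-variants essentially all of them).
#'
#' @param min_q minimum Phred q score.
#' @param min_depth minimum total read depth.
#' @param min_vaf minimum variant allele frequency (fraction).
#' @param homopolymer_min_run minimum identical-base run length.
#' @param repeat_max_unit maximum tandem-repeat unit size (bases).
#' @param repeat_min_span minimum tandem-repeat span (bases).
#' @param adjacency maximum distance (bases) between a run/repeat and the
#'   variant footprint for "immediately adjacent".
#' @param covariant_min_frac minimum fraction of alt reads sharing a second
#'   allele for the co-variant check to fail (always requires >= 2 reads).
#' @param somatic_alt_min minimum alt reads for the somatic-suspect
#'   annotation on sub-threshold-VAF calls.
#' @return validated list of class `triage_thresholds`.
#' @export
triage_thresholds <- function(min_q = 30, min_depth = 20L, min_vaf = 0.25,
                              homopolymer_min_run = 4L, repeat_max_unit = 3L,
                              repeat_min_span = 8L, adjacency = 1L,
                              covariant_min_frac = 0.3,
                              somatic_alt_min = 3L) {
  t <- list(min_q = as.numeric(min_q), min_depth = as.integer(min_depth),
            min_vaf = as.numeric(min_vaf),
            homopolymer_min_run = as.integer(homopolymer_min_run),
            repeat_max_unit = as.integer(repeat_max_unit),
            repeat_min_span = as.integer(repeat_min_span),
            adjacency = as.integer(adjacency),
            covariant_min_frac = as.numeric(covariant_min_frac),
            somatic_alt_min = as.integer(somatic_alt_min))
  if (t$min_q <= 0 || t$min_depth <= 0 || t$homopolymer_min_run <= 0 ||
      t$repeat_min_span <= 0)
    stop("triage thresholds must be positive")
  if (t$min_vaf <= 0 || t$min_vaf > 1) stop("min_vaf must lie in (0, 1]")
  class(t) <- "triage_thresholds"
  t
}

# Intervals (1-based, within seq) of homopolymer runs >= min_run and of
# perfect tandem repeats with unit <= max_unit spanning >= min_span.
context_intervals <- function(seq, min_run, max_unit, min_span) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  iv <- list()
  rl <- rle(ch)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  for (k in which(rl$lengths >= min_run))
    iv[[length(iv) + 1L]] <- c(starts[k], ends[k])
  for (u in seq_len(max_unit)) {
    if (n <= u) next
    match_next <- ch[seq_len(n - u)] == ch[seq_len(n - u) + u]
    rl2 <- rle(match_next)
    e2 <- cumsum(rl2$lengths)
    s2 <- e2 - rl2$lengths + 1L
    for (k in which(rl2$values)) {
      span <- rl2$lengths[k] + u  # matched stretch plus one unit
      if (span >= min_span)
        iv[[length(iv) + 1L]] <- c(s2[k], e2[k] + u)
    }
  }
  iv
}

#' Sequence-context check: homopolymer runs and repeat regions
#'
#' Fails when a homopolymer run (>= `homopolymer_min_run` identical bases)
#' or a short tandem repeat (unit <= `repeat_max_unit` bases, span >=
#' `repeat_min_span`) overlaps or lies within `adjacency` bases of the
#' variant footprint — variants in or immediately adjacent to such context
#' are the dominant artifact mode of semiconductor sequencing. Returns
#' `"not_evaluable"` when the window does not extend far enough on both
#' sides of the footprint to scan.
#'
#' @param pos 1-based variant position; `ref_len` its reference footprint
#'   length.
#' @param window reference base string; `window_start` its 1-based genomic
#'   start.
#' @param thresholds a [triage_thresholds()].
#' @return `"pass"`, `"fail"` or `"not_evaluable"`.
#' @export
check_context <- function(pos, ref_len, window, window_start,
                          thresholds = triage_thresholds()) {
  radius <- max(thresholds$homopolymer_min_run, thresholds$repeat_min_span) +
    thresholds$adjacency
  off1 <- pos - window_start + 1L
  off2 <- off1 + ref_len - 1L
  n <- nchar(window)
  if (off1 - radius < 1L || off2 + radius > n) return("not_evaluable")
  lo <- off1 - radius
  hi <- off2 + radius
  iv <- context_intervals(substr(window, lo, hi),
                          thresholds$homopolymer_min_run,
                          thresholds$repeat_max_unit,
                          thresholds$repeat_min_span)
  foot <- c(off1 - lo + 1L, off2 - lo + 1L)
  for (v in iv) {
    if (v[1L] <= foot[2L] + thresholds$adjacency &&
        v[2L] >= foot[1L] - thresholds$adjacency)
      return("fail")
  }
  "pass"
}

#' Same-read co-variant check
#'
#' Among the reads observing the alt allele, looks for a second
#' non-reference allele shared by at least `covariant_min_frac` of them (and
#' by >= 2 reads): a variant whose supporting reads systematically carry
#' another mismatch or INDEL is suspect (misalignment, chimeric capture).
#' Isolated mismatches on single reads are ordinary sequencing error and
#' are ignored.
#'
#' @param v one-row variant `data.frame`.
#' @param stack the [read_stack()] covering the variant, or `NULL`.
#' @param thresholds a [triage_thresholds()].
#' @return `"pass"`, `"fail"` or `"not_evaluable"` (no stack, position not
#'   covered, or no alt-read observations).
#' @export
check_read_covariants <- function(v, stack,
                                  thresholds = triage_thresholds()) {
  if (is.null(stack)) return("not_evaluable")
  w <- ncol(stack$obs)
  col1 <- v$pos - stack$start
  if (col1 < 1L || col1 > w) return("not_evaluable")
  refv <- strsplit(stack$ref, "", fixed = TRUE)[[1]]
  bp <- obs_base(stack$obs)
  type <- classify_variant_type(v$ref, v$alt)
  foot_cols <- col1:min(w, col1 + nchar(v$ref) - 1L)
  alt_rows <- switch(
    type,
    SNV = which(!is.na(bp[, col1]) & bp[, col1] == v$alt),
    INS = {
      ins <- obs_ins(stack$obs[, col1])
      which(!is.na(stack$obs[, col1]) & ins == substring(v$alt, 2L))
    },
    DEL = {
      jd <- col1 + 1L
      if (jd > w) integer(0) else
        which(!is.na(bp[, jd]) & bp[, jd] == "-")
    },
    integer(0))
  if (length(alt_rows) == 0L) return("not_evaluable")
  need <- max(2L, ceiling(thresholds$covariant_min_frac * length(alt_rows)))
  for (j in setdiff(seq_len(w), foot_cols)) {
    colb <- bp[alt_rows, j]
    ins <- obs_ins(stack$obs[alt_rows, j])
    ins[is.na(stack$obs[alt_rows, j])] <- ""
    nonref <- colb[!is.na(colb) & colb != refv[j]]
    if (length(nonref)) {
      tab <- table(nonref)
      if (any(tab >= need)) return("fail")
    }
    if (any(ins != "")) {
      tab <- table(ins[ins != ""])
      if (any(tab >= need)) return("fail")
    }
  }
  "pass"
}

#' Cohort check: wild-type controls and same-run samples
#'
#' A variant present in any wild-type control, or recurring in other
#' samples of the same sequencing run (patients with different phenotypes),
#' is likely a platform or run artifact.
#'
#' @param v one-row variant `data.frame` (normalized).
#' @param controls,runmates lists of normalized variant `data.frame`s.
#' @return list with `controls` and `runmates` entries, each `"pass"` or
#'   `"fail"`.
#' @export
check_cohort <- function(v, controls = list(), runmates = list()) {
  key <- variant_key(v)
  in_any <- function(sets) {
    for (s in sets) {
      if (is.null(s) || nrow(s) == 0L) next
      if (key %in% variant_key(s)) return(TRUE)
    }
    FALSE
  }
  list(controls = if (in_any(controls)) "fail" else "pass",
       runmates = if (in_any(runmates)) "fail" else "pass")
}

.triage_criteria <- c("q_score", "depth", "vaf", "not_in_controls",
                      "not_in_runmates", "no_read_covariants", "context",
                      "snv_type")

#' Triage one variant call
#'
#' Evaluates the eight high-confidence criteria (q score, depth, VAF,
#' absence from controls, absence from run-mates, no same-read co-variants,
#' clean sequence context, SNV type). The final class is `HIGH_CONFIDENCE`
#' iff every criterion passes; any failing or not-evaluable criterion gives
#' `NEEDS_CONFIRMATION` with the criterion names as reasons — missing data
#' degrades conservatively, never silently passes. Calls with VAF below the
#' threshold but at least `somatic_alt_min` alt reads additionally carry a
#' `somatic_suspect` annotation (coverage-dependent somatic detection; the
#' alignment should be inspected manually).
#'
#' @param v one-row variant `data.frame` (normalized).
#' @param thresholds a [triage_thresholds()].
#' @param window,window_start reference context for [check_context()]
#'   (`NULL` window gives a not-evaluable context criterion).
#' @param stack [read_stack()] for [check_read_covariants()], or `NULL`.
#' @param controls,runmates call-set lists for [check_cohort()].
#' @return one-row `data.frame`: `key`, the eight criterion outcomes, `class`
#'   (`HIGH_CONFIDENCE`/`NEEDS_CONFIRMATION`), `reasons` (comma-separated
#'   failed or not-evaluable criteria), `somatic_suspect`.
#' @export
classify_variant <- function(v, thresholds = triage_thresholds(),
                             window = NULL, window_start = NULL,
                             stack = NULL, controls = list(),
                             runmates = list()) {
  stopifnot(nrow(v) == 1L)
  num_crit <- function(x, cut) {
    if (is.na(x)) "not_evaluable" else if (x >= cut) "pass" else "fail"
  }
  out <- list(
    q_score = num_crit(v$quality, thresholds$min_q),
    depth = num_crit(v$depth, thresholds$min_depth),
    vaf = num_crit(v$vaf, thresholds$min_vaf)
  )
  co <- check_cohort(v, controls, runmates)
  out$not_in_controls <- co$controls
  out$not_in_runmates <- co$runmates
  out$no_read_covariants <- check_read_covariants(v, stack, thresholds)
  out$context <- if (is.null(window)) "not_evaluable" else
    check_context(v$pos, nchar(v$ref), window, window_start, thresholds)
  out$snv_type <- if (v$variant_type == "SNV") "pass" else "fail"
  bad <- names(out)[unlist(out) != "pass"]
  cls <- if (length(bad) == 0L) "HIGH_CONFIDENCE" else "NEEDS_CONFIRMATION"
  ac <- if (v$strand_known) v$alt_fwd + v$alt_rev else
    if (!is.na(v$vaf)) round(v$vaf * v$depth) else NA_integer_
  somatic <- !is.na(v$vaf) && v$vaf < thresholds$min_vaf &&
    !is.na(ac) && ac >= thresholds$somatic_alt_min
  cbind(data.frame(key = variant_key(v), stringsAsFactors = FALSE),
        as.data.frame(out, stringsAsFactors = FALSE),
        data.frame(class = cls,
                   reasons = paste(bad, collapse = ","),
                   somatic_suspect = somatic, stringsAsFactors = FALSE))
}

#' Triage every call in a set
#'
#' Convenience loop over [classify_variant()], resolving per-variant
#' reference windows and read stacks from a panel bundle.
#'
#' @param calls variant `data.frame` (normalized).
#' @param thresholds a [triage_thresholds()].
#' @param panel panel list (`regions` + `reference`), or `NULL`.
#' @param stacks named list of [read_stack()]s keyed by `region_id`, or
#'   `NULL`.
#' @param controls,runmates call-set lists.
#' @return verdict `data.frame`, one row per call.
#' @export
triage_variants <- function(calls, thresholds = triage_thresholds(),
                            panel = NULL, stacks = NULL,
                            controls = list(), runmates = list()) {
  if (nrow(calls) == 0L)
    return(classify_variant(
      variant_calls("s", "r", "chr1", 1L, "A", "C"), thresholds)[0, ])
  out <- vector("list", nrow(calls))
  for (i in seq_len(nrow(calls))) {
    v <- calls[i, , drop = FALSE]
    window <- NULL; window_start <- NULL; stack <- NULL
    if (!is.null(panel)) {
      hit <- which(panel$regions$chrom == v$chrom &
                   panel$regions$start < v$pos & panel$regions$end >= v$pos)
      if (length(hit)) {
        rid <- panel$regions$region_id[hit[1L]]
        window <- panel$reference[[rid]]
        window_start <- panel$regions$start[hit[1L]] + 1L
        if (!is.null(stacks) && rid %in% names(stacks))
          stack <- stacks[[rid]]
      }
    }
    out[[i]] <- classify_variant(v, thresholds, window, window_start, stack,
                                 controls, runmates)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write triage verdicts as TSV
#'
#' @param verdicts verdict `data.frame` from [triage_variants()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_triage <- function(verdicts, path) {
  utils::write.table(verdicts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
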