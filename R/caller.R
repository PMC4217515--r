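#' Pileup caller stringency settings
#'
#' The low-stringency germline settings used by the diagnostic pipeline:
#' minimum coverage 6 (SNP) / 15 (INDEL), minimum alt coverage on each
#' strand 0 (SNP) / 5 (INDEL), minimum variant score 10 (Phred), minimum
#' allele frequency 0.1 (set `min_allele_freq = NA` to disable, as done when
#' re-analysing for low-fraction somatic alleles), and maximum strand bias
#' 0.95 (SNP) / 0.85 (INDEL). All thresholds are inclusive: `>=` passes,
#' and bias `<=` the maximum passes.
#'
#' `per_base_error_rate` parameterizes the variant score's binomial
#' sequencing-error null model (see [variant_score()]); it is a property of
#' the caller's error model, not of the data.
#'
#' @param min_cov_snp,min_cov_indel minimum total depth at the site.
#' @param min_cov_each_strand_snp,min_cov_each_strand_indel minimum
#'   alt-supporting reads required on each strand.
#' @param min_variant_score minimum Phred-scaled variant score.
#' @param min_allele_freq minimum VAF, or `NA` to disable the cutoff.
#' @param strand_bias_max_snp,strand_bias_max_indel maximum
#'   majority-strand fraction of alt reads (see [strand_bias()]).
#' @param per_base_error_rate assumed per-base sequencing error rate.
#' @param score_cap maximum reportable Phred score (caps the
#'   `-10*log10` transform when the tail probability underflows).
#' @return a validated list of class `caller_settings`.
#' @export
caller_settings <- function(min_cov_snp = 6L, min_cov_indel = 15L,
                            min_cov_each_strand_snp = 0L,
                            min_cov_each_strand_indel = 5L,
                            min_variant_score = 10,
                            min_allele_freq = 0.1,
                            strand_bias_max_snp = 0.95,
                            strand_bias_max_indel = 0.85,
                            per_base_error_rate = 0.01,
                            score_cap = 1000) {
  s <- list(min_cov_snp = as.integer(min_cov_snp),
            min_cov_indel = as.integer(min_cov_indel),
            min_cov_each_strand_snp = as.integer(min_cov_each_strand_snp),
            min_cov_each_strand_indel = as.integer(min_cov_each_strand_indel),
            min_variant_score = as.numeric(min_variant_score),
            min_allele_freq = as.numeric(min_allele_freq),
            strand_bias_max_snp = as.numeric(strand_bias_max_snp),
            strand_bias_max_indel = as.numeric(strand_bias_max_indel),
            per_base_error_rate = as.numeric(per_base_error_rate),
            score_cap = as.numeric(score_cap))
  num <- unlist(s[setdiff(names(s), "min_allele_freq")])
  if (any(num < 0)) stop("all caller thresholds must be >= 0")
  fr <- c(s$min_allele_freq, s$strand_bias_max_snp, s$strand_bias_max_indel,
          s$per_base_error_rate)
  if (any(fr < 0 | fr > 1, na.rm = TRUE))
    stop("frequencies must lie in [0, 1]")
  class(s) <- "caller_settings"
  s
}

#' Phred-scaled variant score under a binomial error null
#'
#' `score = -10 * log10( P[ Binomial(depth, error_rate) >= alt_count ] )`:
#' the Phred-scaled probability that random sequencing error alone produces
#' at least the observed number of alt-supporting reads. Zero alt reads give
#' score 0 (the tail probability is 1); the score is monotone non-decreasing
#' in `alt_count` at fixed depth and capped at `cap` when the tail
#' probability underflows.
#'
#' @param alt_count alt-supporting reads, `0 <= alt_count <= depth`.
#' @param depth total reads, `> 0`.
#' @param error_rate assumed per-base error rate, in `(0, 1)`.
#' @param cap maximum score.
#' @return numeric Phred score (vectorized).
#' @export
variant_score <- function(alt_count, depth, error_rate = 0.01, cap = 1000) {
  if (any(depth == 0)) stop("variant score is undefined at depth 0")
  if (any(alt_count < 0) || any(alt_count > depth))
    stop("alt_count must lie in [0, depth]")
  if (error_rate <= 0 || error_rate >= 1)
    stop("error_rate must lie strictly in (0, 1)")
  tail_p <- stats::pbinom(alt_count - 1, depth, error_rate,
                          lower.tail = FALSE)
  pmin(ifelse(tail_p <= 0, Inf, -10 * log10(tail_p)), cap)
}

#' Majority-strand fraction of alt-supporting reads
#'
#' `max(alt_fwd, alt_rev) / (alt_fwd + alt_rev)`: 0.5 for perfect balance,
#' 1 when all alt reads lie on one strand. Returns `NA` (not evaluable)
#' when there are no alt reads.
#'
#' @param alt_fwd,alt_rev non-negative read counts.
#' @return fraction in `[0.5, 1]`, or `NA`.
#' @export
strand_bias <- function(alt_fwd, alt_rev) {
  if (any(alt_fwd < 0, na.rm = TRUE) || any(alt_rev < 0, na.rm = TRUE))
    stop("strand counts must be >= 0")
  tot <- alt_fwd + alt_rev
  ifelse(is.na(tot) | tot == 0, NA_real_, pmax(alt_fwd, alt_rev) / tot)
}

# Enumerate candidate events in a stack: SNVs per column per alt base,
# deletions per maximal gap run, insertions per (column, sequence).
# Deletions touching the window's first column cannot be left-anchored and
# are skipped (documented edge behaviour; generated windows carry margin).
stack_candidates <- function(stack) {
  obs <- stack$obs
  w <- ncol(obs)
  refv <- strsplit(stack$ref, "", fixed = TRUE)[[1]]
  cand <- list()
  base_part <- obs_base(obs)
  for (j in seq_len(w)) {
    col <- base_part[, j]
    cov <- !is.na(col)
    if (!any(cov)) next
    for (b in setdiff(unique(col[cov]), c(refv[j], "-"))) {
      rows <- which(cov & col == b)
      cand[[length(cand) + 1L]] <- list(
        type = "SNV", pos = stack$start + j, ref = refv[j], alt = b,
        col = j, rows = rows)
    }
    ins <- obs_ins(obs[, j])
    ins[is.na(obs[, j])] <- ""
    for (s in setdiff(unique(ins), "")) {
      rows <- which(ins == s)
      cand[[length(cand) + 1L]] <- list(
        type = "INS", pos = stack$start + j, ref = refv[j],
        alt = paste0(refv[j], s), col = j, rows = rows)
    }
  }
  # deletion events: maximal runs of "-" per read, grouped by (start, length)
  del_keys <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(obs))) {
    isgap <- !is.na(base_part[r, ]) & base_part[r, ] == "-"
    if (!any(isgap)) next
    rl <- rle(isgap)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    for (k in which(rl$values)) {
      key <- paste(starts[k], rl$lengths[k], sep = "_")
      del_keys[[key]] <- c(del_keys[[key]], r)
    }
  }
  for (key in ls(del_keys)) {
    parts <- as.integer(strsplit(key, "_", fixed = TRUE)[[1]])
    j0 <- parts[1L]; len <- parts[2L]
    if (j0 <= 1L) next  # cannot anchor on the preceding base
    cand[[length(cand) + 1L]] <- list(
      type = "DEL", pos = stack$start + j0 - 1L,
      ref = paste(refv[(j0 - 1L):(j0 + len - 1L)], collapse = ""),
      alt = refv[j0 - 1L], col = j0, rows = del_keys[[key]])
  }
  cand
}

#' Call variants from a read stack
#'
#' Threshold-based pileup calling: a candidate event (SNV per column per alt
#' base; deletions from maximal gap runs; insertions from insertion
#' observations) is emitted iff all of the following hold at the inclusive
#' boundaries defined by `settings`:
#' total depth `>=` the per-type minimum coverage; alt-supporting reads on
#' each strand `>=` the per-type minimum; [variant_score()] `>=` the minimum
#' score; VAF `>=` the minimum allele frequency (skipped when the cutoff is
#' disabled); and [strand_bias()] `<=` the per-type maximum. Emitted calls
#' are left-aligned and trimmed via [normalize_variant()].
#'
#' @param stack a [read_stack()].
#' @param settings a [caller_settings()].
#' @return variant `data.frame` (possibly empty), one row per call.
#' @export
call_variants <- function(stack, settings = caller_settings()) {
  stopifnot(inherits(stack, "read_stack"))
  empty <- variant_calls(stack$sample_id, stack$run_id, character(),
                         integer(), character(), character())
  if (nrow(stack$obs) == 0L) return(empty)
  depth_by_col <- stack_depth(stack)
  out <- list()
  for (cd in stack_candidates(stack)) {
    is_snv <- cd$type == "SNV"
    dp <- depth_by_col[cd$col]
    alt_fwd <- sum(stack$strand[cd$rows] == "+")
    alt_rev <- sum(stack$strand[cd$rows] == "-")
    ac <- alt_fwd + alt_rev
    min_cov <- if (is_snv) settings$min_cov_snp else settings$min_cov_indel
    min_each <- if (is_snv) settings$min_cov_each_strand_snp else
      settings$min_cov_each_strand_indel
    bias_max <- if (is_snv) settings$strand_bias_max_snp else
      settings$strand_bias_max_indel
    if (dp < min_cov) next
    if (alt_fwd < min_each || alt_rev < min_each) next
    score <- variant_score(ac, dp, settings$per_base_error_rate,
                           settings$score_cap)
    if (score < settings$min_variant_score) next
    vaf <- ac / dp
    if (!is.na(settings$min_allele_freq) && vaf < settings$min_allele_freq)
      next
    sb <- strand_bias(alt_fwd, alt_rev)
    if (!is.na(sb) && sb > bias_max) next
    nv <- normalize_variant(cd$pos, cd$ref, cd$alt, stack$ref,
                            stack$start + 1L)
    out[[length(out) + 1L]] <- variant_calls(
      sample_id = stack$sample_id, run_id = stack$run_id,
      chrom = stack$chrom, pos = nv$pos, ref = nv$ref, alt = nv$alt,
      quality = score, depth = dp, alt_fwd = alt_fwd, alt_rev = alt_rev,
      vaf = vaf)
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  res[order(res$chrom, res$pos, res$ref, res$alt), , drop = FALSE]
}
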