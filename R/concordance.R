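#' Concordance evaluation settings
#'
#' Intronic positions more than a few bases from the splice sites are not
#' reliably captured by exon-flank designs; concordance is therefore
#' evaluated only within the exons padded by `exon_flank_keep` bases
#' (default 5, i.e. the +5/-5 positions are kept, deeper intronic bases are
#' excluded from the evaluation domain).
#'
#' @param exon_flank_keep flanking bases retained around each exon.
#' @return validated list of class `concordance_settings`.
#' @export
concordance_settings <- function(exon_flank_keep = 5L) {
  if (exon_flank_keep < 0L) stop("exon_flank_keep must be >= 0")
  structure(list(exon_flank_keep = as.integer(exon_flank_keep)),
            class = "concordance_settings")
}

#' Base-resolution concordance tally
#'
#' @param tp,fn,tn,fp non-negative counts. `scope` (total evaluated bases)
#'   is their sum.
#' @return list of class `concordance_tally`.
#' @export
concordance_tally <- function(tp, fn, tn, fp) {
  v <- c(tp = tp, fn = fn, tn = tn, fp = fp)
  if (any(v < 0)) stop("tally counts must be >= 0")
  structure(list(tp = as.numeric(tp), fn = as.numeric(fn),
                 tn = as.numeric(tn), fp = as.numeric(fp),
                 scope = as.numeric(tp + fn + tn + fp)),
            class = "concordance_tally")
}

#' @export
print.concordance_tally <- function(x, ...) {
  cat("Concordance tally over", format(x$scope, big.mark = ","),
      "evaluated bases:\n")
  cat("  TP", x$tp, " FN", x$fn, " TN", x$tn, " FP", x$fp, "\n")
  invisible(x)
}

# Intersect truth intervals with flank-padded exons, per chromosome.
# Intervals are 0-based half-open data.frames (chrom, start, end).
evaluation_domain <- function(truth_intervals, exons, keep) {
  out <- list()
  for (ch in unique(truth_intervals$chrom)) {
    ti <- truth_intervals[truth_intervals$chrom == ch, , drop = FALSE]
    ex <- exons[exons$chrom == ch, , drop = FALSE]
    if (nrow(ex) == 0L) next
    ir1 <- IRanges::IRanges(start = ti$start + 1L, end = ti$end)
    ir2 <- IRanges::reduce(IRanges::IRanges(start = ex$start + 1L - keep,
                                            end = ex$end + keep))
    ov <- IRanges::intersect(IRanges::reduce(ir1), ir2)
    if (length(ov) == 0L) next
    out[[ch]] <- data.frame(chrom = ch,
                            start = IRanges::start(ov) - 1L,
                            end = IRanges::end(ov),
                            stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

in_domain <- function(chrom, pos, domain) {
  hit <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(domain))) {
    hit <- hit | (chrom == domain$chrom[i] & pos > domain$start[i] &
                  pos <= domain$end[i])
  }
  hit
}

#' Tally NGS calls against a Sanger truth set
#'
#' The evaluation domain is the intersection of the Sanger-interrogated
#' intervals with the exons padded by `exon_flank_keep` bases. Within the
#' domain, matching is by normalized variant key (an INDEL matches iff the
#' normalized keys match; each event occupies one evaluated site): TP when
#' a variant is in both sets, FN when truth-only, FP when NGS-only, and
#' every remaining interrogated base is a TN. This per-base TN accounting
#' (all interrogated reference bases that are not variant sites) is the
#' convention that yields truth denominators on the order of the amplicon
#' base count; it is recorded in the output so scope can be reconciled.
#'
#' @param ngs_calls variant `data.frame` (normalized).
#' @param truth_variants `data.frame` with `chrom`, `pos`, `ref`, `alt`
#'   (normalized Sanger-confirmed variants).
#' @param truth_intervals `data.frame` with `chrom`, `start`, `end`
#'   (0-based half-open Sanger amplicon intervals).
#' @param exons region `data.frame` of exon intervals (same reference
#'   frame).
#' @param settings a [concordance_settings()].
#' @return a [concordance_tally()] with attribute `domain_bases`.
#' @export
tally_concordance <- function(ngs_calls, truth_variants, truth_intervals,
                              exons, settings = concordance_settings()) {
  dup <- duplicated(truth_variants[, c("chrom", "pos")]) &
    !duplicated(truth_variants[, c("chrom", "pos", "ref", "alt")])
  if (any(dup))
    stop("contradictory truth records at ",
         paste(unique(paste0(truth_variants$chrom[dup], ":",
                             truth_variants$pos[dup])), collapse = ", "))
  domain <- evaluation_domain(truth_intervals, exons,
                              settings$exon_flank_keep)
  scope <- sum(domain$end - domain$start)
  truth_in <- truth_variants[in_domain(truth_variants$chrom,
                                       truth_variants$pos, domain), ,
                             drop = FALSE]
  ngs_in <- ngs_calls[in_domain(ngs_calls$chrom, ngs_calls$pos, domain), ,
                      drop = FALSE]
  tkey <- unique(variant_key(truth_in))
  nkey <- unique(variant_key(ngs_in))
  tp <- length(intersect(tkey, nkey))
  fn <- length(setdiff(tkey, nkey))
  fp <- length(setdiff(nkey, tkey))
  tn <- scope - tp - fn - fp
  if (tn < 0) stop("more variant sites than evaluated bases; check inputs")
  t <- concordance_tally(tp, fn, tn, fp)
  attr(t, "domain_bases") <- scope
  t
}

#' Sensitivity, specificity and error rates from a tally
#'
#' `sensitivity = 100 * tp / (tp + fn)`, `specificity = 100 * tn /
#' (tn + fp)`, `fn_rate = 100 * fn / (tp + fn)`, `fp_rate = 100 * fp /
#' (tn + fp)`; all in percent. The identities `sensitivity + fn_rate = 100`
#' and `specificity + fp_rate = 100` hold exactly. A metric whose
#' denominator is zero is returned as `NA` (explicitly not computable).
#'
#' @param t a [concordance_tally()].
#' @param digits decimals for the rounded reporting columns (3 by default;
#'   use 1 for the display mode).
#' @return `data.frame` with `metric`, `value` (full precision) and
#'   `rounded`.
#' @export
concordance_metrics <- function(t, digits = 3) {
  pos <- t$tp + t$fn
  neg <- t$tn + t$fp
  val <- c(sensitivity = if (pos > 0) 100 * t$tp / pos else NA_real_,
           specificity = if (neg > 0) 100 * t$tn / neg else NA_real_,
           fn_rate = if (pos > 0) 100 * t$fn / pos else NA_real_,
           fp_rate = if (neg > 0) 100 * t$fp / neg else NA_real_)
  data.frame(metric = names(val), value = unname(val),
             rounded = round(unname(val), digits),
             stringsAsFactors = FALSE)
}
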