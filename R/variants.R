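#' Construct a table of variant calls
#'
#' The central record of the toolkit: one row per called variant allele,
#' carrying sample and run provenance, depth, per-strand alt-supporting read
#' counts, a Phred-scaled quality and the variant allele frequency (VAF).
#' The representation is a plain `data.frame` so that every downstream stage
#' (blacklisting, triage, concordance) can use ordinary subsetting.
#'
#' @param sample_id,run_id character; provenance of the call set.
#' @param chrom character; contig name.
#' @param pos integer; 1-based position of the leftmost reference base of the
#'   event (VCF convention; INDELs are anchored on the preceding base).
#' @param ref,alt non-empty base strings (`A`/`C`/`G`/`T`), `ref != alt`.
#' @param quality Phred-scaled variant quality, `>= 0`; `NA` when unknown.
#' @param depth total read depth at the site, `>= 0`.
#' @param alt_fwd,alt_rev alt-supporting read counts on the forward and
#'   reverse strand; `NA` when the source format did not carry strand counts
#'   (such calls are flagged `strand_known = FALSE` and strand-dependent
#'   checks report "not evaluable" for them).
#' @param vaf variant allele frequency in `[0, 1]`; when `NULL` it is derived
#'   as `(alt_fwd + alt_rev) / depth` where `depth > 0`.
#' @param predicted_deleterious logical annotation flag supplied by an
#'   upstream annotation step; it is an input here, never computed.
#'
#' @return A `data.frame` with one row per call and columns `sample_id`,
#'   `run_id`, `chrom`, `pos`, `ref`, `alt`, `variant_type`, `quality`,
#'   `depth`, `alt_fwd`, `alt_rev`, `vaf`, `predicted_deleterious`,
#'   `strand_known`.
#' @export
variant_calls <- function(sample_id, run_id, chrom, pos, ref, alt,
                          quality = NA_real_, depth = 0L,
                          alt_fwd = NA_integer_, alt_rev = NA_integer_,
                          vaf = NULL, predicted_deleterious = FALSE) {
  n <- max(length(chrom), length(pos), length(ref), length(alt))
  df <- data.frame(
    sample_id = rep_len(as.character(sample_id), n),
    run_id = rep_len(as.character(run_id), n),
    chrom = rep_len(as.character(chrom), n),
    pos = rep_len(as.integer(pos), n),
    ref = rep_len(toupper(as.character(ref)), n),
    alt = rep_len(toupper(as.character(alt)), n),
    quality = rep_len(as.numeric(quality), n),
    depth = rep_len(as.integer(depth), n),
    alt_fwd = rep_len(as.integer(alt_fwd), n),
    alt_rev = rep_len(as.integer(alt_rev), n),
    predicted_deleterious = rep_len(as.logical(predicted_deleterious), n),
    stringsAsFactors = FALSE
  )
  df$variant_type <- classify_variant_type(df$ref, df$alt)
  df$strand_known <- !is.na(df$alt_fwd) & !is.na(df$alt_rev)
  if (is.null(vaf)) {
    ac <- ifelse(df$strand_known, df$alt_fwd + df$alt_rev, NA_integer_)
    df$vaf <- ifelse(df$depth > 0 & !is.na(ac), ac / df$depth, NA_real_)
  } else {
    df$vaf <- rep_len(as.numeric(vaf), n)
  }
  validate_variant_calls(df)
  df[, c("sample_id", "run_id", "chrom", "pos", "ref", "alt", "variant_type",
         "quality", "depth", "alt_fwd", "alt_rev", "vaf",
         "predicted_deleterious", "strand_known")]
}

#' Classify a ref/alt pair as SNV, INS, DEL or MNV
#'
#' @param ref,alt base strings.
#' @return character vector of `"SNV"`, `"INS"`, `"DEL"` or `"MNV"`.
#' @export
classify_variant_type <- function(ref, alt) {
  nr <- nchar(ref); na <- nchar(alt)
  ifelse(nr == 1L & na == 1L, "SNV",
         ifelse(na > nr, "INS",
                ifelse(nr > na, "DEL", "MNV")))
}

validate_variant_calls <- function(df) {
  stopifnot(is.data.frame(df))
  if (any(!nzchar(df$ref)) || any(!nzchar(df$alt)))
    stop("ref and alt must be non-empty base strings")
  if (any(df$ref == df$alt))
    stop("ref must differ from alt")
  bad <- grepl("[^ACGTN]", df$ref) | grepl("[^ACGTN]", df$alt)
  if (any(bad))
    stop("ref/alt contain non-base characters: ",
         paste(df$ref[bad], df$alt[bad], sep = ">", collapse = ", "))
  if (any(df$pos < 1L, na.rm = TRUE)) stop("pos must be >= 1")
  if (any(df$depth < 0L, na.rm = TRUE)) stop("depth must be >= 0")
  if (any(df$quality < 0, na.rm = TRUE)) stop("quality must be >= 0")
  ac <- df$alt_fwd + df$alt_rev
  if (any(ac > df$depth, na.rm = TRUE))
    stop("alt_fwd + alt_rev must not exceed depth")
  if (any(df$vaf < 0 | df$vaf > 1, na.rm = TRUE))
    stop("vaf must lie in [0, 1]")
  invisible(df)
}

#' Normalized identity key of a variant
#'
#' `chrom:pos:ref:alt` of the *normalized* representation; equal keys mean
#' the same genomic event. Used for blacklist matching, cohort checks and
#' concordance. Callers are responsible for normalizing first (see
#' [normalize_variant()]).
#'
#' @param calls a variant `data.frame` (or any data.frame with `chrom`,
#'   `pos`, `ref`, `alt` columns).
#' @return character vector of keys.
#' @export
variant_key <- function(calls) {
  paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":")
}

#' Left-align and trim a variant to its minimal anchored representation
#'
#' INDEL notation emitted by callers and annotation chains is frequently
#' non-canonical (right-shifted, padded with shared bases), which breaks
#' identity-based filtering. This routine reduces any representation to the
#' conventional minimal left-aligned form: shared suffix bases are trimmed
#' (extending left through the reference when an allele would empty), the
#' event is shifted to its leftmost equivalent position, and shared prefix
#' bases are trimmed down to a single anchor base for INDELs. SNVs pass
#' through unchanged. The operation is idempotent.
#'
#' @param pos 1-based position of the variant within the genome frame of
#'   `window_start`.
#' @param ref,alt allele strings as reported.
#' @param window reference base string covering the event and enough left
#'   context to permit shifting.
#' @param window_start 1-based genomic position of the first base of
#'   `window`.
#' @return list with elements `pos`, `ref`, `alt`.
#' @export
normalize_variant <- function(pos, ref, alt, window, window_start) {
  ref <- toupper(ref); alt <- toupper(alt); window <- toupper(window)
  w <- strsplit(window, "", fixed = TRUE)[[1]]
  off <- pos - window_start + 1L
  if (off < 1L || off + nchar(ref) - 1L > length(w))
    stop("reference window does not cover the event at pos ", pos)
  have <- paste(w[seq(off, length.out = nchar(ref))], collapse = "")
  if (nzchar(ref) && have != ref)
    stop("reference mismatch at pos ", pos, ": expected '", have,
         "' from the window, got ref '", ref, "'")
  r <- strsplit(ref, "", fixed = TRUE)[[1]]
  a <- strsplit(alt, "", fixed = TRUE)[[1]]
  repeat {
    changed <- FALSE
    if (length(r) > 0L && length(a) > 0L && r[length(r)] == a[length(a)] &&
        !(length(r) == 1L && length(a) == 1L)) {
      r <- r[-length(r)]; a <- a[-length(a)]
      changed <- TRUE
    }
    if (length(r) == 0L || length(a) == 0L) {
      if (off == 1L)
        stop("window too small to left-extend the event at pos ", pos)
      off <- off - 1L
      r <- c(w[off], r); a <- c(w[off], a)
      changed <- TRUE
    }
    if (!changed) break
  }
  while (length(r) > 1L && length(a) > 1L && r[1L] == a[1L]) {
    r <- r[-1L]; a <- a[-1L]; off <- off + 1L
  }
  list(pos = window_start + off - 1L,
       ref = paste(r, collapse = ""),
       alt = paste(a, collapse = ""))
}

#' Normalize every call in a variant table against panel reference windows
#'
#' @param calls variant `data.frame`.
#' @param panel a panel as returned by [simulate_panel()]: a list with
#'   `regions` (see [read_regions()]) and `reference` (named character
#'   vector of per-region reference strings).
#' @return `calls` with `pos`, `ref`, `alt` and `variant_type` rewritten to
#'   the normalized representation.
#' @export
normalize_calls <- function(calls, panel) {
  if (nrow(calls) == 0L) return(calls)
  regions <- panel$regions
  for (i in seq_len(nrow(calls))) {
    hit <- which(regions$chrom == calls$chrom[i] &
                 regions$start < calls$pos[i] &
                 regions$end >= calls$pos[i])
    if (length(hit) == 0L) next
    hit <- hit[1L]
    nv <- normalize_variant(calls$pos[i], calls$ref[i], calls$alt[i],
                            panel$reference[[regions$region_id[hit]]],
                            regions$start[hit] + 1L)
    calls$pos[i] <- nv$pos
    calls$ref[i] <- nv$ref
    calls$alt[i] <- nv$alt
  }
  calls$variant_type <- classify_variant_type(calls$ref, calls$alt)
  calls
}

# INFO tags of the package's VCF dialect (the source platform's tag set is
# not standardized; these are documented in the header of every file written).
.vcf_info_spec <- c(
  DP = "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
  AF = "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Variant allele frequency\">",
  SAF = "##INFO=<ID=SAF,Number=A,Type=Integer,Description=\"Alt-supporting reads, forward strand\">",
  SAR = "##INFO=<ID=SAR,Number=A,Type=Integer,Description=\"Alt-supporting reads, reverse strand\">",
  DEL = "##INFO=<ID=DEL,Number=A,Type=Integer,Description=\"Predicted deleterious flag (0/1)\">"
)

#' Read variant calls from a VCF file
#'
#' Parses a VCF v4.x file (via \pkg{vcfR}) into a variant `data.frame`.
#' Multi-allelic records are split into one row per ALT allele, with
#' per-allele INFO tags (`AF`, `SAF`, `SAR`, `DEL`) split alongside.
#' Missing strand counts do not fail parsing; the affected rows get
#' `strand_known = FALSE` and downstream strand-dependent checks treat them
#' as not evaluable.
#'
#' @param path VCF file.
#' @param sample_id,run_id provenance; when `NULL` they are taken from
#'   `##sample_id=` / `##run_id=` header lines, else `NA`.
#' @return variant `data.frame` (see [variant_calls()]).
#' @export
read_variants <- function(path, sample_id = NULL, run_id = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  meta <- vcf@meta
  hdr_val <- function(tag) {
    ln <- grep(paste0("^##", tag, "="), meta, value = TRUE)
    if (length(ln)) sub(paste0("^##", tag, "="), "", ln[1L]) else NA_character_
  }
  if (is.null(sample_id)) sample_id <- hdr_val("sample_id")
  if (is.null(run_id)) run_id <- hdr_val("run_id")
  fix <- vcf@fix
  if (is.null(fix) || nrow(fix) == 0L) {
    return(variant_calls(sample_id, run_id, character(), integer(),
                         character(), character()))
  }
  info_field <- function(info, tag) {
    m <- regexpr(paste0("(?:^|;)", tag, "=([^;]*)"), info, perl = TRUE)
    if (m == -1L) return(NA_character_)
    hit <- regmatches(info, m)
    sub(paste0("^;?", tag, "="), "", hit)
  }
  out <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    k <- length(alts)
    info <- fix[i, "INFO"]
    g <- function(tag) {
      v <- info_field(info, tag)
      if (is.na(v)) return(rep(NA_character_, k))
      parts <- strsplit(v, ",", fixed = TRUE)[[1]]
      rep_len(parts, k)
    }
    pos <- suppressWarnings(as.integer(fix[i, "POS"]))
    if (is.na(pos))
      stop("malformed VCF record at line-record ", i, ": non-integer POS '",
           fix[i, "POS"], "'")
    dp <- suppressWarnings(as.integer(info_field(info, "DP")))
    if (is.na(dp)) {
      warning("record ", i, " lacks DP; depth marked unknown (0)")
      dp <- 0L
    }
    af <- suppressWarnings(as.numeric(g("AF")))
    saf <- suppressWarnings(as.integer(g("SAF")))
    sar <- suppressWarnings(as.integer(g("SAR")))
    del <- suppressWarnings(as.integer(g("DEL")))
    qual <- suppressWarnings(as.numeric(fix[i, "QUAL"]))
    out[[i]] <- variant_calls(
      sample_id = sample_id, run_id = run_id,
      chrom = fix[i, "CHROM"], pos = pos,
      ref = fix[i, "REF"], alt = alts,
      quality = qual, depth = dp,
      alt_fwd = saf, alt_rev = sar,
      vaf = if (all(is.na(af))) NULL else af,
      predicted_deleterious = !is.na(del) & del == 1L
    )
  }
  do.call(rbind, out)
}

#' Write variant calls as a VCF file
#'
#' Emits plain-text VCF v4.2 with the package's documented INFO dialect
#' (`DP`, `AF`, `SAF`, `SAR`, `DEL`) and `##sample_id=` / `##run_id=` header
#' lines, so that [read_variants()] round-trips all fields.
#'
#' @param calls variant `data.frame`.
#' @param path output file.
#' @param sample_id,run_id provenance written to the header; defaults to
#'   the (unique) values in `calls`. Supply explicitly for empty call sets.
#' @return `path`, invisibly.
#' @export
write_variants <- function(calls, path, sample_id = NULL, run_id = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##source=pidpanel_", utils::packageVersion("pidpanel")),
           unname(.vcf_info_spec))
  sid <- if (is.null(sample_id)) unique(calls$sample_id) else sample_id
  rid <- if (is.null(run_id)) unique(calls$run_id) else run_id
  if (length(sid) == 1L && !is.na(sid)) hdr <- c(hdr, paste0("##sample_id=", sid))
  if (length(rid) == 1L && !is.na(rid)) hdr <- c(hdr, paste0("##run_id=", rid))
  hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  fmt_num <- function(x) ifelse(is.na(x), ".", format(x, scientific = FALSE,
                                                      trim = TRUE, digits = 10))
  body <- character(0)
  if (nrow(calls)) {
    info <- paste0("DP=", calls$depth,
                   ";AF=", fmt_num(round(calls$vaf, 6)),
                   ifelse(calls$strand_known,
                          paste0(";SAF=", calls$alt_fwd, ";SAR=", calls$alt_rev),
                          ""),
                   ";DEL=", as.integer(calls$predicted_deleterious))
    body <- paste(calls$chrom, calls$pos, ".", calls$ref, calls$alt,
                  fmt_num(calls$quality), "PASS", info, sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}
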