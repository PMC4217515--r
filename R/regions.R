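#' Construct a table of panel target regions
#'
#' Intervals follow the BED convention: 0-based inclusive `start`, exclusive
#' `end`. All internal region arithmetic in the package is half-open
#' 0-based; variant positions alone are 1-based (VCF convention).
#'
#' @param region_id,gene,chrom character.
#' @param start,end integers, `start < end` (0-based half-open).
#' @param flank bases of exon flank included in the capture design
#'   (default 10; extended designs use 25).
#' @return `data.frame` with columns `region_id`, `gene`, `chrom`, `start`,
#'   `end`, `flank`, sorted by `(chrom, start)`.
#' @export
target_regions <- function(region_id, gene = NA_character_, chrom, start, end,
                           flank = 10L) {
  df <- data.frame(region_id = as.character(region_id),
                   gene = as.character(gene),
                   chrom = as.character(chrom),
                   start = as.integer(start),
                   end = as.integer(end),
                   flank = as.integer(flank),
                   stringsAsFactors = FALSE)
  bad <- df$start >= df$end
  if (any(bad))
    stop("start must be < end; offending region(s): ",
         paste(df$region_id[bad], collapse = ", "))
  if (any(df$flank < 0L)) stop("flank must be >= 0")
  df[order(df$chrom, df$start), , drop = FALSE]
}

#' Read panel target regions from a BED file
#'
#' Accepts 3+ column BED (0-based half-open). `region_id` is taken from the
#' name column when present, otherwise synthesized (`region_000001`, ...);
#' a name of the form `GENE|ID` is split into `gene` and `region_id`.
#' Records are returned sorted by `(chrom, start)`; overlapping regions are
#' preserved, never merged.
#'
#' @param path BED file.
#' @param flank design flank recorded on each region (metadata only).
#' @return region `data.frame` (see [target_regions()]).
#' @export
read_regions <- function(path, flank = 10L) {
  gr <- as.data.frame(rtracklayer::import(path, format = "bed"))
  n <- nrow(gr)
  if (n == 0L)
    return(target_regions(character(), character(), character(),
                          integer(), integer())[0, ])
  nm <- if (!is.null(gr$name)) as.character(gr$name) else rep(NA_character_, n)
  nm[is.na(nm) | !nzchar(nm)] <-
    sprintf("region_%06d", which(is.na(nm) | !nzchar(nm)))
  gene <- ifelse(grepl("|", nm, fixed = TRUE), sub("\\|.*$", "", nm),
                 NA_character_)
  rid <- sub("^.*\\|", "", nm)
  target_regions(region_id = rid, gene = gene,
                 chrom = as.character(gr$seqnames),
                 start = gr$start - 1L,  # GRanges is 1-based closed
                 end = gr$end,
                 flank = flank)
}

#' Write panel target regions as a 4-column BED file
#'
#' The name column stores `gene|region_id` when a gene is recorded,
#' otherwise `region_id`, so [read_regions()] round-trips both fields.
#'
#' @param regions region `data.frame`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  nm <- ifelse(is.na(regions$gene), regions$region_id,
               paste0(regions$gene, "|", regions$region_id))
  writeLines(paste(regions$chrom, regions$start, regions$end, nm, sep = "\t"),
             path)
  invisible(path)
}

#' Per-base depth profiles
#'
#' A set of depth profiles is a named list of non-negative integer vectors,
#' one per region, each of length `end - start` of its region.
#'
#' @param profiles named list of integer vectors.
#' @param regions matching region `data.frame` (optional; when supplied,
#'   lengths are checked against the intervals).
#' @return the validated named list.
#' @export
depth_profiles <- function(profiles, regions = NULL) {
  stopifnot(is.list(profiles), !is.null(names(profiles)))
  for (id in names(profiles)) {
    d <- profiles[[id]]
    if (any(d < 0)) stop("negative depth in profile ", id)
    if (!is.null(regions)) {
      r <- regions[regions$region_id == id, , drop = FALSE]
      if (nrow(r) == 1L && length(d) != r$end - r$start)
        stop("profile ", id, " has length ", length(d),
             " but region spans ", r$end - r$start, " bases")
    }
  }
  profiles
}

#' Write / read depth profiles as a long-format TSV
#'
#' Columns: `region_id`, `offset` (0-based within the region), `depth`.
#'
#' @param profiles named list of integer vectors.
#' @param path file path.
#' @return `write_depth_profiles()` returns `path` invisibly;
#'   `read_depth_profiles()` the named list.
#' @export
write_depth_profiles <- function(profiles, path) {
  df <- do.call(rbind, lapply(names(profiles), function(id)
    data.frame(region_id = id, offset = seq_along(profiles[[id]]) - 1L,
               depth = as.integer(profiles[[id]]))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_depth_profiles
#' @export
read_depth_profiles <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  out <- lapply(split(df, df$region_id), function(d)
    as.integer(d$depth[order(d$offset)]))
  depth_profiles(out[unique(df$region_id)])
}
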