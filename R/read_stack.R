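#' Columnar read stack over a region window
#'
#' The substrate for pileup calling and the same-read co-variant triage
#' check. A stack records, for every read, the observed allele at every
#' window position: a plain base (`"A"`), a deleted base (`"-"`), a base
#' followed by an insertion (`"A+TT"`, the insertion lying to its right), or
#' `NA` where the read does not cover the position. Stacks are columnar
#' allele observations, not full sequencer reads: sufficient for every
#' computation in this package while staying desk-scale.
#'
#' @param chrom contig name.
#' @param start 0-based start of the window (half-open interval
#'   `[start, start + nchar(ref))`).
#' @param ref reference base string of the window.
#' @param obs character matrix, one row per read, one column per window
#'   position.
#' @param strand character vector (`"+"`/`"-"`), one per read.
#' @param read_id optional read identifiers.
#' @param sample_id,run_id provenance carried onto emitted calls.
#' @return object of class `read_stack`.
#' @export
read_stack <- function(chrom, start, ref, obs, strand, read_id = NULL,
                       sample_id = NA_character_, run_id = NA_character_) {
  ref <- toupper(ref)
  w <- nchar(ref)
  if (!is.matrix(obs)) obs <- matrix(obs, nrow = length(strand), byrow = TRUE)
  if (ncol(obs) != w)
    stop("observation matrix has ", ncol(obs), " columns but the window is ",
         w, " bases")
  if (nrow(obs) != length(strand))
    stop("strand vector length must equal the number of reads")
  if (!all(strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (is.null(read_id)) read_id <- sprintf("read_%05d", seq_along(strand))
  structure(list(chrom = as.character(chrom), start = as.integer(start),
                 ref = ref, obs = obs, strand = as.character(strand),
                 read_id = as.character(read_id),
                 sample_id = as.character(sample_id),
                 run_id = as.character(run_id)),
            class = "read_stack")
}

#' @export
print.read_stack <- function(x, ...) {
  cat("read_stack: ", x$chrom, ":", x$start, "-", x$start + nchar(x$ref),
      " (", nrow(x$obs), " reads x ", ncol(x$obs), " bases)\n", sep = "")
  invisible(x)
}

#' Number of reads covering each window column
#'
#' @param stack a [read_stack()].
#' @return integer vector, one entry per window position.
#' @export
stack_depth <- function(stack) {
  if (nrow(stack$obs) == 0L) return(integer(ncol(stack$obs)))
  colSums(!is.na(stack$obs))
}

# Base part of an observation ("A+TT" -> "A"; "-" stays "-").
obs_base <- function(x) sub("\\+.*$", "", x)

# Insertion part ("A+TT" -> "TT"; "" when none).
obs_ins <- function(x) ifelse(grepl("+", x, fixed = TRUE),
                              sub("^[^+]*\\+", "", x), "")
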