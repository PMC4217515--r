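#' Build a recurrent-artifact blacklist from healthy-control call sets
#'
#' Low-stringency calling inflates the false-positive load with
#' platform-specific recurrent artifacts. These are identified from a panel
#' of healthy controls: a variant key enters the blacklist iff it is flagged
#' `predicted_deleterious` and is present as a called variant in **more than
#' one** distinct control sample. Presence means presence at any VAF or
#' quality — the filter acts on occurrence, not call strength.
#'
#' @param control_callsets list of variant `data.frame`s, one per control
#'   sample (calls normalized). Each must carry a single, distinct
#'   `sample_id`; a duplicated control `sample_id` is an error
#'   (double-counting hazard).
#' @return object of class `blacklist`: a `data.frame` with columns `chrom`,
#'   `pos`, `ref`, `alt`, `key` and `n_controls` (provenance; always
#'   `>= 2`).
#' @export
build_blacklist <- function(control_callsets) {
  ids <- vapply(control_callsets, function(x) {
    u <- unique(x$sample_id)
    if (length(u) > 1L) stop("a control call set mixes sample_ids: ",
                             paste(u, collapse = ", "))
    if (length(u) == 0L) NA_character_ else u
  }, character(1))
  seen <- ids[!is.na(ids)]
  if (anyDuplicated(seen))
    stop("duplicate control sample_id(s): ",
         paste(unique(seen[duplicated(seen)]), collapse = ", "))
  per_control <- lapply(control_callsets, function(x) {
    x <- x[x$predicted_deleterious %in% TRUE, , drop = FALSE]
    unique(x[, c("chrom", "pos", "ref", "alt")])
  })
  all_keys <- do.call(rbind, per_control)
  if (is.null(all_keys) || nrow(all_keys) == 0L) {
    bl <- data.frame(chrom = character(), pos = integer(), ref = character(),
                     alt = character(), key = character(),
                     n_controls = integer(), stringsAsFactors = FALSE)
    class(bl) <- c("blacklist", "data.frame")
    return(bl)
  }
  key <- variant_key(all_keys)
  counts <- table(key)
  keep <- names(counts)[counts > 1L]
  bl <- unique(all_keys[key %in% keep, , drop = FALSE])
  bl$key <- variant_key(bl)
  bl$n_controls <- as.integer(counts[bl$key])
  bl <- bl[order(bl$chrom, bl$pos, bl$ref, bl$alt), , drop = FALSE]
  rownames(bl) <- NULL
  class(bl) <- c("blacklist", "data.frame")
  bl
}

#' Subtract a blacklist from a patient call set
#'
#' Splits a call set into calls kept and calls removed by exact
#' normalized-key match against the blacklist. The union of the two parts is
#' the input, order preserved within each part; a call at a blacklisted
#' position but with a different alt allele is kept. Idempotent.
#'
#' @param patient_calls variant `data.frame` (normalized).
#' @param bl a [build_blacklist()] result (or object from
#'   [read_blacklist()]).
#' @return list with elements `kept` and `removed`, both variant
#'   `data.frame`s.
#' @export
apply_blacklist <- function(patient_calls, bl) {
  hit <- variant_key(patient_calls) %in% bl$key
  list(kept = patient_calls[!hit, , drop = FALSE],
       removed = patient_calls[hit, , drop = FALSE])
}

#' Serialize / load a blacklist as 4-column BED
#'
#' BED geometry is interval-only, so the full normalized key
#' (`chrom:pos:ref:alt`) is stored in the name column, with the interval
#' spanning the reference footprint (`pos-1`, `pos-1+nchar(ref)`); an
#' optional 5th column carries the control count.
#'
#' @param bl a blacklist.
#' @param path BED file path.
#' @return `write_blacklist()` returns `path` invisibly; `read_blacklist()`
#'   the blacklist object.
#' @export
write_blacklist <- function(bl, path) {
  writeLines(paste(bl$chrom, bl$pos - 1L, bl$pos - 1L + nchar(bl$ref),
                   bl$key, bl$n_controls, sep = "\t"),
             path)
  invisible(path)
}

#' @rdname write_blacklist
#' @export
read_blacklist <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    bl <- data.frame(chrom = character(), pos = integer(), ref = character(),
                     alt = character(), key = character(),
                     n_controls = integer(), stringsAsFactors = FALSE)
  } else {
    f <- strsplit(lines, "\t", fixed = TRUE)
    key <- vapply(f, `[`, character(1), 4L)
    kp <- strsplit(key, ":", fixed = TRUE)
    bl <- data.frame(
      chrom = vapply(kp, `[`, character(1), 1L),
      pos = as.integer(vapply(kp, `[`, character(1), 2L)),
      ref = vapply(kp, `[`, character(1), 3L),
      alt = vapply(kp, `[`, character(1), 4L),
      key = key,
      n_controls = as.integer(vapply(f, function(x)
        if (length(x) >= 5L) x[5L] else NA_character_, character(1))),
      stringsAsFactors = FALSE)
  }
  class(bl) <- c("blacklist", "data.frame")
  bl
}

#' Tabular report of a blacklist filtering step
#'
#' One row per patient call: key, blacklist control count (NA when not
#' blacklisted) and the action taken.
#'
#' @param patient_calls variant `data.frame`.
#' @param bl blacklist.
#' @return `data.frame` with columns `key`, `n_controls`, `action`.
#' @export
blacklist_report <- function(patient_calls, bl) {
  key <- variant_key(patient_calls)
  idx <- match(key, bl$key)
  data.frame(key = key,
             n_controls = bl$n_controls[idx],
             action = ifelse(is.na(idx), "kept", "removed"),
             stringsAsFactors = FALSE)
}
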