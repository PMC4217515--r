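#' Reagent cost model: Sanger vs targeted NGS
#'
#' Sanger sequencing costs scale linearly with the number of amplicons
#' (default $10 per amplicon of reagents) while the targeted NGS assay is a
#' flat per-sample cost (default $580). Labor is deliberately excluded —
#' it dominates total cost and favours NGS even more strongly — but a
#' labor multiplier hook exists for sensitivity analyses (defaults off).
#'
#' @param sanger_per_amplicon USD per Sanger amplicon.
#' @param ngs_per_sample USD per NGS sample.
#' @param labor_multiplier optional multiplier `>= 1` applied to both arms
#'   to sketch labor; `NULL` (default) leaves labor out.
#' @return list of class `cost_model`.
#' @export
cost_model <- function(sanger_per_amplicon = 10, ngs_per_sample = 580,
                       labor_multiplier = NULL) {
  if (sanger_per_amplicon < 0 || ngs_per_sample < 0)
    stop("costs must be >= 0")
  if (!is.null(labor_multiplier) && labor_multiplier < 1)
    stop("labor_multiplier must be >= 1")
  structure(list(sanger_per_amplicon = as.numeric(sanger_per_amplicon),
                 ngs_per_sample = as.numeric(ngs_per_sample),
                 labor_multiplier = labor_multiplier),
            class = "cost_model")
}

#' Phenotype gene panels
#'
#' A phenotype panel maps candidate genes to the number of Sanger amplicons
#' each requires. Known-family single-amplicon confirmation is modeled as a
#' one-gene, one-amplicon panel.
#'
#' @param phenotype panel name.
#' @param genes character vector of gene symbols.
#' @param amplicons integer vector of per-gene amplicon counts (`>= 1`).
#' @return `data.frame` with columns `phenotype`, `gene`, `amplicons`.
#' @export
phenotype_panel <- function(phenotype, genes, amplicons) {
  if (length(genes) != length(amplicons))
    stop("genes and amplicons differ in length")
  if (length(genes) == 0L) stop("a panel must contain at least one gene")
  if (any(amplicons < 1L)) stop("amplicon counts must be >= 1")
  data.frame(phenotype = phenotype, gene = as.character(genes),
             amplicons = as.integer(amplicons), stringsAsFactors = FALSE)
}

#' Read phenotype panels from TSV
#'
#' Columns: `phenotype`, `gene`, `amplicons`. The packaged fixture
#' `system.file("extdata", "phenotype_panels.tsv", package = "pidpanel")`
#' ships five published example panels.
#'
#' @param path TSV file; defaults to the packaged panel fixture.
#' @return `data.frame` with one row per (phenotype, gene).
#' @export
read_phenotype_panels <- function(path = system.file(
    "extdata", "phenotype_panels.tsv", package = "pidpanel")) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (any(df$amplicons < 1L)) stop("amplicon counts must be >= 1")
  df
}

#' Total amplicon count of a panel
#'
#' @param panel `data.frame` from [phenotype_panel()] (a single phenotype).
#' @return integer sum of per-gene amplicon counts.
#' @export
panel_amplicons <- function(panel) {
  if (nrow(panel) == 0L) stop("empty panel")
  sum(panel$amplicons)
}

#' Compare Sanger and NGS reagent costs for a panel
#'
#' Sanger cost is amplicons x per-amplicon cost; NGS is the flat per-sample
#' cost. `break_even` is the smallest integer amplicon count at which
#' Sanger becomes strictly more expensive than NGS (59 at the $10/$580
#' defaults); the comparison flips exactly there.
#'
#' @param panel a [phenotype_panel()] `data.frame`.
#' @param model a [cost_model()].
#' @return list: `phenotype`, `total_amplicons`, `sanger_usd`, `ngs_usd`,
#'   `cheaper` (`"sanger"`/`"ngs"`/`"tie"`), `break_even`.
#' @export
compare_costs <- function(panel, model = cost_model()) {
  n <- panel_amplicons(panel)
  mult <- if (is.null(model$labor_multiplier)) 1 else model$labor_multiplier
  sanger <- n * model$sanger_per_amplicon * mult
  ngs <- model$ngs_per_sample * mult
  cheaper <- if (sanger < ngs) "sanger" else if (ngs < sanger) "ngs" else "tie"
  break_even <- if (model$sanger_per_amplicon > 0)
    floor(model$ngs_per_sample / model$sanger_per_amplicon) + 1L
  else NA_integer_
  list(phenotype = unique(panel$phenotype), total_amplicons = n,
       sanger_usd = sanger, ngs_usd = ngs, cheaper = cheaper,
       break_even = break_even)
}
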