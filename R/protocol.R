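#' Paired Wilcoxon signed-rank test
#'
#' The paired nonparametric test used for region-by-region protocol
#' comparison. Zero differences are dropped (Wilcoxon's original
#' convention); absolute differences are ranked with mid-ranks for ties;
#' `V` is the sum of the ranks of the positive differences. The two-sided
#' p-value comes from the exact null distribution for `n <= exact_max`
#' nonzero differences — computed by a rank-polynomial convolution over all
#' `2^n` sign assignments, which handles ties exactly — and from the normal
#' approximation with the usual tie correction otherwise.
#'
#' @param diffs numeric vector of paired differences (or `x`), or minuend
#'   when `y` is supplied (`diffs - y` is tested).
#' @param y optional second sample (paired).
#' @param exact_max largest number of nonzero differences for which the
#'   exact distribution is enumerated.
#' @return list of class `wilcoxon_sr`: `V`, `p_value`, `n_nonzero`,
#'   `method` (`"exact"`/`"normal"`). All-zero differences give `V = NA`,
#'   `p_value = NA` (not computable).
#' @export
wilcoxon_signed_rank <- function(diffs, y = NULL, exact_max = 25L) {
  if (!is.null(y)) {
    if (length(diffs) != length(y)) stop("paired samples differ in length")
    diffs <- diffs - y
  }
  d <- diffs[!is.na(diffs)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(structure(list(V = NA_real_, p_value = NA_real_, n_nonzero = 0L,
                          method = "not_computable"),
                     class = "wilcoxon_sr"))
  r <- rank(abs(d))  # mid-ranks for ties
  V <- sum(r[d > 0])
  if (n <= exact_max) {
    # exact distribution of V over the 2^n equiprobable sign assignments:
    # convolution of (1 + x^(2*r_i)) polynomials on doubled ranks (doubling
    # makes mid-ranks integral)
    r2 <- as.integer(round(2 * r))
    maxs <- sum(r2)
    dist <- numeric(maxs + 1L)
    dist[1L] <- 1
    for (ri in r2) {
      shifted <- c(rep(0, ri), dist[seq_len(maxs + 1L - ri)])
      dist <- dist + shifted
    }
    dist <- dist / 2^n
    v2 <- as.integer(round(2 * V))
    p_le <- sum(dist[seq_len(v2 + 1L)])
    p_ge <- sum(dist[(v2 + 1L):(maxs + 1L)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (V - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  structure(list(V = V, p_value = p, n_nonzero = n, method = method),
            class = "wilcoxon_sr")
}

#' @export
print.wilcoxon_sr <- function(x, ...) {
  if (x$method == "not_computable") {
    cat("Wilcoxon signed-rank: not computable (all differences zero)\n")
  } else {
    cat("Wilcoxon signed-rank (paired, two-sided, ", x$method, "): V = ",
        x$V, ", p-value = ", format.pval(x$p_value), " (n = ", x$n_nonzero,
        " nonzero)\n", sep = "")
  }
  invisible(x)
}

#' Descriptive summary of paired per-region protocol metrics
#'
#' @param data `data.frame` with columns `region_id`, `depth_default`,
#'   `depth_optimized`, `cov_default`, `cov_optimized` (per-region mean
#'   read depth and percent coverage under each protocol).
#' @return list with per-metric, per-arm `median`, `q25`, `q75`, `min`,
#'   `max`; per-metric median deltas (optimized - default); per-arm flag
#'   counts (region flagged when mean depth < 20 or coverage < 100%) and
#'   the flag delta.
#' @export
paired_summary <- function(data) {
  need <- c("region_id", "depth_default", "depth_optimized",
            "cov_default", "cov_optimized")
  if (!all(need %in% names(data)))
    stop("paired data must have columns: ", paste(need, collapse = ", "))
  if (nrow(data) == 0L) stop("no region pairs supplied")
  five <- function(x) c(median = stats::median(x),
                        q25 = unname(stats::quantile(x, 0.25)),
                        q75 = unname(stats::quantile(x, 0.75)),
                        min = min(x), max = max(x))
  flags <- function(depth, cov) sum(depth < 20 | cov < 100)
  f_def <- flags(data$depth_default, data$cov_default)
  f_opt <- flags(data$depth_optimized, data$cov_optimized)
  list(
    n_regions = nrow(data),
    depth = list(default = five(data$depth_default),
                 optimized = five(data$depth_optimized),
                 delta_median = stats::median(data$depth_optimized) -
                   stats::median(data$depth_default)),
    coverage = list(default = five(data$cov_default),
                    optimized = five(data$cov_optimized),
                    delta_median = stats::median(data$cov_optimized) -
                      stats::median(data$cov_default)),
    flags = list(default = f_def, optimized = f_opt,
                 delta = f_opt - f_def)
  )
}

#' Compare two library-preparation protocols region by region
#'
#' Full paired comparison of a default and an optimized protocol over the
#' same panel: descriptive statistics and flag counts
#' ([paired_summary()]), paired Wilcoxon signed-rank tests on per-region
#' mean depth and percent coverage, a descriptive linear regression of
#' optimized on default for each metric, and the list of regions whose
#' coverage decreased under the optimized protocol.
#'
#' @param default_arm,optimized_arm `data.frame`s with columns `region_id`,
#'   `mean_depth`, `pct_covered` — one row per region, identical region
#'   sets (paired design; mismatched sets are an error).
#' @return list of class `protocol_comparison`.
#' @export
compare_protocols <- function(default_arm, optimized_arm) {
  if (!setequal(default_arm$region_id, optimized_arm$region_id) ||
      nrow(default_arm) != nrow(optimized_arm))
    stop("the two arms cover different region sets (paired design required)")
  o <- optimized_arm[match(default_arm$region_id, optimized_arm$region_id), ]
  data <- data.frame(region_id = default_arm$region_id,
                     depth_default = default_arm$mean_depth,
                     depth_optimized = o$mean_depth,
                     cov_default = default_arm$pct_covered,
                     cov_optimized = o$pct_covered,
                     stringsAsFactors = FALSE)
  summ <- paired_summary(data)
  regression <- function(x, yv) {
    fit <- stats::lm(yv ~ x)
    # identical arms give a degenerate perfect fit; report it quietly
    r2 <- suppressWarnings(summary(fit)$r.squared)
    list(slope = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]),
         r_squared = r2)
  }
  structure(list(
    summary = summ,
    depth_test = wilcoxon_signed_rank(data$depth_optimized,
                                      data$depth_default),
    coverage_test = wilcoxon_signed_rank(data$cov_optimized,
                                         data$cov_default),
    depth_regression = regression(data$depth_default, data$depth_optimized),
    coverage_regression = regression(data$cov_default, data$cov_optimized),
    decreased_regions =
      data$region_id[data$cov_optimized < data$cov_default],
    data = data
  ), class = "protocol_comparison")
}

#' @export
print.protocol_comparison <- function(x, ...) {
  s <- x$summary
  cat("Protocol comparison over", s$n_regions, "paired regions\n")
  cat("  median depth: default", s$depth$default["median"],
      "-> optimized", s$depth$optimized["median"],
      sprintf("(delta %+g)\n", s$depth$delta_median))
  cat("  median %coverage: default", s$coverage$default["median"],
      "-> optimized", s$coverage$optimized["median"],
      sprintf("(delta %+g)\n", s$coverage$delta_median))
  cat("  flags: default", s$flags$default, "-> optimized",
      s$flags$optimized, sprintf("(delta %+d)\n", s$flags$delta))
  cat("  depth test:    "); print(x$depth_test)
  cat("  coverage test: "); print(x$coverage_test)
  cat("  regions with decreased coverage:", length(x$decreased_regions),
      "\n")
  invisible(x)
}
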