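# Independent brute-force oracles. Written as plain scalar enumerations,
# deliberately not sharing code with the package implementation.

# Enumerate every representation (pos, ref, alt) over the window that yields
# the same edited haplotype as the given variant. Coordinates are 1-based
# within the window frame (window_start = 1). max_ref bounds the search.
enumerate_equivalents <- function(pos, ref, alt, window, max_ref = 8L) {
  n <- nchar(window)
  hap <- paste0(substr(window, 1, pos - 1), alt,
                substr(window, pos + nchar(ref), n))
  reps <- list()
  for (p2 in seq_len(n)) {
    for (lr in 0:min(max_ref, n - p2 + 1L)) {
      la <- nchar(hap) - (p2 - 1L) - (n - (p2 + lr) + 1L)
      if (la < 0L) next
      pre_w <- substr(window, 1, p2 - 1L)
      pre_h <- substr(hap, 1, p2 - 1L)
      suf_w <- substr(window, p2 + lr, n)
      suf_h <- substr(hap, nchar(hap) - nchar(suf_w) + 1L, nchar(hap))
      if (pre_w != pre_h || suf_w != suf_h) next
      r2 <- substr(window, p2, p2 + lr - 1L)
      a2 <- substr(hap, p2, p2 + la - 1L)
      if (r2 == a2) next
      reps[[length(reps) + 1L]] <- list(pos = p2, ref = r2, alt = a2)
    }
  }
  reps
}

# Apply a representation to the window; used to verify class membership.
apply_variant <- function(pos, ref, alt, window) {
  paste0(substr(window, 1, pos - 1), alt,
         substr(window, pos + nchar(ref), nchar(window)))
}

# Brute-force caller: enumerates every column and event with scalar loops
# and applies the stated predicates directly. Score via explicit dbinom
# summation, bias via max/sum.
brute_force_caller <- function(stack, settings) {
  obs <- stack$obs
  n_reads <- nrow(obs)
  w <- ncol(obs)
  refv <- strsplit(stack$ref, "", fixed = TRUE)[[1]]
  base_of <- function(x) sub("\\+.*$", "", x)
  score_of <- function(ac, dp) {
    p <- 0
    for (k in ac:dp) p <- p + dbinom(k, dp, settings$per_base_error_rate)
    if (p <= 0) return(settings$score_cap)
    min(-10 * log10(p), settings$score_cap)
  }
  passes <- function(rows, dp, is_snv) {
    ac <- length(rows)
    fwd <- sum(stack$strand[rows] == "+")
    rev <- ac - fwd
    min_cov <- if (is_snv) settings$min_cov_snp else settings$min_cov_indel
    min_each <- if (is_snv) settings$min_cov_each_strand_snp else
      settings$min_cov_each_strand_indel
    bias_max <- if (is_snv) settings$strand_bias_max_snp else
      settings$strand_bias_max_indel
    if (dp < min_cov) return(FALSE)
    if (fwd < min_each || rev < min_each) return(FALSE)
    if (score_of(ac, dp) < settings$min_variant_score) return(FALSE)
    if (!is.na(settings$min_allele_freq) &&
        ac / dp < settings$min_allele_freq) return(FALSE)
    if (ac > 0 && max(fwd, rev) / ac > bias_max) return(FALSE)
    TRUE
  }
  keys <- character(0)
  add_key <- function(pos, ref, alt) {
    nv <- pidpanel::normalize_variant(pos, ref, alt, stack$ref,
                                      stack$start + 1L)
    keys <<- c(keys, paste(stack$chrom, nv$pos, nv$ref, nv$alt, sep = ":"))
  }
  for (j in seq_len(w)) {
    covered <- which(!is.na(obs[, j]))
    dp <- length(covered)
    if (dp == 0L) next
    bases <- base_of(obs[covered, j])
    for (b in c("A", "C", "G", "T")) {
      if (b == refv[j]) next
      rows <- covered[bases == b]
      if (length(rows) == 0L) next
      if (passes(rows, dp, TRUE)) add_key(stack$start + j, refv[j], b)
    }
    # insertions keyed by inserted sequence
    has_ins <- grepl("+", obs[covered, j], fixed = TRUE)
    if (any(has_ins)) {
      seqs <- sub("^[^+]*\\+", "", obs[covered, j][has_ins])
      for (s in unique(seqs)) {
        rows <- covered[has_ins][seqs == s]
        if (passes(rows, dp, FALSE))
          add_key(stack$start + j, refv[j], paste0(refv[j], s))
      }
    }
  }
  # deletions: maximal gap runs per read, grouped
  groups <- list()
  for (r in seq_len(n_reads)) {
    j <- 1L
    while (j <= w) {
      if (!is.na(obs[r, j]) && base_of(obs[r, j]) == "-") {
        j2 <- j
        while (j2 < w && !is.na(obs[r, j2 + 1L]) &&
               base_of(obs[r, j2 + 1L]) == "-") j2 <- j2 + 1L
        key <- paste(j, j2 - j + 1L)
        groups[[key]] <- c(groups[[key]], r)
        j <- j2 + 1L
      } else j <- j + 1L
    }
  }
  for (key in names(groups)) {
    se <- as.integer(strsplit(key, " ")[[1]])
    j0 <- se[1L]; len <- se[2L]
    if (j0 <= 1L) next
    dp <- sum(!is.na(obs[, j0]))
    if (passes(groups[[key]], dp, FALSE))
      add_key(stack$start + j0 - 1L,
              paste(refv[(j0 - 1L):(j0 + len - 1L)], collapse = ""),
              refv[j0 - 1L])
  }
  sort(unique(keys))
}

# Random small stack generator for oracle-equivalence testing.
random_small_stack <- function(seed) {
  set.seed(seed)
  w <- sample(20:35, 1)
  refseq <- paste(sample(c("A", "C", "G", "T"), w, replace = TRUE),
                  collapse = "")
  reg <- target_regions("rx", "GX", "chr9", 500L, 500L + w)
  depth <- sample(c(5L, 12L, 25L, 40L), 1)
  planted <- NULL
  u <- runif(1)
  if (u < 0.5) {
    off <- sample(3:(w - 4), 1)
    rb <- substr(refseq, off + 1, off + 1)
    planted <- data.frame(offset = off, ref = rb,
                          alt = sample(setdiff(c("A", "C", "G", "T"), rb), 1),
                          vaf = runif(1, 0.05, 1), stringsAsFactors = FALSE)
  } else if (u < 0.8) {
    off <- sample(3:(w - 6), 1)
    if (runif(1) < 0.5) {
      dl <- sample(1:2, 1)
      planted <- data.frame(offset = off,
                            ref = substr(refseq, off + 1, off + 1 + dl),
                            alt = substr(refseq, off + 1, off + 1),
                            vaf = runif(1, 0.2, 1), stringsAsFactors = FALSE)
    } else {
      rb <- substr(refseq, off + 1, off + 1)
      planted <- data.frame(offset = off, ref = rb,
                            alt = paste0(rb, sample(c("T", "AG"), 1)),
                            vaf = runif(1, 0.2, 1), stringsAsFactors = FALSE)
    }
  }
  simulate_read_stack(reg, refseq, rep(depth, w), planted,
                      error_rate = 0.02, seed = seed + 1000L,
                      sample_id = "S", run_id = "R")
}

# A clean stack whose reads all match the reference except the requested
# alt reads at one column (1-based col).
clean_stack <- function(refseq, n_reads, alt_col, alt_base, n_alt,
                        start = 0L, chrom = "chr1") {
  refv <- strsplit(refseq, "", fixed = TRUE)[[1]]
  obs <- matrix(rep(refv, each = n_reads), nrow = n_reads)
  if (n_alt > 0) obs[seq_len(n_alt), alt_col] <- alt_base
  strand <- rep(c("+", "-"), length.out = n_reads)
  read_stack(chrom, start, refseq, obs, strand, sample_id = "S",
             run_id = "R")
}
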