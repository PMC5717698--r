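#' Filter loci on polymorphism, minor allele frequency and missingness
#'
#' Applies the standard panel filters in a fixed order — monomorphic first,
#' then pooled minor allele frequency, then pooled missingness — so each
#' removed locus is attributed to exactly one rule. MAF and missingness are
#' computed on the pooled dataset (all lineages together, one pass).
#' Boundary convention: a locus with MAF exactly `maf_min` is retained
#' (removal requires MAF strictly below the floor) and one missing in
#' exactly `max_missing` of individuals is retained (removal requires
#' strictly more).
#'
#' @param ds A [genotype_dataset()].
#' @param maf_min Minimum pooled minor-allele frequency (default 0.01).
#' @param max_missing Maximum pooled missing fraction (default 0.15).
#' @return A list with class `locus_filter`: `dataset` (the filtered
#'   [genotype_dataset()]) and `removed`, a data frame `locus,rule` with
#'   `rule` in `monomorphic`, `maf`, `missing`.
#' @export
filter_loci <- function(ds, maf_min = 0.01, max_missing = 0.15) {
  stopifnot(inherits(ds, "genotype_dataset"))
  if (maf_min < 0 || maf_min >= 0.5) stop("maf_min must be in [0, 0.5)")
  if (max_missing <= 0 || max_missing > 1) stop("max_missing must be in (0, 1]")

  g <- ds$genotypes
  n_called <- colSums(!is.na(g))
  p <- colSums(g, na.rm = TRUE) / (2 * n_called)    # NaN when never called
  maf <- pmin(p, 1 - p)
  miss_frac <- (nrow(g) - n_called) / nrow(g)   # exact at count boundaries

  mono <- n_called == 0 | p %in% c(0, 1)
  low_maf <- !mono & maf < maf_min
  too_missing <- !mono & !low_maf & miss_frac > max_missing
  drop <- mono | low_maf | too_missing

  removed <- data.frame(
    locus = colnames(g)[drop],
    rule = c("monomorphic", "maf", "missing")[
      ifelse(mono, 1L, ifelse(low_maf, 2L, 3L))[drop]],
    stringsAsFactors = FALSE)
  if (all(drop)) stop("no loci left after filtering (empty panel)")

  out <- list(dataset = subset_dataset(ds, loci = colnames(g)[!drop]),
              removed = removed,
              maf_min = maf_min, max_missing = max_missing)
  class(out) <- "locus_filter"
  out
}

#' @export
print.locus_filter <- function(x, ...) {
  cat("locus_filter:", n_loci(x$dataset), "loci retained,",
      nrow(x$removed), "removed\n")
  if (nrow(x$removed)) print(table(x$removed$rule))
  invisible(x)
}

#' Per-population counted-allele frequencies
#'
#' For each population j and locus i: `p[j, i]` is the counted-allele
#' frequency among non-missing genotypes and `m[j, i] = 2 * n_called` the
#' allele sample size. A (population, locus) cell with no called genotypes
#' has `m = 0` and `p = NA` (undefined, never coerced to 0).
#'
#' @param ds A [genotype_dataset()].
#' @return A `freq_table`: list with matrices `p` and `m`
#'   (populations x loci), `populations` (metadata rows in matrix order)
#'   and `loci`.
#' @export
allele_frequencies <- function(ds) {
  stopifnot(inherits(ds, "genotype_dataset"))
  if (!n_loci(ds) || !n_individuals(ds)) stop("empty dataset")
  pop <- factor(ds$individuals$population,
                levels = ds$populations$population)
  g <- ds$genotypes
  counts <- rowsum(ifelse(is.na(g), 0L, g), pop)          # allele copies
  called <- rowsum((!is.na(g)) + 0L, pop)
  m <- 2L * called
  p <- counts / m
  p[m == 0] <- NA_real_
  structure(list(p = p, m = m,
                 populations = ds$populations,
                 loci = colnames(g)),
            class = "freq_table")
}

#' @export
print.freq_table <- function(x, ...) {
  cat("freq_table:", nrow(x$p), "populations x", length(x$loci), "loci\n")
  invisible(x)
}
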