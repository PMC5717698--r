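#' Observed heterozygosity per locus
#'
#' Ho(locus) = heterozygote count / non-missing genotype count, optionally
#' within groups (e.g. per lineage). An all-missing locus is undefined (NA).
#'
#' @param ds A [genotype_dataset()].
#' @param by `"all"` (pooled), `"lineage"` or `"population"`.
#' @return A list: `ho` — matrix of Ho (groups x loci) — and `mean_ho`,
#'   the per-group mean over loci with defined Ho.
#' @export
observed_heterozygosity <- function(ds, by = c("all", "lineage", "population")) {
  stopifnot(inherits(ds, "genotype_dataset"))
  by <- match.arg(by)
  if (!n_individuals(ds)) stop("empty dataset")
  grp <- switch(by,
    all = rep("all", n_individuals(ds)),
    population = ds$individuals$population,
    lineage = ds$populations$lineage[
      match(ds$individuals$population, ds$populations$population)])
  grp <- factor(grp, levels = unique(grp))
  g <- ds$genotypes
  het <- rowsum((!is.na(g) & g == 1L) + 0L, grp)
  called <- rowsum((!is.na(g)) + 0L, grp)
  ho <- het / called
  ho[called == 0] <- NA_real_
  list(ho = ho, mean_ho = rowMeans(ho, na.rm = TRUE))
}

# Weir & Cockerham (1984) per-locus variance components for one biallelic
# locus from per-population (n_i, p_i, h_i): sample sizes in individuals,
# counted-allele frequencies, observed heterozygote frequencies.
wc_components_one <- function(n, p, h) {
  keep <- n > 0
  n <- n[keep]; p <- p[keep]; h <- h[keep]
  r <- length(n)
  if (r < 2) return(c(a = NA_real_, b = NA_real_, c = NA_real_))
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

#' Weir-Cockerham F_ST
#'
#' Per-locus variance components a (among populations), b (among
#' individuals within populations) and c (within individuals) following
#' Weir & Cockerham's (1984) estimator for diploid biallelic data, with
#' theta-hat = a / (a + b + c) per locus and the multilocus estimate as the
#' ratio of summed components (ratio of sums, not mean of ratios). Loci
#' monomorphic across the groups are undefined (0/0) and excluded from the
#' multilocus sums. Negative per-locus estimates are retained.
#'
#' @param ds A [genotype_dataset()].
#' @param grouping Optional per-individual labels to use instead of
#'   population membership.
#' @return A list of class `fst_result`: `per_locus` data frame
#'   (`locus,a,b,c,theta`), `multilocus`, and the summed components.
#' @export
wc_fst <- function(ds, grouping = NULL) {
  stopifnot(inherits(ds, "genotype_dataset"))
  if (is.null(grouping)) grouping <- ds$individuals$population
  grouping <- factor(grouping, levels = unique(grouping))
  if (nlevels(grouping) < 2) stop("need at least 2 populations")
  g <- ds$genotypes
  called <- rowsum((!is.na(g)) + 0L, grouping)
  count <- rowsum(ifelse(is.na(g), 0L, g), grouping)
  hets <- rowsum((!is.na(g) & g == 1L) + 0L, grouping)
  p <- count / (2 * called); p[called == 0] <- 0
  h <- hets / called; h[called == 0] <- 0

  comp <- vapply(seq_len(ncol(g)), function(j)
    wc_components_one(called[, j], p[, j], h[, j]), numeric(3))
  a <- comp[1, ]; b <- comp[2, ]; cc <- comp[3, ]
  tot <- a + b + cc
  theta <- ifelse(is.na(tot) | tot == 0, NA_real_, a / tot)
  usable <- !is.na(tot) & tot != 0
  per_locus <- data.frame(locus = colnames(g), a = a, b = b, c = cc,
                          theta = theta, stringsAsFactors = FALSE)
  structure(list(per_locus = per_locus,
                 multilocus = sum(a[usable]) / sum(tot[usable]),
                 sum_a = sum(a[usable]), sum_total = sum(tot[usable])),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat("Weir-Cockerham F_ST:", nrow(x$per_locus), "loci, multilocus =",
      format(x$multilocus, digits = 4), "\n")
  invisible(x)
}

#' Pairwise population F_ST matrix
#'
#' Multilocus Weir-Cockerham estimates for every population pair.
#'
#' @param ds A [genotype_dataset()].
#' @return Symmetric matrix with zero diagonal, populations in the order of
#'   the population table.
#' @export
pairwise_fst <- function(ds) {
  stopifnot(inherits(ds, "genotype_dataset"))
  pops <- ds$populations$population
  n <- length(pops)
  out <- matrix(0, n, n, dimnames = list(pops, pops))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sub <- subset_dataset(ds, populations = pops[c(i, j)])
    out[i, j] <- out[j, i] <- wc_fst(sub)$multilocus
  }
  out
}
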