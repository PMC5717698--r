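#' Construct a genotype dataset
#'
#' The root object of the pipeline: a matrix of biallelic genotype codes
#' (copies of the counted allele, 0/1/2, `NA` = missing) for individuals
#' grouped into river populations, together with per-population coordinates
#' and a lineage (continent) label.
#'
#' @param genotypes Integer matrix, individuals in rows and loci in columns,
#'   values in `{0, 1, 2, NA}`. Row names are individual ids, column names
#'   locus names.
#' @param individuals Data frame with columns `individual` and `population`,
#'   one row per genotype-matrix row, in the same order.
#' @param populations Data frame with columns `population`, `latitude`
#'   (degrees N), `longitude` (degrees E) and `lineage`.
#'
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(genotypes, individuals, populations) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  individuals <- as.data.frame(individuals, stringsAsFactors = FALSE)
  populations <- as.data.frame(populations, stringsAsFactors = FALSE)

  need_ind <- c("individual", "population")
  if (!all(need_ind %in% names(individuals)))
    stop("`individuals` must have columns: ", paste(need_ind, collapse = ", "))
  need_pop <- c("population", "latitude", "longitude", "lineage")
  if (!all(need_pop %in% names(populations)))
    stop("`populations` must have columns: ", paste(need_pop, collapse = ", "))
  if (nrow(genotypes) != nrow(individuals))
    stop("genotype matrix has ", nrow(genotypes), " rows but `individuals` has ",
         nrow(individuals))
  if (is.null(colnames(genotypes)))
    colnames(genotypes) <- paste0("locus_", seq_len(ncol(genotypes)))
  if (anyDuplicated(colnames(genotypes)))
    stop("locus names must be unique")
  bad <- !(genotypes %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad))
    stop("genotype codes must be 0, 1, 2 or NA; found ",
         paste(unique(genotypes[bad]), collapse = ", "))
  missing_pop <- setdiff(individuals$population, populations$population)
  if (length(missing_pop))
    stop("individuals reference populations absent from the population table: ",
         paste(missing_pop, collapse = ", "))
  if (any(!is.finite(populations$latitude)))
    stop("population latitudes must be finite")
  rownames(genotypes) <- individuals$individual

  structure(
    list(genotypes = genotypes,
         individuals = individuals[, need_ind],
         populations = populations[, need_pop]),
    class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  n_miss <- sum(is.na(x$genotypes))
  cat("genotype_dataset:", nrow(x$genotypes), "individuals x",
      ncol(x$genotypes), "loci\n")
  cat("  populations:", nrow(x$populations),
      " lineages:", paste(unique(x$populations$lineage), collapse = ", "), "\n")
  cat(sprintf("  missing genotypes: %d (%.1f%%)\n", n_miss,
              100 * n_miss / length(x$genotypes)))
  invisible(x)
}

#' Number of loci / individuals in a dataset
#' @param ds A `genotype_dataset`.
#' @return Integer count.
#' @export
n_loci <- function(ds) ncol(ds$genotypes)

#' @rdname n_loci
#' @export
n_individuals <- function(ds) nrow(ds$genotypes)

#' Subset a genotype dataset
#'
#' @param ds A `genotype_dataset`.
#' @param loci Locus names (or indices) to keep; default all.
#' @param populations Population ids to keep; default all.
#' @param lineage Optional lineage label; keeps only populations of that
#'   lineage (applied after `populations`).
#' @return A `genotype_dataset` restricted to the requested loci/populations.
#' @export
subset_dataset <- function(ds, loci = NULL, populations = NULL, lineage = NULL) {
  stopifnot(inherits(ds, "genotype_dataset"))
  pops <- ds$populations
  if (!is.null(populations)) {
    unknown <- setdiff(populations, pops$population)
    if (length(unknown)) stop("unknown populations: ",
                              paste(unknown, collapse = ", "))
    pops <- pops[pops$population %in% populations, , drop = FALSE]
  }
  if (!is.null(lineage)) {
    pops <- pops[pops$lineage %in% lineage, , drop = FALSE]
    if (!nrow(pops)) stop("no populations with lineage ",
                          paste(lineage, collapse = "/"))
  }
  keep_ind <- ds$individuals$population %in% pops$population
  g <- ds$genotypes[keep_ind, , drop = FALSE]
  if (!is.null(loci)) {
    if (is.character(loci)) {
      unknown <- setdiff(loci, colnames(g))
      if (length(unknown)) stop("unknown loci: ", paste(unknown, collapse = ", "))
    }
    g <- g[, loci, drop = FALSE]
  }
  genotype_dataset(g, ds$individuals[keep_ind, , drop = FALSE], pops)
}

#' Per-population latitudes in a fixed order
#' @param ds A `genotype_dataset`.
#' @param populations Population order wanted; default the population table order.
#' @return Named numeric vector of latitudes.
#' @export
population_latitudes <- function(ds, populations = NULL) {
  tab <- ds$populations
  if (is.null(populations)) populations <- tab$population
  lat <- tab$latitude[match(populations, tab$population)]
  names(lat) <- populations
  lat
}
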