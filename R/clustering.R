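# North-south membership coefficients: a DAPC-style pipeline (PCA ->
# K-means groups -> LDA posteriors) on the clinal-locus genotypes, and the
# south-to-north 0-1 standardization applied to ANY coefficient source
# (DAPC, admixture Q, spatial-PCA lagged scores) so methods are comparable.

#' DAPC-style membership coefficients at K = 2
#'
#' Individual genotypes at the supplied (clinal) loci are mean-imputed,
#' centered, reduced by PCA, grouped by K-means (K = 2, multiple seeded
#' restarts, best inertia kept), and linear discriminant analysis on those
#' groups yields per-individual posterior membership probabilities. The
#' per-population coefficient is the mean individual membership of one
#' group, oriented so the coefficient correlates positively with latitude
#' (the label-switching fix).
#'
#' @param ds A [genotype_dataset()], typically already restricted to clinal
#'   loci and one lineage via [subset_dataset()].
#' @param loci Optional locus subset applied first.
#' @param n_pcs Retained principal components; default the number of
#'   components explaining 80% of variance, capped at `n_individuals / 3`.
#' @param n_start K-means restarts.
#' @param seed Integer seed for the restarts.
#' @return A data frame of class `cluster_coefficients`: `population,
#'   coefficient, standardized, method, orientation` plus attribute
#'   `n_pcs`.
#' @export
dapc_membership <- function(ds, loci = NULL, n_pcs = NULL, n_start = 20,
                            seed = 1) {
  stopifnot(inherits(ds, "genotype_dataset"))
  if (!is.null(loci)) ds <- subset_dataset(ds, loci = loci)
  if (!n_loci(ds)) stop("empty clinal locus set")
  if (nrow(ds$populations) < 2) stop("need >= 2 populations")

  g <- ds$genotypes
  mu <- colMeans(g, na.rm = TRUE)
  gm <- g
  for (j in seq_len(ncol(gm))) gm[is.na(gm[, j]), j] <- mu[j]
  gm <- scale(gm, center = TRUE, scale = FALSE)
  keep <- apply(gm, 2, stats::sd) > 0
  gm <- gm[, keep, drop = FALSE]

  pc <- stats::prcomp(gm, center = FALSE)
  if (is.null(n_pcs)) {
    cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
    n_pcs <- min(which(cum >= 0.8), floor(nrow(gm) / 3))
    n_pcs <- max(n_pcs, 1L)
  }
  if (n_pcs >= nrow(gm)) stop("n_pcs must be < number of individuals")
  scores <- pc$x[, seq_len(n_pcs), drop = FALSE]

  set.seed(as.integer(seed))
  km <- stats::kmeans(scores, centers = 2, nstart = n_start, iter.max = 50)
  post <- if (n_pcs == 1 || length(unique(km$cluster)) < 2) {
    cbind(km$cluster == 1, km$cluster == 2) + 0
  } else {
    ld <- MASS::lda(scores, grouping = factor(km$cluster))
    stats::predict(ld, as.data.frame(scores))$posterior
  }

  pop <- factor(ds$individuals$population,
                levels = ds$populations$population)
  coef_raw <- tapply(post[, 1], pop, mean)
  lat <- ds$populations$latitude
  std <- standardize_south_north(as.numeric(coef_raw), lat,
                                 populations = ds$populations$population,
                                 method = "dapc")
  attr(std, "n_pcs") <- n_pcs
  std
}

#' Standardize clustering coefficients south-to-north on [0, 1]
#'
#' Orients any per-population coefficient vector (membership probability,
#' admixture Q, spatial-PCA lagged score) so it correlates positively with
#' latitude — flipping its sign when the Pearson correlation with latitude
#' is negative — and then min-max scales it to `[0, 1]`. When the
#' correlation is exactly zero (non-constant input) the orientation is
#' chosen so the northernmost population sits at or above the mean.
#'
#' @param raw Per-population coefficient values (not all equal).
#' @param latitudes Population latitudes, same order.
#' @param populations Optional population ids.
#' @param method Source label (`"dapc"`, `"structure"`, `"spca"`, ...).
#' @return A data frame of class `cluster_coefficients`: `population,
#'   coefficient` (raw input), `standardized`, `method`, `orientation`
#'   (+1/-1 sign applied).
#' @export
standardize_south_north <- function(raw, latitudes,
                                    populations = NULL, method = "other") {
  if (length(raw) < 2) stop("need >= 2 populations")
  if (length(raw) != length(latitudes))
    stop("raw and latitudes lengths differ")
  if (stats::sd(raw) == 0)
    stop("constant coefficients: no south-north orientation defined")
  r <- stats::cor(raw, latitudes)
  orientation <- if (is.na(r) || r == 0) {
    if (raw[which.max(latitudes)] >= mean(raw)) 1 else -1
  } else if (r < 0) -1 else 1
  v <- orientation * raw
  std <- (v - min(v)) / (max(v) - min(v))
  if (is.null(populations)) populations <- paste0("pop", seq_along(raw))
  out <- data.frame(population = populations, coefficient = raw,
                    standardized = std, method = method,
                    orientation = orientation, stringsAsFactors = FALSE)
  class(out) <- c("cluster_coefficients", "data.frame")
  out
}
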