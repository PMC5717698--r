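# Fixture builders and independent oracles used across the suite.

# small in-memory dataset: genotype rows supplied per population
toy_dataset <- function(pop_genotypes, latitudes = NULL, lineage = NULL,
                        loci = NULL) {
  pops <- names(pop_genotypes)
  g <- do.call(rbind, pop_genotypes)
  if (is.null(loci)) loci <- colnames(g)
  if (is.null(loci)) loci <- paste0("L", seq_len(ncol(g)))
  colnames(g) <- loci
  n_per <- vapply(pop_genotypes, nrow, integer(1))
  individuals <- data.frame(
    individual = paste0(rep(pops, n_per), "_i", unlist(lapply(n_per, seq_len))),
    population = rep(pops, n_per), stringsAsFactors = FALSE)
  if (is.null(latitudes)) latitudes <- seq(45, 60, length.out = length(pops))
  if (is.null(lineage)) lineage <- "lin1"
  populations <- data.frame(population = pops, latitude = latitudes,
                            longitude = seq_along(pops), lineage = lineage,
                            stringsAsFactors = FALSE)
  genotype_dataset(g, individuals, populations)
}

write_toy_metadata <- function(pops, path,
                               latitudes = seq(45, 50, length.out = length(pops)),
                               lineage = "lin1") {
  write.csv(data.frame(population = pops, latitude = latitudes,
                       longitude = seq_along(pops), lineage = lineage),
            path, row.names = FALSE, quote = FALSE)
  path
}

# Independent Weir-Cockerham oracle: allele-indicator nested ANOVA route
# (mean squares among populations / among individuals / within individuals),
# algebraically distinct from the closed-form component formulas.
wc_oracle <- function(genotypes, pop) {
  ok <- !is.na(genotypes)
  pop <- factor(pop[ok]); g <- genotypes[ok]
  n <- as.numeric(table(pop))
  r <- nlevels(pop); N <- sum(n)
  # explicit allele-level data: each individual contributes 2 alleles
  a1 <- ifelse(g == 2, 1, ifelse(g == 1, 1, 0))
  a2 <- ifelse(g == 2, 1, 0)
  allele <- c(a1, a2)
  ind <- factor(rep(seq_along(g), 2))
  pop2 <- factor(rep(as.character(pop), 2))
  grand <- mean(allele)
  pop_means <- tapply(allele, pop2, mean)
  ind_means <- tapply(allele, ind, mean)
  pop_of_ind <- tapply(as.character(pop2), ind, `[`, 1)
  ss_p <- sum(2 * n * (pop_means - grand)^2)
  ss_i <- sum(2 * (ind_means - pop_means[pop_of_ind])^2)
  ss_g <- sum((allele - ind_means[ind])^2)
  ms_p <- ss_p / (r - 1)
  ms_i <- ss_i / (N - r)
  ms_g <- ss_g / N
  nc <- (N - sum(n^2) / N) / (r - 1)
  cc <- ms_g
  b <- (ms_i - ms_g) / 2
  a <- (ms_p - ms_i) / (2 * nc)
  list(a = a, b = b, c = cc, theta = a / (a + b + cc))
}

# exact hypergeometric tail by full enumeration of n-subsets of N labels
hyper_enum_tail <- function(N, K, n, k, strict = FALSE) {
  subsets <- combn(N, n)
  overlaps <- colSums(subsets <= K)     # labels 1..K form the fixed subset
  if (strict) mean(overlaps > k) else mean(overlaps >= k)
}

# Floyd-Warshall all-pairs shortest paths: independent of igraph's Dijkstra
floyd_warshall <- function(adj) {
  d <- adj
  n <- nrow(d)
  for (k in seq_len(n)) for (i in seq_len(n)) {
    relax <- d[i, k] + d[k, ]
    upd <- relax < d[i, ]
    d[i, upd] <- relax[upd]
  }
  d
}

# adjacency (edge-weight) matrix of a cost raster's water graph, built
# directly from first principles for the brute-force spatial oracle
raster_adjacency <- function(raster) {
  w <- raster$water
  nr <- nrow(w); nc <- ncol(w)
  ids <- which(w)
  pos <- arrayInd(ids, dim(w))
  n <- length(ids)
  adj <- matrix(Inf, n, n); diag(adj) <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    dr <- abs(pos[i, 1] - pos[j, 1]); dc <- abs(pos[i, 2] - pos[j, 2])
    if (dr <= 1 && dc <= 1) {
      adj[i, j] <- geosphere::distHaversine(
        c(raster$lon[pos[i, 2]], raster$lat[pos[i, 1]]),
        c(raster$lon[pos[j, 2]], raster$lat[pos[j, 1]])) / 1000
    }
  }
  list(adj = adj, pos = pos, ids = ids)
}
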