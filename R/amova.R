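# Two-level AMOVA (groups / populations within groups / within populations)
# on squared-Euclidean distances between individual genotype allele-count
# vectors. Missing genotypes are imputed by the locus mean before distances
# are formed.

amova_block_sums <- function(d2, pop) {
  pop <- as.factor(pop)
  P <- nlevels(pop)
  idx <- split(seq_along(pop), pop)
  W <- numeric(P); B <- matrix(0, P, P)
  for (p in seq_len(P)) {
    ip <- idx[[p]]
    W[p] <- sum(d2[ip, ip]) / 2
    if (p < P) for (q in (p + 1):P) {
      B[p, q] <- B[q, p] <- sum(d2[idx[[p]], idx[[q]]])
    }
  }
  list(W = W, B = B, n = lengths(idx), levels = levels(pop))
}

amova_components <- function(bs, group_of_pop) {
  n <- bs$n; P <- length(n); N <- sum(n)
  grp <- as.factor(group_of_pop)
  G <- nlevels(grp)
  gidx <- split(seq_len(P), grp)

  ss_wp <- sum(bs$W / n)
  ss_wg <- 0
  sum_np2_over_ng <- 0
  ng <- numeric(G)
  for (g in seq_len(G)) {
    ps <- gidx[[g]]
    ng[g] <- sum(n[ps])
    s <- sum(bs$W[ps])
    if (length(ps) > 1) s <- s + sum(bs$B[ps, ps]) / 2
    ss_wg <- ss_wg + s / ng[g]
    sum_np2_over_ng <- sum_np2_over_ng + sum(n[ps]^2) / ng[g]
  }
  tot_pairs <- sum(bs$W) + sum(bs$B) / 2
  ss_t <- tot_pairs / N
  ss_ag <- ss_t - ss_wg
  ss_ap <- ss_wg - ss_wp

  df_ag <- G - 1; df_ap <- P - G; df_wp <- N - P
  ms_wp <- ss_wp / df_wp
  sigma_c <- ms_wp
  n_prime <- (N - sum_np2_over_ng) / df_ap
  sigma_b <- (ss_ap / df_ap - sigma_c) / n_prime
  n_dprime <- (sum_np2_over_ng - sum(n^2) / N) / df_ag
  n_tprime <- (N - sum(ng^2) / N) / df_ag
  sigma_a <- (ss_ag / df_ag - sigma_c - n_dprime * sigma_b) / n_tprime

  tot <- sigma_a + sigma_b + sigma_c
  # degenerate strata (zero variance below a level) give 0/0: report 0
  ratio0 <- function(num, den) if (den == 0) 0 else num / den
  list(ss = c(among_groups = ss_ag, among_pops = ss_ap,
              within_pops = ss_wp, total = ss_t),
       df = c(among_groups = df_ag, among_pops = df_ap, within_pops = df_wp),
       sigma = c(among_groups = sigma_a, among_pops = sigma_b,
                 within_pops = sigma_c),
       f_ct = ratio0(sigma_a, tot),
       f_sc = ratio0(sigma_b, sigma_b + sigma_c),
       f_st = ratio0(sigma_a + sigma_b, tot))
}

#' Two-level analysis of molecular variance
#'
#' Partitions squared-Euclidean genotype distance among groups
#' (lineages/continents), among populations within groups, and within
#' populations, yielding the fixation indices F_CT, F_SC and F_ST with
#' permutation p-values: populations are permuted among groups for F_CT and
#' individuals among populations within groups for F_SC. Permutation
#' p-values use the (exceedances + 1) / (n_perm + 1) convention.
#'
#' @param ds A [genotype_dataset()].
#' @param groups Named character vector mapping population id to group
#'   label; default the lineage labels of the population table.
#' @param n_perm Permutations per test.
#' @param seed Integer seed.
#' @return A list of class `amova_result`: `ss`, `df`, `sigma` (variance
#'   components), `f_ct`, `f_sc`, `f_st`, `p_f_ct`, `p_f_sc`.
#' @export
amova_two_level <- function(ds, groups = NULL, n_perm = 999, seed = 1) {
  stopifnot(inherits(ds, "genotype_dataset"))
  if (is.null(groups))
    groups <- stats::setNames(ds$populations$lineage, ds$populations$population)
  pops <- ds$populations$population
  if (!all(pops %in% names(groups)))
    stop("groups must cover every population")
  group_of_pop <- groups[pops]
  if (length(unique(group_of_pop)) < 2) stop("need at least 2 groups")
  if (any(table(group_of_pop) == 1))
    warning("a group contains a single population; its F_SC contribution is undefined")

  g <- ds$genotypes
  mu <- colMeans(g, na.rm = TRUE)
  gi <- g
  for (j in seq_len(ncol(gi))) gi[is.na(gi[, j]), j] <- mu[j]
  d2 <- as.matrix(stats::dist(gi))^2

  pop_f <- factor(ds$individuals$population, levels = pops)
  bs <- amova_block_sums(d2, pop_f)
  obs <- amova_components(bs, group_of_pop)

  set.seed(as.integer(seed))
  # F_CT: permute populations among groups
  exceed_ct <- 0L
  for (b in seq_len(n_perm)) {
    perm <- amova_components(bs, sample(group_of_pop))
    if (perm$f_ct >= obs$f_ct) exceed_ct <- exceed_ct + 1L
  }
  # F_SC: permute individuals among populations within each group
  exceed_sc <- 0L
  ind_group <- group_of_pop[as.character(pop_f)]
  labels <- as.character(pop_f)
  for (b in seq_len(n_perm)) {
    shuffled <- labels
    for (grp in unique(ind_group)) {
      sel <- which(ind_group == grp)
      shuffled[sel] <- labels[sel][sample(length(sel))]
    }
    perm <- amova_components(amova_block_sums(d2, factor(shuffled, levels = pops)),
                             group_of_pop)
    if (perm$f_sc >= obs$f_sc) exceed_sc <- exceed_sc + 1L
  }

  structure(c(obs, list(p_f_ct = (exceed_ct + 1) / (n_perm + 1),
                        p_f_sc = (exceed_sc + 1) / (n_perm + 1),
                        n_perm = n_perm)),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("Two-level AMOVA\n")
  cat(sprintf("  F_CT = %.4f (p = %.4g)  F_SC = %.4f (p = %.4g)  F_ST = %.4f\n",
              x$f_ct, x$p_f_ct, x$f_sc, x$p_f_sc, x$f_st))
  print(data.frame(df = x$df, SS = x$ss[1:3], sigma = x$sigma))
  invisible(x)
}
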