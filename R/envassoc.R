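# Environmental association: collinearity pruning by variance inflation
# factor, and redundancy analysis of clinal-locus allele frequencies on
# climate predictors with permutation tests (vegan's constrained
# ordination engine behind the surface).

#' Iteratively prune predictors by variance inflation factor
#'
#' `VIF_k = 1 / (1 - R^2_k)` from regressing predictor k on all the
#' others. The largest-VIF predictor is dropped (exactly collinear columns
#' have infinite VIF and go first; among ties the later column is dropped,
#' so the earlier of two duplicates survives) and VIFs are recomputed until
#' all fall below `threshold`.
#'
#' @param X Data frame or matrix of >= 2 numeric predictors.
#' @param threshold VIF ceiling (default 5).
#' @return A list of class `vif_report`: `vif_initial`, `vif_final`,
#'   `dropped` (in drop order), `retained`, `threshold`.
#' @export
vif_prune <- function(X, threshold = 5) {
  X <- as.data.frame(X)
  if (ncol(X) < 2) stop("need >= 2 predictors")
  if (nrow(X) < ncol(X) + 2)
    stop("need at least #predictors + 2 rows")
  compute_vifs <- function(df) {
    vapply(seq_len(ncol(df)), function(k) {
      fit <- stats::lm(df[[k]] ~ ., data = df[, -k, drop = FALSE])
      r2 <- suppressWarnings(summary(fit)$r.squared)   # perfect fits warn
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
  }
  vif_initial <- stats::setNames(compute_vifs(X), names(X))
  dropped <- character(0)
  cur <- X
  while (ncol(cur) >= 2) {
    v <- compute_vifs(cur)
    if (all(v < threshold)) break
    worst <- max(which(v == max(v)))   # ties: drop the later column
    dropped <- c(dropped, names(cur)[worst])
    cur <- cur[, -worst, drop = FALSE]
  }
  vif_final <- if (ncol(cur) >= 2)
    stats::setNames(compute_vifs(cur), names(cur))
  else stats::setNames(rep(1, ncol(cur)), names(cur))
  structure(list(vif_initial = vif_initial, vif_final = vif_final,
                 dropped = dropped, retained = names(cur),
                 threshold = threshold),
            class = "vif_report")
}

#' @export
print.vif_report <- function(x, ...) {
  cat("vif_prune: retained", length(x$retained), "predictors (threshold",
      x$threshold, ")\n")
  if (length(x$dropped)) cat("  dropped:", paste(x$dropped, collapse = " > "), "\n")
  print(round(x$vif_final, 2))
  invisible(x)
}

#' Redundancy analysis of clinal allele frequencies on environment
#'
#' Constrained ordination: the population x clinal-locus frequency matrix
#' is the multivariate response, climate covariates the predictors, with
#' optional conditioning covariates (e.g. latitude and longitude)
#' partialled out first. Global significance by permutation of (reduced-
#' model) response rows; per-term marginal (type-III) tests each predictor
#' given all others. Fitted with `vegan::rda` / `anova.cca`.
#'
#' @param Y Numeric matrix/data frame, populations x loci (allele
#'   frequencies). Rows must align with `X`.
#' @param X Data frame of predictors.
#' @param condition Optional data frame of conditioning covariates.
#' @param n_perm Permutations for the global and marginal tests.
#' @param seed Integer seed.
#' @return A list of class `rda_result`: `total_variance`,
#'   `constrained_variance`, `proportion_explained`, `global_f`,
#'   `global_p`, `terms` (data frame `term,f,p`), `model` (the vegan fit).
#' @export
rda_assoc <- function(Y, X, condition = NULL, n_perm = 1000, seed = 1) {
  Y <- as.matrix(Y)
  X <- as.data.frame(X)
  if (nrow(Y) != nrow(X)) stop("Y and X row counts differ")
  dat <- X
  rhs <- paste(names(X), collapse = " + ")
  if (!is.null(condition)) {
    condition <- as.data.frame(condition)
    if (nrow(condition) != nrow(Y)) stop("condition rows differ from Y")
    dat <- cbind(X, condition)
    rhs <- paste0(rhs, " + Condition(",
                  paste(names(condition), collapse = " + "), ")")
  }
  n_min <- ncol(X) + if (is.null(condition)) 0 else ncol(condition)
  if (nrow(Y) <= n_min + 1) stop("too few rows for the requested model")

  mod <- vegan::rda(stats::as.formula(paste("Y ~", rhs)), data = dat)
  qrank <- if (is.null(mod$CCA)) 0 else mod$CCA$qrank
  tot <- mod$tot.chi
  con <- if (is.null(mod$CCA)) 0 else mod$CCA$tot.chi
  resid_var <- if (is.null(mod$CA)) 0 else mod$CA$tot.chi

  if (qrank == 0) {
    # predictors fully absorbed by the conditioning covariates: nothing
    # left to test, constrained variance ~ 0
    return(structure(list(total_variance = tot, constrained_variance = con,
                          proportion_explained = con / tot,
                          global_f = 0, global_p = 1,
                          terms = data.frame(), n_perm = n_perm, model = mod),
                     class = "rda_result"))
  }
  if (qrank < ncol(X))
    stop("rank-deficient predictors after conditioning: only ", qrank,
         " independent directions among ", paste(names(X), collapse = ", "))

  if (resid_var < 1e-12 * tot) {
    # perfect fit: the observed pseudo-F is unbounded, so no permutation
    # can exceed it and the p-value takes its minimal attainable value
    return(structure(list(total_variance = tot, constrained_variance = con,
                          proportion_explained = con / tot,
                          global_f = Inf, global_p = 1 / (n_perm + 1),
                          terms = data.frame(), n_perm = n_perm, model = mod),
                     class = "rda_result"))
  }

  set.seed(as.integer(seed))
  global <- vegan::anova.cca(mod, permutations = n_perm)
  set.seed(as.integer(seed) + 1L)
  marginal <- tryCatch(
    vegan::anova.cca(mod, by = "margin", permutations = n_perm),
    error = function(e) NULL)
  terms <- if (is.null(marginal)) data.frame() else
    data.frame(term = rownames(marginal)[seq_len(nrow(marginal) - 1)],
               f = marginal$F[seq_len(nrow(marginal) - 1)],
               p = marginal$`Pr(>F)`[seq_len(nrow(marginal) - 1)],
               stringsAsFactors = FALSE)
  structure(list(total_variance = tot,
                 constrained_variance = con,
                 proportion_explained = con / tot,
                 global_f = global$F[1],
                 global_p = global$`Pr(>F)`[1],
                 terms = terms, n_perm = n_perm, model = mod),
            class = "rda_result")
}

#' @export
print.rda_result <- function(x, ...) {
  cat(sprintf(
    "RDA: %.1f%% of variance constrained; global F = %.3f, p = %.4g (%d perms)\n",
    100 * x$proportion_explained, x$global_f, x$global_p, x$n_perm))
  if (nrow(x$terms)) {
    cat("  marginal (type-III) terms:\n")
    print(x$terms, row.names = FALSE)
  }
  invisible(x)
}
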