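# One-config orchestration of the full analysis: simulate (or read) ->
# filter -> summary stats -> per-lineage clines -> cross-lineage overlap ->
# clustering -> coefficient models -> spatial distances -> environmental
# association. Every artifact is a CSV/JSON file listed (with checksum) in
# the returned manifest; a failed stage aborts with its name.

#' Validate a pipeline configuration
#'
#' A config is a named list (or path to a YAML file): either a `simulate`
#' block (arguments to [synth_config()]) or an `input` block
#' (`genepop`/`genotype_csv`, `metadata`, optional `environment` CSV
#' paths); an `output_dir`; a global `seed`; optional `stages` (default
#' all feasible) and per-stage parameter blocks `filter`, `clines`,
#' `overlap`, `cluster`, `model`, `spatial`, `envassoc`.
#'
#' @param config Named list or YAML path.
#' @return The validated config list (with defaults filled).
#' @export
validate_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config validation error: config must be a list")
  if (is.null(config$output_dir))
    stop("config validation error: output_dir missing")
  if (is.null(config$simulate) && is.null(config$input))
    stop("config validation error: need a `simulate` or `input` block")
  config$seed <- as.integer(config$seed %||% 1L)
  all_stages <- c("filter", "stats", "clines", "overlap", "cluster",
                  "model", "spatial", "envassoc")
  config$stages <- config$stages %||% all_stages
  bad <- setdiff(config$stages, all_stages)
  if (length(bad))
    stop("config validation error: unknown stages ", paste(bad, collapse = ", "))
  if ("envassoc" %in% config$stages && is.null(config$simulate) &&
      is.null(config$input$environment))
    stop("config validation error: stage `envassoc` requested but no ",
         "`input$environment` table provided")
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the cline-analysis pipeline from one configuration
#'
#' Executes the stages in dependency order, writing each stage's artifact
#' under `output_dir` and logging parameters, seeds and sizes. Lineages are
#' analysed independently throughout; the only cross-lineage stage is the
#' clinal-overlap test. Reruns with an identical config give
#' checksum-identical artifacts.
#'
#' @param config See [validate_pipeline_config()].
#' @param quiet Suppress log lines.
#' @return A data frame manifest (`stage, path, md5`), invisibly also
#'   carrying the stage results in attribute `results`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  config <- validate_pipeline_config(config)
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_file <- file.path(out_dir, "run.log")
  cat("", file = log_file)
  say <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
    cat(msg, "\n", file = log_file, append = TRUE)
    if (!quiet) message(msg)
  }
  manifest <- data.frame(stage = character(0), path = character(0),
                         md5 = character(0), stringsAsFactors = FALSE)
  results <- list()
  emit <- function(stage, name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    manifest[nrow(manifest) + 1L, ] <<- c(stage, path,
                                          unname(tools::md5sum(path)))
  }

  # -- inputs ----------------------------------------------------------
  truth <- NULL; env <- NULL
  if (!is.null(config$simulate)) {
    sc <- do.call(synth_config,
                  c(config$simulate, list(seed = config$seed)))
    sim <- simulate_dataset(sc)
    ds <- sim$dataset; env <- sim$environment; truth <- sim$truth
    say("simulate: %d individuals x %d loci, seed %d",
        n_individuals(ds), n_loci(ds), config$seed)
    emit("simulate", "simulated_genotypes.csv",
         function(p) write_genotype_csv(ds, p))
    emit("simulate", "populations.csv", function(p)
      utils::write.csv(ds$populations, p, row.names = FALSE, quote = FALSE))
    emit("simulate", "environment.csv", function(p)
      utils::write.csv(env, p, row.names = FALSE, quote = FALSE))
    emit("simulate", "truth.json", function(p)
      jsonlite::write_json(list(shared_clinal = truth$shared_clinal,
                                clinal = truth$clinal),
                           p, auto_unbox = TRUE, pretty = TRUE))
  } else {
    inp <- config$input
    ds <- if (!is.null(inp$genepop))
      read_genepop(inp$genepop, inp$metadata)
    else read_genotype_csv(inp$genotype_csv, inp$metadata)
    if (!is.null(inp$environment))
      env <- utils::read.csv(inp$environment, stringsAsFactors = FALSE)
    say("input: %d individuals x %d loci", n_individuals(ds), n_loci(ds))
  }
  lineages <- unique(ds$populations$lineage)

  # -- filter ----------------------------------------------------------
  if ("filter" %in% config$stages) {
    fp <- config$filter %||% list()
    flt <- filter_loci(ds, maf_min = fp$maf_min %||% 0.01,
                       max_missing = fp$max_missing %||% 0.15)
    ds <- flt$dataset
    say("filter: %d loci retained, %d removed", n_loci(ds), nrow(flt$removed))
    emit("filter", "removed_loci.csv", function(p)
      utils::write.csv(flt$removed, p, row.names = FALSE, quote = FALSE))
    results$filter <- flt
  }

  freqs <- allele_frequencies(ds)

  # -- stats -----------------------------------------------------------
  if ("stats" %in% config$stages) {
    fst <- wc_fst(ds)
    ho <- observed_heterozygosity(ds, by = "lineage")
    say("stats: multilocus F_ST = %.4f; mean Ho %s", fst$multilocus,
        paste(sprintf("%s = %.3f", names(ho$mean_ho), ho$mean_ho),
              collapse = ", "))
    per_locus <- data.frame(locus = fst$per_locus$locus,
                            fst = fst$per_locus$theta,
                            ho = colMeans(ho$ho, na.rm = TRUE))
    emit("stats", "locus_stats.csv", function(p)
      utils::write.csv(per_locus, p, row.names = FALSE, quote = FALSE))
    results$stats <- list(fst = fst, ho = ho)
    if (length(lineages) >= 2) {
      am <- amova_two_level(ds, n_perm = config$stats$n_perm %||% 99,
                            seed = config$seed + 11L)
      say("stats: AMOVA F_CT = %.3f (p = %.3g), F_SC = %.3f", am$f_ct,
          am$p_f_ct, am$f_sc)
      results$stats$amova <- am
    }
  }

  # -- clines per lineage ---------------------------------------------
  clinal <- list()
  if ("clines" %in% config$stages) {
    cp <- config$clines %||% list()
    thr <- cp$threshold %||% 0.40
    for (lin in lineages) {
      fits <- fit_clines(freqs, lineage = lin)
      cs <- classify_clinal(fits, threshold = thr)
      scan <- threshold_scan(fits, cp$scan_grid %||% seq(0, 0.95, 0.05))
      clinal[[lin]] <- cs
      say("clines[%s]: %d of %d loci clinal (threshold %.2f, knee %.2f)",
          lin, length(cs$loci), nrow(fits), thr, scan$knee)
      fits$clinal <- fits$locus %in% cs$loci
      emit("clines", paste0("clines_", lin, ".csv"), function(p)
        utils::write.csv(fits, p, row.names = FALSE, quote = FALSE))
      emit("clines", paste0("threshold_scan_", lin, ".csv"), function(p)
        utils::write.csv(scan$table, p, row.names = FALSE, quote = FALSE))
    }
    results$clines <- clinal
  }

  # -- overlap ---------------------------------------------------------
  if ("overlap" %in% config$stages && length(clinal) >= 2) {
    k_obs <- length(intersect(clinal[[1]]$loci, clinal[[2]]$loci))
    ov <- overlap_permutation(N = n_loci(ds),
                              n1 = length(clinal[[1]]$loci),
                              n2 = length(clinal[[2]]$loci),
                              k_obs = k_obs,
                              iters = config$overlap$iters %||% 100000L,
                              seed = config$seed + 23L)
    say("overlap: %d shared clinal loci, strict tail %.4f (exact %.4f)",
        k_obs, ov$p_perm_strict, ov$p_exact_strict)
    emit("overlap", "overlap.json", function(p)
      jsonlite::write_json(unclass(ov), p, auto_unbox = TRUE, pretty = TRUE))
    results$overlap <- ov
  }

  # -- clustering + models per lineage --------------------------------
  if ("cluster" %in% config$stages && length(clinal)) {
    coefs <- list()
    for (lin in lineages) {
      if (!length(clinal[[lin]]$loci)) { say("cluster[%s]: no clinal loci, skipped", lin); next }
      sub <- subset_dataset(ds, loci = clinal[[lin]]$loci, lineage = lin)
      cc <- dapc_membership(sub, seed = config$seed + 31L)
      coefs[[lin]] <- cc
      say("cluster[%s]: %d populations, %d PCs", lin, nrow(cc),
          attr(cc, "n_pcs"))
      emit("cluster", paste0("coefficients_", lin, ".csv"), function(p)
        utils::write.csv(cc, p, row.names = FALSE, quote = FALSE))
    }
    results$cluster <- coefs

    if ("model" %in% config$stages && length(coefs)) {
      for (lin in names(coefs)) {
        pops <- coefs[[lin]]$population
        meta <- ds$populations[match(pops, ds$populations$population), ]
        preds <- data.frame(latitude = meta$latitude)
        if (!is.null(env))
          preds <- cbind(preds,
                         env[match(pops, env$population),
                             setdiff(names(env), "population"), drop = FALSE])
        tab <- compare_predictors(coefs[[lin]]$standardized, preds)
        say("model[%s]: best predictor %s (AIC %.2f, r2 %.3f)", lin,
            tab$predictor[1], tab$aic[1], tab$mcfadden_r2[1])
        emit("model", paste0("models_", lin, ".csv"), function(p)
          utils::write.csv(tab, p, row.names = FALSE, quote = FALSE))
        results$model[[lin]] <- tab
      }
    }
  }

  # -- spatial ---------------------------------------------------------
  dists <- list()
  if ("spatial" %in% config$stages) {
    for (lin in lineages) {
      meta <- ds$populations[ds$populations$lineage == lin, ]
      dm <- if (!is.null(config$spatial$raster)) {
        least_cost_distances(meta, read_ascii_grid(config$spatial$raster),
                             snap_radius = config$spatial$snap_radius %||% 3)
      } else {
        m <- geosphere::distm(meta[, c("longitude", "latitude")]) / 1000
        dimnames(m) <- list(meta$population, meta$population)
        m
      }
      dists[[lin]] <- dm
      nm <- nmds_project(dm, seed = config$seed + 41L)
      say("spatial[%s]: %d populations, NMDS stress %.4f", lin, nrow(dm),
          nm$stress)
      emit("spatial", paste0("distances_", lin, ".csv"), function(p)
        utils::write.csv(round(dm, 6), p, quote = FALSE))
      results$spatial[[lin]] <- list(distances = dm, embedding = nm)
    }
  }

  # -- environmental association --------------------------------------
  if ("envassoc" %in% config$stages && !is.null(env) && length(clinal)) {
    np <- config$envassoc$n_perm %||% 999
    for (lin in lineages) {
      if (!length(clinal[[lin]]$loci)) next
      meta <- ds$populations[ds$populations$lineage == lin, ]
      pops <- meta$population
      Xe <- env[match(pops, env$population),
                setdiff(names(env), "population"), drop = FALSE]
      vr <- vif_prune(Xe, threshold = config$envassoc$vif_threshold %||% 5)
      sub_f <- allele_frequencies(subset_dataset(ds, loci = clinal[[lin]]$loci,
                                                 lineage = lin))
      Y <- sub_f$p[match(pops, rownames(sub_f$p)), , drop = FALSE]
      Y[is.na(Y)] <- matrix(colMeans(Y, na.rm = TRUE), nrow(Y), ncol(Y),
                            byrow = TRUE)[is.na(Y)]
      rd <- rda_assoc(Y, Xe[, vr$retained, drop = FALSE],
                      condition = meta[, c("latitude", "longitude")],
                      n_perm = np, seed = config$seed + 53L)
      say("envassoc[%s]: RDA global F = %.2f, p = %.4g; retained %s", lin,
          rd$global_f, rd$global_p, paste(vr$retained, collapse = ","))
      results$envassoc[[lin]] <- list(vif = vr, rda = rd)
      emit("envassoc", paste0("envassoc_", lin, ".json"), function(p)
        jsonlite::write_json(
          list(vif_retained = vr$retained, vif_dropped = vr$dropped,
               rda = list(proportion_explained = rd$proportion_explained,
                          global_f = rd$global_f, global_p = rd$global_p,
                          terms = rd$terms)),
          p, auto_unbox = TRUE, pretty = TRUE, digits = NA))
      if (length(dists)) {
        fst_m <- pairwise_fst(subset_dataset(ds, loci = clinal[[lin]]$loci,
                                             lineage = lin))
        env_d <- as.matrix(stats::dist(scale(Xe[, vr$retained, drop = FALSE])))
        pm <- partial_mantel(fst_m, env_d, dists[[lin]], n_perm = np,
                             seed = config$seed + 61L)
        say("envassoc[%s]: partial Mantel r = %.3f, p = %.4g", lin, pm$r, pm$p)
        results$envassoc[[lin]]$partial_mantel <- pm
      }
    }
  }

  emit("manifest", "manifest.csv", function(p)
    utils::write.csv(manifest, p, row.names = FALSE, quote = FALSE))
  say("pipeline complete: %d artifacts", nrow(manifest))
  attr(manifest, "results") <- results
  attr(manifest, "truth") <- truth
  invisible(manifest)
}
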