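# End-to-end orchestration: generate -> build -> metrics -> delta-nulls ->
# connectivity / scale-of-effect -> community -> regression, with a run
# manifest for reproducibility.

PIPELINE_STAGES <- c("synthesize", "networks", "metrics", "null_models",
                     "connectivity_scale", "community", "regression")

#' Run the full synthetic-study analysis pipeline
#'
#' Executes the seven pipeline stages on a synthetic study generated from
#' `config`, with every stochastic stage seeded deterministically from the
#' master seed (fixed per-stage offsets, so stages can be reproduced in
#' isolation). Any stage failure aborts with the stage name; the partial
#' manifest is attached to the error condition.
#'
#' @param config a [syntheticConfig()].
#' @param seed master seed (default: the config's).
#' @param nNull,nNullModularity Patefield draws per metric for the
#'   delta-transformation (study-design defaults 1000 and 100).
#' @param nPerm permutations for the environmental vector fits (default
#'   99999).
#' @param saParams annealing settings for observed-network modularity.
#' @param outDir optional directory; when given, the main tables are
#'   written there as TSV plus a plain-text manifest.
#' @return list with `manifest`, the generated `records` and `siteData`,
#'   the per-site `networks` (both resolutions), `metrics`, `deltas`,
#'   `connectivity`, `scaleTable`, `community` (dissimilarity, ordination
#'   coordinates, vector fits), `models`, `deltaTests` and
#'   `resolutionTests`.
#' @export
runPipeline <- function(config = syntheticConfig(), seed = config$seed,
                        nNull = 1000L, nNullModularity = 100L,
                        nPerm = 99999L, saParams = saParameters(),
                        outDir = NULL) {
  manifest <- list(configHash = fnv1a32(config), masterSeed = as.integer(seed),
                   stages = PIPELINE_STAGES,
                   stageSeeds = setNames(seed + 1000L * seq_along(PIPELINE_STAGES),
                                         PIPELINE_STAGES),
                   timings = setNames(rep(NA_real_, length(PIPELINE_STAGES)),
                                      PIPELINE_STAGES),
                   version = as.character(utils::packageVersion("pollinet")))
  out <- list()
  runStage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      cond <- simpleError(sprintf("pipeline stage '%s' failed: %s", name,
                                  conditionMessage(e)))
      attr(cond, "manifest") <- manifest
      stop(cond)
    })
    manifest$timings[[name]] <<- proc.time()[["elapsed"]] - t0
    res
  }
  seeds <- manifest$stageSeeds

  study <- runStage("synthesize", generateStudy(config, seed = seeds[["synthesize"]]))
  records <- study$records
  siteData <- study$siteData

  networks <- runStage("networks", {
    sites <- sort(unique(records$site_id))
    nets <- lapply(sites, function(s) {
      sp <- buildNetwork(records, s)
      list(species = sp, genus = aggregateToGenus(sp))
    })
    setNames(nets, sites)
  })

  metrics <- runStage("metrics", {
    rows <- lapply(seq_along(networks), function(i) {
      rbind(networkMetrics(networks[[i]]$species, saParams = saParams,
                           seed = seeds[["metrics"]] + i),
            networkMetrics(networks[[i]]$genus, saParams = saParams,
                           seed = seeds[["metrics"]] + i))
    })
    do.call(rbind, rows)
  })

  deltas <- runStage("null_models", {
    rows <- lapply(seq_along(networks), function(i) {
      rbind(deltaTransform(networks[[i]]$species, nNull = nNull,
                           nNullModularity = nNullModularity,
                           seed = seeds[["null_models"]] + 131L * i,
                           saParams = saParams),
            deltaTransform(networks[[i]]$genus, nNull = nNull,
                           nNullModularity = nNullModularity,
                           seed = seeds[["null_models"]] + 131L * i + 57L,
                           saParams = saParams))
    })
    do.call(rbind, rows)
  })

  connScale <- runStage("connectivity_scale", {
    conn <- siteConnectivity(study$landscape)
    siteData$connectivity_3d <- as.numeric(conn[siteData$site_id])
    impCols <- c("imperv_100", "imperv_500", "imperv_1000")
    responses <- list(
      bee_richness      = siteCommunitySummary(records, "wild_bee")$richness,
      butterfly_richness = siteCommunitySummary(records, "butterfly")$richness,
      hoverfly_visits   = siteCommunitySummary(records, "hoverfly")$visits,
      honeybee_visits   = siteData$honeybee_visits,
      total_visits      = siteCommunitySummary(records, "all")$visits)
    st <- lapply(names(responses), function(rn) {
      sel <- selectScale(responses[[rn]], siteData[impCols])
      data.frame(response = rn, selected_radius = sel$radius,
                 r_100 = sel$correlations[["imperv_100"]],
                 r_500 = sel$correlations[["imperv_500"]],
                 r_1000 = sel$correlations[["imperv_1000"]],
                 stringsAsFactors = FALSE)
    })
    list(connectivity = conn, scaleTable = do.call(rbind, st),
         responses = responses, siteData = siteData)
  })
  siteData <- connScale$siteData

  community <- runStage("community", {
    filtered <- filterMinVisits(records, 3)
    comm <- communityMatrix(filtered)
    dis <- brayCurtisPrepared(comm)
    coords <- stats::cmdscale(as.dist(dis), k = 2)
    envVars <- c("imperv_500", "connectivity_3d", "bare_soil")
    fits <- lapply(seq_along(envVars), function(i) {
      v <- envVars[i]
      ef <- envfitPermutation(coords, siteData[[v]][match(rownames(coords),
                                                          siteData$site_id)],
                              nPerm = nPerm,
                              seed = seeds[["community"]] + i)
      data.frame(variable = v, r2 = ef$r2, p = ef$p, stringsAsFactors = FALSE)
    })
    list(dissimilarity = dis, coords = coords, envfit = do.call(rbind, fits))
  })

  regressionOut <- runStage("regression", {
    st <- connScale$scaleTable
    impFor <- function(rn) {
      paste0("imperv_", st$selected_radius[st$response == rn])
    }
    candidates <- function(rn, honeybeeResponse = FALSE) {
      cols <- if (honeybeeResponse) c(impFor(rn), "connectivity_3d")
        else c(impFor(rn), "connectivity_3d", "log_patch_size",
               "flowering_plant_richness", "veg_height", "bare_soil",
               "honeybee_visits")
      siteData[unique(cols)]
    }
    coords <- as.matrix(siteData[c("x", "y")])
    fitOne <- function(rn, y, honeybeeResponse = FALSE) {
      X <- candidates(rn, honeybeeResponse)
      # collinearity drops and fit diagnostics are logged per model rather
      # than surfaced as loose warnings (expected at n of order 10)
      log <- character(0)
      keep <- function(expr) withCallingHandlers(expr, warning = function(w) {
        log <<- c(log, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
      scr <- keep(vifScreen(X, cutoff = 3))
      sel <- keep(subsetSelectAic(y, X[scr$retained], maxTerms = 3))
      mi <- moransI(residuals(sel$best$fit), coords)
      list(response = rn, vif = scr, selection = sel, morans_i = mi,
           log = log)
    }
    resp <- connScale$responses
    models <- list(
      bee_richness = fitOne("bee_richness", resp$bee_richness),
      butterfly_richness = fitOne("butterfly_richness", resp$butterfly_richness),
      hoverfly_visits = fitOne("hoverfly_visits", resp$hoverfly_visits),
      honeybee_visits = fitOne("honeybee_visits",
                               round(resp$honeybee_visits),
                               honeybeeResponse = TRUE))
    deltaTests <- lapply(split(deltas, list(deltas$metric, deltas$resolution)),
                         function(d) {
                           res <- tryCatch(deltaMeta(d$delta),
                                           error = function(e) NULL)
                           if (is.null(res)) return(NULL)
                           data.frame(metric = d$metric[1],
                                      resolution = d$resolution[1],
                                      mean_delta = res$mean, t = res$t,
                                      p = res$p, stringsAsFactors = FALSE)
                         })
    deltaTests <- do.call(rbind, deltaTests[!vapply(deltaTests, is.null,
                                                    logical(1))])
    resTests <- lapply(unique(deltas$metric), function(met) {
      sp <- deltas[deltas$metric == met & deltas$resolution == "species", ]
      ge <- deltas[deltas$metric == met & deltas$resolution == "genus", ]
      ord <- match(sp$site_id, ge$site_id)
      rc <- tryCatch(resolutionCompare(sp$delta, ge$delta[ord]),
                     error = function(e) NULL)
      if (is.null(rc)) return(NULL)
      data.frame(metric = met, r = rc$r, r_p = rc$r_p, t = rc$t,
                 t_p = rc$t_p, stringsAsFactors = FALSE)
    })
    resTests <- do.call(rbind, resTests[!vapply(resTests, is.null, logical(1))])
    list(models = models, deltaTests = deltaTests, resolutionTests = resTests)
  })

  result <- list(manifest = manifest, records = records, siteData = siteData,
                 networks = networks, metrics = metrics, deltas = deltas,
                 connectivity = connScale$connectivity,
                 scaleTable = connScale$scaleTable, community = community,
                 models = regressionOut$models,
                 deltaTests = regressionOut$deltaTests,
                 resolutionTests = regressionOut$resolutionTests)
  if (!is.null(outDir)) writePipelineOutputs(result, outDir)
  result
}

writePipelineOutputs <- function(result, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeInteractionRecords(result$records, file.path(outDir, "records.tsv"))
  write.table(result$siteData, file.path(outDir, "site_data.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(result$metrics, file.path(outDir, "network_metrics.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(result$deltas, file.path(outDir, "delta_metrics.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(result$scaleTable, file.path(outDir, "scale_selection.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  mf <- result$manifest
  lines <- c(sprintf("config_hash\t%s", mf$configHash),
             sprintf("master_seed\t%d", mf$masterSeed),
             sprintf("version\t%s", mf$version),
             sprintf("stage_seed_%s\t%d", names(mf$stageSeeds), mf$stageSeeds),
             sprintf("stage_time_%s\t%.3f", names(mf$timings),
                     unlist(mf$timings)))
  writeLines(lines, file.path(outDir, "manifest.tsv"))
  invisible(outDir)
}

#' Tally interactions and species by pollinator group
#'
#' Totals and integer percentage shares (commercial rounding, half away
#' from zero) of interactions and of visitor species per pollinator group,
#' plus the number of plant species — the headline figures of a visitation
#' survey.
#'
#' @param records interaction records.
#' @return list with `interactions` and `species` data.frames (group,
#'   total, share_pct), `n_plant_species`, `total_interactions` and
#'   `total_visitor_species`.
#' @export
tallyReport <- function(records) {
  validateRecords(records)
  groups <- POLLINATOR_GROUPS
  visits <- vapply(groups, function(g) {
    sum(records$count[records$visitor_group == g])
  }, numeric(1))
  nspec <- vapply(groups, function(g) {
    length(unique(records$visitor_species[records$visitor_group == g]))
  }, numeric(1))
  list(
    interactions = data.frame(
      group = groups, total = visits,
      share_pct = roundHalfUp(100 * visits / sum(visits)),
      stringsAsFactors = FALSE),
    species = data.frame(
      group = groups, total = nspec,
      share_pct = roundHalfUp(100 * nspec / sum(nspec)),
      stringsAsFactors = FALSE),
    n_plant_species = length(unique(records$plant_species)),
    total_interactions = sum(visits),
    total_visitor_species = sum(nspec))
}
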