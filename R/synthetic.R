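#' Configuration of the synthetic study-design generator
#'
#' Parameterises a synthetic urban dry-grassland visitation study: a set of
#' grassland patches on an urbanisation gradient, species pools for wild
#' bees, hoverflies, butterflies and flowering plants (plus the managed
#' honey bee), and group-specific responses to the landscape. Defaults
#' emulate the design the package targets: 11 sites, pools of 105 bee, 38
#' hoverfly and 22 butterfly species, 8 sampling rounds, wild bee and
#' butterfly richness declining with impervious surface (at the 500 m and
#' 100 m radii respectively), hoverflies unresponsive, and honey-bee visits
#' and flower abundance increasing with urbanisation.
#'
#' @param nSites number of grassland patches.
#' @param seed master seed; all generator functions derive their streams
#'   from it.
#' @param imperviousRange range (%) spanned by the urbanisation gradient.
#' @param crossScaleCorr target pairwise Pearson correlation of the
#'   impervious percentages across the 100/500/1000 m radii, in \[0, 1\].
#' @param patchSizeRange patch area range in square metres.
#' @param nBuildingsPerSite expected buildings in a site's neighbourhood at
#'   average urbanisation (the realised count scales with local impervious
#'   cover).
#' @param heightRange building height range (m).
#' @param poolSizes named counts: `bees`, `hoverflies`, `butterflies`,
#'   `plants`.
#' @param effectSizes named log-scale slopes per percentage point of
#'   impervious surface (richness of bees at 500 m, butterflies at 100 m,
#'   honey-bee visits at 100 m, flower abundance at 500 m) and per cm of
#'   vegetation height (visit rates of hoverflies and butterflies).
#' @param specialisationStrength non-negative rate at which plant-visitor
#'   pairing probability decays with latent trait distance; 0 gives fully
#'   exchangeable (generalised) visitation, large values near-one-to-one
#'   specialisation.
#' @param samplingRounds transect rounds pooled per site.
#' @param countFamily `"nbinom"` (default; ecological counts are
#'   overdispersed) or `"poisson"` for per-visitor visit totals.
#' @param dispersion negative-binomial size parameter.
#' @param baselines expected values at the gradient midpoint: per-site
#'   richness by group, plant richness, honey-bee visits per site, and the
#'   group-specific mean visit totals per present visitor species (the
#'   group rate multipliers; the defaults weight wild bees as the dominant
#'   visitor group, with hoverflies and butterflies minor and the honey bee
#'   a high-volume single species).
#' @param bareSoilCorr correlation between bare-soil cover and impervious
#'   surface (urban dry grasslands on sealed surroundings tend to be
#'   sparsely vegetated); high by default so the collinearity screen has a
#'   realistic casualty.
#' @param extent side (m) of the square study region.
#' @return validated config list of class `"syntheticConfig"`.
#' @export
syntheticConfig <- function(nSites = 11L,
                            seed = 1L,
                            imperviousRange = c(5, 75),
                            crossScaleCorr = 0.8,
                            patchSizeRange = c(2e3, 1.5e5),
                            nBuildingsPerSite = 40L,
                            heightRange = c(4, 30),
                            poolSizes = c(bees = 105L, hoverflies = 38L,
                                          butterflies = 22L, plants = 70L),
                            effectSizes = c(
                              bee_richness_vs_impervious     = -0.012,
                              butterfly_vs_impervious        = -0.020,
                              hoverfly_vs_impervious         = 0,
                              honeybee_vs_impervious         = 0.020,
                              flower_abundance_vs_impervious = 0.010,
                              visits_vs_vegheight            = 0.010),
                            specialisationStrength = 4,
                            samplingRounds = 8L,
                            countFamily = c("nbinom", "poisson"),
                            dispersion = 2,
                            baselines = c(bee_richness = 30,
                                          hoverfly_richness = 12,
                                          butterfly_richness = 9,
                                          plant_richness = 18,
                                          honeybee_visits = 40,
                                          bee_visit_rate = 3.4,
                                          hoverfly_visit_rate = 2,
                                          butterfly_visit_rate = 2),
                            bareSoilCorr = 0.92,
                            extent = 10000) {
  countFamily <- match.arg(countFamily)
  stopifnot(
    nSites >= 1, length(imperviousRange) == 2,
    diff(imperviousRange) > 0, imperviousRange[1] >= 0,
    imperviousRange[2] <= 100,
    crossScaleCorr >= 0, crossScaleCorr <= 1,
    diff(patchSizeRange) > 0, patchSizeRange[1] > 0,
    diff(heightRange) > 0, heightRange[1] >= 0,
    all(poolSizes >= 1),
    all(c("bees", "hoverflies", "butterflies", "plants") %in% names(poolSizes)),
    specialisationStrength >= 0, samplingRounds >= 1, dispersion > 0
  )
  structure(list(
    nSites = as.integer(nSites), seed = as.integer(seed),
    imperviousRange = imperviousRange, crossScaleCorr = crossScaleCorr,
    patchSizeRange = patchSizeRange,
    nBuildingsPerSite = as.integer(nBuildingsPerSite),
    heightRange = heightRange, poolSizes = poolSizes,
    effectSizes = effectSizes,
    specialisationStrength = specialisationStrength,
    samplingRounds = as.integer(samplingRounds),
    countFamily = countFamily, dispersion = dispersion,
    baselines = baselines, bareSoilCorr = bareSoilCorr, extent = extent),
    class = "syntheticConfig")
}

# map a latent standard-normal vector into [lo, hi] linearly (min-max);
# linear, so Pearson correlations among latents are preserved exactly
.minmaxMap <- function(z, lo, hi) {
  if (max(z) - min(z) < 1e-12) return(rep((lo + hi) / 2, length(z)))
  lo + (z - min(z)) / (max(z) - min(z)) * (hi - lo)
}

#' Generate a synthetic landscape
#'
#' Places `nSites` grassland patches uniformly in the study region, draws a
#' latent urbanisation gradient, and derives impervious percentages at the
#' three radii as latent-gradient-plus-radius-specific-noise calibrated so
#' that the pairwise correlation across radii approximates
#' `crossScaleCorr`. Building counts scale with local impervious cover;
#' positions are uniform in each site's neighbourhood with heights uniform
#' in `heightRange`.
#'
#' @param config a [syntheticConfig()].
#' @param seed integer; defaults to the config's master seed.
#' @return a [Landscape-class].
#' @export
generateLandscape <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "syntheticConfig"))
  n <- config$nSites
  if (n < 2) stop("need at least 2 sites (pairwise distances undefined)")
  withSeed(seed, {
    x <- runif(n, 0, config$extent)
    y <- runif(n, 0, config$extent)
    latent <- rnorm(n)
    rho <- sqrt(config$crossScaleCorr)
    imp <- sapply(1:3, function(k) {
      z <- rho * latent + sqrt(1 - rho^2) * rnorm(n)
      .minmaxMap(z, config$imperviousRange[1], config$imperviousRange[2])
    })
    colnames(imp) <- c("imperv_100", "imperv_500", "imperv_1000")
    area <- exp(runif(n, log(config$patchSizeRange[1]),
                      log(config$patchSizeRange[2])))
    siteIds <- sprintf("site%02d", seq_len(n))
    nb <- rpois(n, config$nBuildingsPerSite * imp[, "imperv_100"] /
                  mean(imp[, "imperv_100"]))
    bl <- lapply(seq_len(n), function(i) {
      if (nb[i] == 0) return(NULL)
      rr <- 600 * sqrt(runif(nb[i]))
      th <- runif(nb[i], 0, 2 * pi)
      data.frame(x = x[i] + rr * cos(th), y = y[i] + rr * sin(th),
                 height = runif(nb[i], config$heightRange[1],
                                config$heightRange[2]))
    })
    buildings <- do.call(rbind, bl)
    if (is.null(buildings)) {
      buildings <- data.frame(x = numeric(0), y = numeric(0),
                              height = numeric(0))
    }
    d <- as.matrix(dist(cbind(x, y)))
    dimnames(d) <- list(siteIds, siteIds)
    sites <- data.frame(site_id = siteIds, x = x, y = y, area = area,
                        imp, stringsAsFactors = FALSE)
    new("Landscape", sites = sites, buildings = buildings, distances = d)
  })
}

# species pools with genus structure, latent traits and commonness weights
.makePools <- function(config) {
  mk <- function(prefix, n, genusFrac) {
    nGen <- max(1L, round(n * genusFrac))
    genus <- sprintf("%sG%02d", prefix, sample.int(nGen, n, replace = TRUE))
    species <- sprintf("%s_sp%03d", genus, seq_len(n))
    data.frame(species = species, genus = genus,
               trait = runif(n), weight = rlnorm(n, 0, 1) ,
               stringsAsFactors = FALSE)
  }
  list(
    wild_bee  = mk("Bee", config$poolSizes[["bees"]], 0.3),
    hoverfly  = mk("Fly", config$poolSizes[["hoverflies"]], 0.35),
    butterfly = mk("But", config$poolSizes[["butterflies"]], 0.5),
    honey_bee = data.frame(species = "Apis_mellifera", genus = "Apis",
                           trait = 0.5, weight = 1, stringsAsFactors = FALSE),
    plants    = mk("Plant", config$poolSizes[["plants"]], 0.4)
  )
}

#' Generate synthetic flower-visitation records
#'
#' Draws per-site floral communities and visitor assemblages with the
#' configured group-specific log-linear responses to the landscape, then
#' visit counts from the configured count distribution, allocated across
#' plants with probability decaying in latent trait distance at rate
#' `specialisationStrength` and spread over sampling rounds.
#'
#' @param landscape a [Landscape-class] from [generateLandscape()].
#' @param config the matching [syntheticConfig()].
#' @param seed integer; defaults to `config$seed + 1`.
#' @return list with `records` (long-format interaction records),
#'   `siteData` (per-site local habitat predictors: vegetation height, bare
#'   soil, flowering plant richness and abundance, honey-bee visits) and
#'   `pools` (the species pools used).
#' @export
generateVisits <- function(landscape, config, seed = config$seed + 1) {
  stopifnot(inherits(config, "syntheticConfig"), is(landscape, "Landscape"))
  sites <- landscapeSites(landscape)
  n <- nrow(sites)
  eff <- config$effectSizes
  base <- config$baselines
  cImp <- mean(config$imperviousRange)
  withSeed(seed, {
    pools <- .makePools(config)
    if (any(vapply(pools, nrow, 1L) == 0)) stop("empty species pool")
    vegHeight <- pmin(120, pmax(10, rnorm(n, 55, 18)))
    zImp <- as.numeric(scale(sites$imperv_100))
    rb <- config$bareSoilCorr
    bareSoil <- .minmaxMap(rb * zImp + sqrt(1 - rb^2) * rnorm(n), 2, 40)

    drawCount <- function(mu) {
      if (config$countFamily == "poisson") rpois(length(mu), mu)
      else rnbinom(length(mu), mu = mu, size = config$dispersion)
    }
    groupRichness <- function(group, impCol) {
      slope <- switch(group,
        wild_bee  = eff[["bee_richness_vs_impervious"]],
        butterfly = eff[["butterfly_vs_impervious"]],
        hoverfly  = eff[["hoverfly_vs_impervious"]])
      b0 <- switch(group, wild_bee = base[["bee_richness"]],
                   butterfly = base[["butterfly_richness"]],
                   hoverfly = base[["hoverfly_richness"]])
      mu <- b0 * exp(slope * (sites[[impCol]] - cImp))
      pmin(nrow(pools[[group]]), rpois(n, mu))
    }
    richness <- list(
      wild_bee  = groupRichness("wild_bee", "imperv_500"),
      hoverfly  = groupRichness("hoverfly", "imperv_500"),
      butterfly = groupRichness("butterfly", "imperv_100"))

    recs <- list()
    siteRows <- list()
    for (s in seq_len(n)) {
      sid <- sites$site_id[s]
      # floral community
      np <- min(nrow(pools$plants),
                max(3L, rpois(1, base[["plant_richness"]])))
      pidx <- sample.int(nrow(pools$plants), np, prob = pools$plants$weight)
      plants <- pools$plants[pidx, ]
      abund <- plants$weight * rlnorm(np, 0, 0.4) *
        exp(eff[["flower_abundance_vs_impervious"]] *
              (sites$imperv_500[s] - cImp))
      vegEff <- exp(eff[["visits_vs_vegheight"]] * (vegHeight[s] - 55))
      siteRecs <- list()
      for (group in c("wild_bee", "hoverfly", "butterfly", "honey_bee")) {
        pool <- pools[[group]]
        if (group == "honey_bee") {
          vidx <- 1L
        } else {
          k <- richness[[group]][s]
          if (k == 0) next
          vidx <- sample.int(nrow(pool), k, prob = pool$weight)
        }
        # commonness modulates rates within the local assemblage, but is
        # normalised so the configured group rate is the assemblage mean
        wNorm <- setNames(rep(1, nrow(pool)), NULL)
        wNorm[vidx] <- pool$weight[vidx] / mean(pool$weight[vidx])
        for (v in vidx) {
          mu <- if (group == "honey_bee") {
            base[["honeybee_visits"]] *
              exp(eff[["honeybee_vs_impervious"]] * (sites$imperv_100[s] - cImp))
          } else {
            rate <- switch(group, wild_bee = base[["bee_visit_rate"]],
                           hoverfly = base[["hoverfly_visit_rate"]],
                           butterfly = base[["butterfly_visit_rate"]])
            rate * wNorm[v] *
              (if (group %in% c("hoverfly", "butterfly")) vegEff else 1)
          }
          tot <- drawCount(mu)
          if (tot < 1) next
          w <- abund * exp(-config$specialisationStrength *
                             abs(pool$trait[v] - plants$trait))
          byPlant <- as.integer(rmultinom(1, tot, w))
          for (p in which(byPlant > 0)) {
            byRound <- as.integer(rmultinom(1, byPlant[p],
                                            rep(1, config$samplingRounds)))
            for (rr in which(byRound > 0)) {
              siteRecs[[length(siteRecs) + 1L]] <- data.frame(
                site_id = sid, round = sprintf("r%d", rr),
                plant_species = plants$species[p],
                visitor_species = pool$species[v],
                visitor_group = group, count = byRound[rr],
                stringsAsFactors = FALSE)
            }
          }
        }
      }
      recs[[s]] <- if (length(siteRecs)) do.call(rbind, siteRecs) else NULL
      siteRows[[s]] <- data.frame(
        site_id = sid, veg_height = vegHeight[s], bare_soil = bareSoil[s],
        flowering_plant_richness = np, flower_abundance = sum(abund),
        stringsAsFactors = FALSE)
    }
    records <- do.call(rbind, recs)
    if (is.null(records)) stop("no visits generated; raise baseline rates")
    rownames(records) <- NULL
    siteData <- do.call(rbind, siteRows)
    hb <- tapply(records$count[records$visitor_group == "honey_bee"],
                 records$site_id[records$visitor_group == "honey_bee"], sum)
    siteData$honeybee_visits <- as.numeric(hb[siteData$site_id])
    siteData$honeybee_visits[is.na(siteData$honeybee_visits)] <- 0
    list(records = records, siteData = siteData, pools = pools)
  })
}

#' One-shot synthetic study
#'
#' Convenience wrapper: landscape plus visits plus a merged per-site
#' predictor table (landscape covariates joined to local habitat
#' variables).
#'
#' @param config a [syntheticConfig()].
#' @param seed master seed; defaults to the config's.
#' @return list with `landscape`, `records`, `siteData`, `pools`.
#' @export
generateStudy <- function(config = syntheticConfig(), seed = config$seed) {
  landscape <- generateLandscape(config, seed = seed)
  vis <- generateVisits(landscape, config, seed = seed + 1L)
  siteData <- merge(landscapeSites(landscape), vis$siteData, by = "site_id",
                    sort = TRUE)
  siteData$log_patch_size <- log(siteData$area)
  list(landscape = landscape, records = vis$records, siteData = siteData,
       pools = vis$pools)
}
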