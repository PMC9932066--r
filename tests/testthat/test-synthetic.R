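test_that("the generator is byte-reproducible given (config, seed)", {
  cfg <- smallConfig()
  s1 <- generateStudy(cfg, seed = 31)
  s2 <- generateStudy(cfg, seed = 31)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$siteData, s2$siteData)
  expect_identical(landscapeSites(s1$landscape), landscapeSites(s2$landscape))
  s3 <- generateStudy(cfg, seed = 32)
  expect_false(identical(s1$records, s3$records))
})

test_that("perfect cross-scale correlation aligns impervious ranks", {
  cfg <- syntheticConfig(nSites = 30, crossScaleCorr = 1)
  ls <- generateLandscape(cfg, seed = 2)
  s <- landscapeSites(ls)
  expect_identical(rank(s$imperv_100), rank(s$imperv_500))
  expect_identical(rank(s$imperv_100), rank(s$imperv_1000))
})

test_that("cross-scale correlation is calibrated (n = 500 Monte-Carlo check)", {
  cfg <- syntheticConfig(nSites = 500, crossScaleCorr = 0.8)
  ls <- generateLandscape(cfg, seed = 3)
  s <- landscapeSites(ls)
  expect_lt(abs(cor(s$imperv_100, s$imperv_500) - 0.8), 0.05)
  expect_lt(abs(cor(s$imperv_500, s$imperv_1000) - 0.8), 0.05)
})

test_that("landscape invariants hold and tiny designs are rejected", {
  cfg <- smallConfig()
  ls <- generateLandscape(cfg, seed = 4)
  s <- landscapeSites(ls)
  expect_true(all(s$area > 0))
  imp <- as.matrix(s[, c("imperv_100", "imperv_500", "imperv_1000")])
  expect_true(all(imp >= 0 & imp <= 100))
  d <- siteDistances(ls)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, nrow(s)))
  expect_true(all(landscapeBuildings(ls)$height >= 0))
  expect_error(generateLandscape(syntheticConfig(nSites = 1), seed = 1),
               "at least 2")
})

test_that("emitted records respect the schema and reference the landscape", {
  cfg <- syntheticConfig(nSites = 11)
  ls <- generateLandscape(cfg, seed = 7)
  vis <- generateVisits(ls, cfg, seed = 8)
  rec <- vis$records
  expect_silent(validateRecords(rec))
  expect_true(all(rec$site_id %in% landscapeSites(ls)$site_id))
  expect_true(all(rec$visitor_group %in%
                    c("wild_bee", "hoverfly", "butterfly", "honey_bee")))
  expect_true(all(rec$round %in% sprintf("r%d", 1:cfg$samplingRounds)))
  # every pool is represented in the map from species to group
  expect_true(all(rec$visitor_species[rec$visitor_group == "honey_bee"] ==
                    "Apis_mellifera"))
})

test_that("bee richness declines along the configured 500 m covariate", {
  cfg <- syntheticConfig(nSites = 60)
  st <- generateStudy(cfg, seed = 13)
  bees <- siteCommunitySummary(st$records, "wild_bee")
  fit <- fitCountModel(bees$richness,
                       data.frame(imp = st$siteData$imperv_500),
                       family = "poisson")
  est <- fit$coefficients["imp", "Estimate"]
  se <- fit$coefficients["imp", "Std. Error"]
  slope <- cfg$effectSizes[["bee_richness_vs_impervious"]]
  expect_lt(abs(est - slope), 2.5 * se)
  expect_lt(est, 0)
})

test_that("a zero slope is recovered as null (CI covers 0 in most replicates)", {
  eff <- syntheticConfig()$effectSizes
  eff[["bee_richness_vs_impervious"]] <- 0
  cover <- 0
  nRep <- 25
  for (r in seq_len(nRep)) {
    cfg <- syntheticConfig(nSites = 40, effectSizes = eff,
                           poolSizes = c(bees = 105, hoverflies = 10,
                                         butterflies = 8, plants = 40),
                           baselines = c(bee_richness = 20,
                                         hoverfly_richness = 3,
                                         butterfly_richness = 3,
                                         plant_richness = 10,
                                         honeybee_visits = 10,
                                         bee_visit_rate = 3.4,
                                         hoverfly_visit_rate = 2,
                                         butterfly_visit_rate = 2))
    st <- generateStudy(cfg, seed = 1000 + r)
    bees <- siteCommunitySummary(st$records, "wild_bee")
    fit <- fitCountModel(bees$richness,
                         data.frame(imp = st$siteData$imperv_500),
                         family = "poisson")
    est <- fit$coefficients["imp", "Estimate"]
    se <- fit$coefficients["imp", "Std. Error"]
    if (abs(est) < 2 * se) cover <- cover + 1
  }
  expect_gte(cover / nRep, 0.8)
})

test_that("honey-bee visits rise with urbanisation and hoverflies stay flat", {
  cfg <- syntheticConfig(nSites = 60)
  st <- generateStudy(cfg, seed = 17)
  hb <- fitCountModel(round(st$siteData$honeybee_visits),
                      data.frame(imp = st$siteData$imperv_100))
  expect_gt(hb$coefficients["imp", "Estimate"], 0)
  flies <- siteCommunitySummary(st$records, "hoverfly")
  fl <- fitCountModel(flies$richness,
                      data.frame(imp = st$siteData$imperv_500),
                      family = "poisson")
  est <- fl$coefficients["imp", "Estimate"]
  se <- fl$coefficients["imp", "Std. Error"]
  expect_lt(abs(est), 3 * se)
})

test_that("group interaction shares are monotone in the group rate multipliers", {
  base <- smallConfig()
  st1 <- generateStudy(base, seed = 23)
  sh1 <- tallyReport(st1$records)$interactions
  boosted <- smallConfig(baselines = c(bee_richness = 12,
                                       hoverfly_richness = 6,
                                       butterfly_richness = 5,
                                       plant_richness = 10,
                                       honeybee_visits = 20,
                                       bee_visit_rate = 6.8,
                                       hoverfly_visit_rate = 2,
                                       butterfly_visit_rate = 2))
  st2 <- generateStudy(boosted, seed = 23)
  sh2 <- tallyReport(st2$records)$interactions
  expect_gt(sh2$share_pct[sh2$group == "wild_bee"],
            sh1$share_pct[sh1$group == "wild_bee"])
})

test_that("stronger trait matching raises network specialisation", {
  loose <- smallConfig(specialisationStrength = 0)
  tight <- smallConfig(specialisationStrength = 10)
  h <- function(cfg, seed) {
    st <- generateStudy(cfg, seed = seed)
    mean(vapply(unique(st$records$site_id), function(s) {
      as.numeric(h2prime(buildNetwork(st$records, s)))
    }, numeric(1)))
  }
  expect_gt(h(tight, 41), h(loose, 41))
})

test_that("invalid configurations are rejected", {
  expect_error(syntheticConfig(crossScaleCorr = 1.2))
  expect_error(syntheticConfig(poolSizes = c(bees = 0, hoverflies = 3,
                                             butterflies = 3, plants = 5)))
  expect_error(syntheticConfig(imperviousRange = c(50, 50)))
  expect_error(syntheticConfig(heightRange = c(30, 4)))
})
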