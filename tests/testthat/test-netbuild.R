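test_that("building a network pools counts across rounds", {
  rec <- data.frame(site_id = "siteA", round = c("r1", "r2"),
                    plant_species = "P1", visitor_species = "V1",
                    visitor_group = "wild_bee", count = c(2, 3),
                    stringsAsFactors = FALSE)
  net <- buildNetwork(rec, "siteA")
  expect_identical(dim(interactionMatrix(net)), c(1L, 1L))
  expect_equal(as.numeric(interactionMatrix(net)), 5)
  expect_equal(totalInteractions(net), 5)
})

test_that("absent plant-visitor pairs stay zero without zero margins", {
  rec <- expand.grid(plant_species = c("P1", "P2", "P3"),
                     visitor_species = c("V1", "V2"),
                     stringsAsFactors = FALSE)
  rec$site_id <- "s"; rec$round <- "r1"; rec$visitor_group <- "hoverfly"
  rec$count <- 1
  rec <- rec[-4, ]   # drop one pair
  net <- buildNetwork(rec, "s")
  a <- interactionMatrix(net)
  expect_identical(dim(a), c(3L, 2L))
  expect_equal(sum(a == 0), 1)
  expect_true(all(rowSums(a) > 0) && all(colSums(a) > 0))
})

test_that("interaction totals are conserved across a generated study", {
  st <- generateStudy(smallConfig(), seed = 11)
  sites <- unique(st$records$site_id)
  ms <- vapply(sites, function(s) totalInteractions(buildNetwork(st$records, s)),
               numeric(1))
  expect_equal(sum(ms), sum(st$records$count))
})

test_that("unknown site errors", {
  rec <- printedTallyFixture()
  expect_error(buildNetwork(rec, "nowhere"), "no records")
})

test_that("genus aggregation sums congeneric columns and preserves m", {
  a <- matrix(c(1, 0, 0, 2, 3, 1), nrow = 2,
              dimnames = list(c("P1", "P2"),
                              c("Gen1_a", "Gen1_b", "Gen2_c")))
  net <- BipartiteNetwork(a, siteId = "s")
  g <- aggregateToGenus(net)
  expect_identical(visitorSpecies(g), c("Gen1", "Gen2"))
  expect_equal(unname(interactionMatrix(g)[, "Gen1"]), c(1, 2))
  expect_equal(totalInteractions(g), totalInteractions(net))
  expect_identical(netResolution(g), "genus")
})

test_that("aggregation with all-distinct genera is the identity up to labels", {
  a <- matrix(1:6, 2, 3,
              dimnames = list(c("P1", "P2"), c("Ga_x", "Gb_y", "Gc_z")))
  net <- BipartiteNetwork(a, siteId = "s")
  g <- aggregateToGenus(net)
  expect_equal(unname(interactionMatrix(g)), unname(interactionMatrix(net)))
})

test_that("random genus maps conserve m and row totals; genus level is a fixed point", {
  set.seed(3)
  for (rep in 1:10) {
    a <- randomSmallNet(4, 6, 25)
    net <- BipartiteNetwork(a, siteId = "s")
    tax <- setNames(sprintf("G%d_", sample(3, 6, replace = TRUE)),
                    colnames(a))
    tax <- sub("_$", "", tax)
    g <- aggregateToGenus(net, tax)
    expect_equal(totalInteractions(g), sum(a))
    expect_equal(unname(rowSums(interactionMatrix(g))), unname(rowSums(a)))
    gg <- aggregateToGenus(g, taxonomyFromLabels(visitorSpecies(g)))
    expect_equal(interactionMatrix(gg), interactionMatrix(g))
  }
})

test_that("missing genus mapping errors and names the species", {
  a <- matrix(1:4, 2, 2, dimnames = list(c("P1", "P2"), c("Ga_x", "Gb_y")))
  net <- BipartiteNetwork(a, siteId = "s")
  expect_error(aggregateToGenus(net, c(Ga_x = "Ga")), "Gb_y")
})

test_that("minimum-visit filter matches a brute-force tally and k = 1 is identity", {
  st <- generateStudy(smallConfig(), seed = 5)
  rec <- st$records
  f3 <- filterMinVisits(rec, 3)
  tot <- tapply(rec$count, rec$visitor_species, sum)
  expect_setequal(unique(f3$visitor_species), names(tot)[tot >= 3])
  expect_true(all(tapply(f3$count, f3$visitor_species, sum) >= 3))
  expect_identical(filterMinVisits(rec, 1), rec)
  # species with exactly 2 total visits are removed at the survey threshold
  two <- names(tot)[tot == 2]
  if (length(two)) expect_false(any(two %in% f3$visitor_species))
})

test_that("records survive a write/read round trip and rebuild identically", {
  st <- generateStudy(smallConfig(), seed = 9)
  tmp <- tempfile(fileext = ".tsv")
  writeInteractionRecords(st$records, tmp)
  back <- readInteractionRecords(tmp)
  s <- st$records$site_id[1]
  expect_equal(interactionMatrix(buildNetwork(back, s)),
               interactionMatrix(buildNetwork(st$records, s)))
  tmp2 <- tempfile(fileext = ".tsv")
  net <- buildNetwork(st$records, s)
  writeNetworkMatrix(net, tmp2)
  net2 <- readNetworkMatrix(tmp2, siteId = s)
  expect_equal(interactionMatrix(net2), interactionMatrix(net))
})

test_that("degenerate record tables are rejected", {
  rec <- printedTallyFixture()
  bad <- rec; bad$count[1] <- 0
  expect_error(buildNetwork(bad, "siteA"), "positive integers")
  bad2 <- rec; bad2$visitor_group[1] <- "beetle"
  expect_error(validateRecords(bad2), "beetle")
})
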