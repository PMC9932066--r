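# Fixtures built in code.

# A records table whose per-group interaction and species totals equal the
# headline tallies of a published urban dry-grassland survey: 1095 wild-bee,
# 270 hoverfly, 203 butterfly and 448 honey-bee visits (2016 total) by
# 105 + 38 + 22 wild species plus the honey bee, on 67 plant species.
printedTallyFixture <- function() {
  spec <- list(
    wild_bee  = c(nsp = 105, visits = 1095),
    hoverfly  = c(nsp = 38,  visits = 270),
    butterfly = c(nsp = 22,  visits = 203),
    honey_bee = c(nsp = 1,   visits = 448))
  plantIds <- sprintf("Plant_%02d", 1:67)
  rows <- list()
  k <- 0
  for (g in names(spec)) {
    nsp <- spec[[g]][["nsp"]]; visits <- spec[[g]][["visits"]]
    base <- visits %/% nsp
    counts <- rep(base, nsp) + (seq_len(nsp) <= visits %% nsp)
    for (i in seq_len(nsp)) {
      k <- k + 1
      rows[[k]] <- data.frame(
        site_id = "siteA", round = "r1",
        plant_species = plantIds[((k - 1) %% 67) + 1],
        visitor_species = sprintf("%s_sp%03d", g, i),
        visitor_group = g, count = counts[i], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# tiny deterministic two-block network: two internally complete,
# mutually disconnected 3x3 blocks
twoBlockNet <- function() {
  a <- matrix(0, 6, 6)
  a[1:3, 1:3] <- 2
  a[4:6, 4:6] <- 2
  dimnames(a) <- list(sprintf("P%d", 1:6), sprintf("V%d", 1:6))
  a
}

smallConfig <- function(...) {
  args <- list(
    nSites = 6,
    poolSizes = c(bees = 40, hoverflies = 15, butterflies = 10, plants = 25),
    baselines = c(bee_richness = 12, hoverfly_richness = 6,
                  butterfly_richness = 5, plant_richness = 10,
                  honeybee_visits = 20, bee_visit_rate = 3.4,
                  hoverfly_visit_rate = 2, butterfly_visit_rate = 2))
  over <- list(...)
  args[names(over)] <- over
  do.call(syntheticConfig, args)
}
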