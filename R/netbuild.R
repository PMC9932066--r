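#' Validate a long-format interaction record table
#'
#' Records are the package's exchange format for flower-visitation data:
#' one row per (site, sampling round, plant, visitor) with a positive visit
#' count and the visitor's pollinator group.
#'
#' @param records data.frame with columns `site_id`, `round`,
#'   `plant_species`, `visitor_species`, `visitor_group`, `count`.
#' @return the records, invisibly, after validation.
#' @export
validateRecords <- function(records) {
  need <- c("site_id", "round", "plant_species", "visitor_species",
            "visitor_group", "count")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("records are missing columns: ", paste(miss, collapse = ", "))
  }
  if (any(records$count < 1) || any(records$count != round(records$count))) {
    stop("visit counts must be positive integers")
  }
  bad <- setdiff(unique(records$visitor_group), POLLINATOR_GROUPS)
  if (length(bad)) {
    stop("unknown visitor groups: ", paste(bad, collapse = ", "))
  }
  invisible(records)
}

#' Build a site-level quantitative network from interaction records
#'
#' Pools all sampling rounds of one site into a plant x visitor count
#' matrix. Plants or visitors never observed at the site do not appear
#' (no all-zero rows or columns), and the matrix total equals the summed
#' visit counts of the site's records.
#'
#' @param records long-format interaction records (see [validateRecords()]).
#' @param site a site id present in `records`.
#' @param includeHoneyBees keep the managed honey bee as a network column
#'   (default TRUE; set FALSE for wild-pollinator-only summaries).
#' @return a [BipartiteNetwork-class] at species resolution.
#' @examples
#' rec <- data.frame(site_id = "A", round = c(1, 2),
#'                   plant_species = "P1", visitor_species = "V1",
#'                   visitor_group = "wild_bee", count = c(2, 3))
#' buildNetwork(rec, "A")
#' @export
buildNetwork <- function(records, site, includeHoneyBees = TRUE) {
  validateRecords(records)
  rec <- records[records$site_id == site, , drop = FALSE]
  if (!nrow(rec)) stop("no records for site '", site, "'")
  if (!includeHoneyBees) {
    rec <- rec[rec$visitor_group != "honey_bee", , drop = FALSE]
    if (!nrow(rec)) stop("site '", site, "' has only honey-bee records")
  }
  counts <- tapply(rec$count,
                   list(plant = rec$plant_species,
                        visitor = rec$visitor_species),
                   sum, default = 0)
  counts <- as.matrix(counts)
  groups <- tapply(rec$visitor_group, rec$visitor_species,
                   function(g) g[[1L]])
  BipartiteNetwork(counts, siteId = site, resolution = "species",
                   visitorGroup = setNames(as.character(groups),
                                           names(groups)))
}

#' Derive a species -> genus taxonomy map from species labels
#'
#' Species labels of the form `"Genus_epithet"` (the generator's convention,
#' and a common field convention) are split at the first underscore or space.
#'
#' @param species character vector of species labels.
#' @return named character vector: species -> genus.
#' @export
taxonomyFromLabels <- function(species) {
  species <- unique(species)
  genus <- sub("[_ ].*$", "", species)
  if (any(!nzchar(genus))) stop("empty genus label derived")
  setNames(genus, species)
}

#' Aggregate the visitor side of a network to genus resolution
#'
#' Visitor columns sharing a genus are summed; plant rows are left at
#' species resolution. The interaction total m is preserved.
#'
#' @param net a [BipartiteNetwork-class] at species resolution.
#' @param taxonomy named character vector mapping every visitor species of
#'   `net` to a genus; defaults to [taxonomyFromLabels()] on the visitor
#'   labels.
#' @return a [BipartiteNetwork-class] with `resolution = "genus"`.
#' @export
aggregateToGenus <- function(net, taxonomy = taxonomyFromLabels(visitorSpecies(net))) {
  stopifnot(is(net, "BipartiteNetwork"))
  vis <- visitorSpecies(net)
  missing <- vis[!vis %in% names(taxonomy)]
  if (length(missing)) {
    stop("no genus mapping for visitor species: ",
         paste(missing, collapse = ", "))
  }
  genus <- taxonomy[vis]
  a <- interactionMatrix(net)
  agg <- t(rowsum(t(a), group = genus))
  grp <- visitorGroups(net)
  genusGroup <- tapply(grp[vis], genus, function(g) g[[1L]])
  BipartiteNetwork(agg, siteId = siteId(net), resolution = "genus",
                   visitorGroup = setNames(as.character(genusGroup),
                                           names(genusGroup)))
}

#' Drop rarely observed visitor species from interaction records
#'
#' Composition analyses use only visitor species with at least `k` visits
#' summed across all sites (default 3), to avoid statistical noise from
#' singletons and doubletons.
#'
#' @param records interaction records.
#' @param k minimum total visit count (default 3).
#' @return the filtered records (possibly with zero rows).
#' @export
filterMinVisits <- function(records, k = 3) {
  validateRecords(records)
  k <- assertCount(k, "k")
  if (k < 1) stop("'k' must be >= 1")
  tot <- tapply(records$count, records$visitor_species, sum)
  keep <- names(tot)[tot >= k]
  records[records$visitor_species %in% keep, , drop = FALSE]
}
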