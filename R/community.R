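# Community-level summaries and composition-analysis preprocessing.

#' Shannon diversity of a count vector
#'
#' \eqn{H = -\sum p \ln p} in nats, with `p` the normalised counts.
#'
#' @param counts non-negative counts, at least one positive.
#' @export
shannonDiversity <- function(counts) {
  if (all(counts == 0)) stop("all counts are zero")
  if (any(counts < 0)) stop("negative counts")
  as.numeric(diversity(matrix(counts, nrow = 1), index = "shannon"))
}

#' Per-site community summaries from interaction records
#'
#' Richness, Shannon diversity and pooled visitation totals per site, for
#' one pollinator group or all wild pollinators.
#'
#' @param records interaction records.
#' @param group one of the pollinator groups, `"wild"` (all except the
#'   honey bee) or `"all"`.
#' @return data.frame: site_id, richness, shannon, visits.
#' @export
siteCommunitySummary <- function(records, group = "wild") {
  validateRecords(records)
  rec <- if (group == "all") records
    else if (group == "wild") records[records$visitor_group != "honey_bee", ]
    else records[records$visitor_group == group, ]
  sites <- sort(unique(records$site_id))
  out <- lapply(sites, function(s) {
    r <- rec[rec$site_id == s, , drop = FALSE]
    if (!nrow(r)) {
      return(data.frame(site_id = s, richness = 0L, shannon = NA_real_,
                        visits = 0L, stringsAsFactors = FALSE))
    }
    cnt <- tapply(r$count, r$visitor_species, sum)
    data.frame(site_id = s, richness = length(cnt),
               shannon = shannonDiversity(as.numeric(cnt)),
               visits = sum(cnt), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Site x species community matrix from records
#'
#' @param records interaction records (typically after [filterMinVisits()]).
#' @return integer matrix, sites as rows, visitor species as columns.
#' @export
communityMatrix <- function(records) {
  validateRecords(records)
  m <- tapply(records$count,
              list(site = records$site_id, species = records$visitor_species),
              sum, default = 0)
  as.matrix(m)
}

#' Prepared Bray-Curtis dissimilarity for composition analysis
#'
#' The composition-analysis preprocessing chain: square-root transform,
#' Wisconsin double standardisation (divide by species maxima, then by site
#' totals), then Bray-Curtis dissimilarity. Input species should already be
#' filtered to those with at least three visits overall
#' (see [filterMinVisits()]).
#'
#' @param comm site x species count matrix.
#' @return a symmetric `dist`-derived matrix with zero diagonal, entries in
#'   \[0, 1\].
#' @export
brayCurtisPrepared <- function(comm) {
  comm <- as.matrix(comm)
  if (nrow(comm) < 2) stop("need at least 2 sites")
  empty <- rownames(comm)[rowSums(comm) == 0]
  if (length(empty)) {
    stop("site(s) with zero total after filtering: ",
         paste(empty, collapse = ", "))
  }
  std <- wisconsin(sqrt(comm))
  as.matrix(vegdist(std, method = "bray"))
}

#' Permutation test for an environmental vector fitted to an ordination
#'
#' Fits the best linear vector of an environmental variable onto 2-D
#' ordination coordinates (the squared multiple correlation of the variable
#' on the two axes) and assesses it by permuting the variable across sites.
#' The p-value uses the add-one estimator
#' \eqn{p = (1 + \#\{R^2_{perm} \ge R^2_{obs}\})/(1 + n_{perm})}, so its
#' smallest attainable value is \eqn{1/(1+n_{perm})}.
#'
#' @param coords site x 2 matrix of ordination coordinates (any standard
#'   multidimensional-scaling routine, e.g. `stats::cmdscale` on
#'   [brayCurtisPrepared()] output).
#' @param env numeric environmental variable, one value per site.
#' @param nPerm number of permutations (default 99999).
#' @param seed optional seed.
#' @return list with `r2` and `p`.
#' @export
envfitPermutation <- function(coords, env, nPerm = 99999, seed = NULL) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 2, nrow(coords) == length(env))
  if (sd(env) == 0) stop("constant environmental variable")
  if (nPerm < 99) stop("use at least 99 permutations")
  X <- scale(coords, scale = FALSE)
  H <- X %*% solve(crossprod(X)) %*% t(X)       # projection onto the axes
  r2of <- function(e) {
    e <- e - mean(e)
    as.numeric(crossprod(e, H %*% e) / crossprod(e))
  }
  obs <- r2of(env)
  hits <- withSeed(seed, {
    sum(vapply(seq_len(nPerm),
               function(i) r2of(sample(env)) >= obs - 1e-12, logical(1)))
  })
  list(r2 = obs, p = (1 + hits) / (1 + nPerm))
}
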