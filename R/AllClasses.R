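#' BipartiteNetwork: a quantitative plant x flower-visitor count matrix
#'
#' The central data container of the package: a site-level quantitative
#' bipartite network with flowering plants as rows and flower visitors as
#' columns. Cell \eqn{a_{ij}} holds the pooled number of visits of visitor
#' \eqn{j} to plant \eqn{i} across all sampling rounds. Rows and columns are
#' kept in lexicographic label order so that matrices are canonical, and
#' all-zero rows or columns are disallowed (network metrics are undefined for
#' unobserved species).
#'
#' @slot counts non-negative integer matrix; rows = plants, columns =
#'   visitors, with unique dimnames.
#' @slot siteId single character site label.
#' @slot resolution taxonomic resolution of the visitor side, either
#'   \code{"species"} or \code{"genus"}. Plants are always at species level.
#' @slot visitorGroup named character vector mapping each visitor column to
#'   its pollinator group (\code{wild_bee}, \code{hoverfly},
#'   \code{butterfly}, \code{honey_bee}).
#'
#' @seealso [buildNetwork()], [aggregateToGenus()], [networkMetrics()]
#' @exportClass BipartiteNetwork
setClass("BipartiteNetwork",
  representation(
    counts       = "matrix",
    siteId       = "character",
    resolution   = "character",
    visitorGroup = "character"
  )
)

.validBipartiteNetwork <- function(object) {
  msg <- character()
  a <- object@counts
  if (!is.numeric(a)) msg <- c(msg, "counts must be numeric")
  if (any(a < 0) || any(a != round(a))) {
    msg <- c(msg, "counts must be non-negative integers")
  }
  if (is.null(rownames(a)) || is.null(colnames(a))) {
    msg <- c(msg, "counts must have row (plant) and column (visitor) names")
  } else {
    if (anyDuplicated(rownames(a))) msg <- c(msg, "duplicated plant labels")
    if (anyDuplicated(colnames(a))) msg <- c(msg, "duplicated visitor labels")
  }
  if (sum(a) < 1) msg <- c(msg, "network must contain at least one visit")
  if (nrow(a) > 0 && any(rowSums(a) == 0)) {
    msg <- c(msg, "all-zero plant rows are not allowed")
  }
  if (ncol(a) > 0 && any(colSums(a) == 0)) {
    msg <- c(msg, "all-zero visitor columns are not allowed")
  }
  if (length(object@siteId) != 1L) msg <- c(msg, "siteId must be length 1")
  if (length(object@resolution) != 1L ||
      !object@resolution %in% c("species", "genus")) {
    msg <- c(msg, "resolution must be 'species' or 'genus'")
  }
  if (length(object@visitorGroup) &&
      !all(colnames(a) %in% names(object@visitorGroup))) {
    msg <- c(msg, "visitorGroup must cover every visitor column")
  }
  if (length(msg)) msg else TRUE
}

setValidity("BipartiteNetwork", .validBipartiteNetwork)

#' Construct a BipartiteNetwork from a labelled count matrix
#'
#' @param counts non-negative integer matrix with plant rownames and visitor
#'   colnames. Rows/columns are reordered lexicographically.
#' @param siteId site label.
#' @param resolution `"species"` (default) or `"genus"`.
#' @param visitorGroup optional named character vector (visitor -> group).
#' @return a [BipartiteNetwork-class] object.
#' @examples
#' m <- matrix(c(3, 0, 1, 2), 2, 2,
#'             dimnames = list(c("PlantA", "PlantB"), c("Bee1", "Fly1")))
#' net <- BipartiteNetwork(m, siteId = "s1")
#' totalInteractions(net)
#' @export
BipartiteNetwork <- function(counts, siteId = "site", resolution = "species",
                             visitorGroup = character()) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  counts <- counts[order(rownames(counts)), order(colnames(counts)),
                   drop = FALSE]
  dimnames(counts) <- list(rownames(counts), colnames(counts))  # canonical
  new("BipartiteNetwork", counts = counts, siteId = as.character(siteId),
      resolution = resolution, visitorGroup = visitorGroup)
}

setMethod("show", "BipartiteNetwork", function(object) {
  a <- object@counts
  cat(sprintf(
    "BipartiteNetwork [site %s, %s resolution]\n  %d plants x %d visitors, %d interactions\n",
    object@siteId, object@resolution, nrow(a), ncol(a), sum(a)))
  if (length(object@visitorGroup)) {
    tab <- table(object@visitorGroup[colnames(a)])
    cat("  visitor groups:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
})

#' Landscape: patch geometry, urbanisation covariates and buildings
#'
#' Holds the landscape side of a (synthetic or real) study design: one row
#' per grassland patch with its centroid, area and impervious-surface
#' percentages at the 100/500/1000 m radii, a table of buildings
#' (coordinates and heights) and the symmetric matrix of inter-patch
#' distances used by the connectivity index.
#'
#' @slot sites data.frame with columns `site_id`, `x`, `y`, `area`,
#'   `imperv_100`, `imperv_500`, `imperv_1000`.
#' @slot buildings data.frame with columns `x`, `y`, `height`.
#' @slot distances symmetric numeric matrix of inter-patch distances (m),
#'   zero diagonal, dimnames = site ids.
#' @exportClass Landscape
setClass("Landscape",
  representation(sites = "data.frame", buildings = "data.frame",
                 distances = "matrix")
)

.validLandscape <- function(object) {
  msg <- character()
  s <- object@sites
  need <- c("site_id", "x", "y", "area",
            "imperv_100", "imperv_500", "imperv_1000")
  if (!all(need %in% names(s))) {
    msg <- c(msg, paste("sites must have columns:", paste(need, collapse = ", ")))
  } else {
    imp <- as.matrix(s[, c("imperv_100", "imperv_500", "imperv_1000")])
    if (any(imp < 0 | imp > 100)) msg <- c(msg, "impervious % must be in [0,100]")
    if (any(s$area <= 0)) msg <- c(msg, "patch areas must be positive")
  }
  b <- object@buildings
  if (nrow(b) && (!all(c("x", "y", "height") %in% names(b)) ||
                  any(b$height < 0))) {
    msg <- c(msg, "buildings need x, y and non-negative height")
  }
  d <- object@distances
  if (nrow(d) != nrow(s) || !isSymmetric(unname(d)) ||
      any(abs(diag(d)) > 1e-9)) {
    msg <- c(msg, "distances must be symmetric with zero diagonal, one row per site")
  }
  if (length(msg)) msg else TRUE
}

setValidity("Landscape", .validLandscape)

setMethod("show", "Landscape", function(object) {
  cat(sprintf("Landscape: %d patches, %d buildings\n",
              nrow(object@sites), nrow(object@buildings)))
  cat(sprintf("  impervious (500 m): %.1f-%.1f%%\n",
              min(object@sites$imperv_500), max(object@sites$imperv_500)))
})
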