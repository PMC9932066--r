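# The building-height-modified Hanski connectivity index and
# scale-of-effect selection for multi-radius landscape predictors.

# Distance from points (x, y) to the segment p1-p2.
pointSegmentDistance <- function(x, y, p1, p2) {
  vx <- p2[1] - p1[1]; vy <- p2[2] - p1[2]
  len2 <- vx^2 + vy^2
  if (len2 == 0) return(sqrt((x - p1[1])^2 + (y - p1[2])^2))
  t <- ((x - p1[1]) * vx + (y - p1[2]) * vy) / len2
  t <- pmin(1, pmax(0, t))
  sqrt((x - (p1[1] + t * vx))^2 + (y - (p1[2] + t * vy))^2)
}

#' Summed building heights along an inter-patch corridor
#'
#' The connecting route between two patches is the straight segment between
#' their centroids; buildings whose location lies within `radius` metres of
#' the segment (point-to-segment distance) contribute their full height to
#' the sum. This is the vertical-obstruction term of the 3D connectivity
#' index.
#'
#' @param p1,p2 numeric length-2 centroids (x, y) in metres.
#' @param buildings data.frame with columns `x`, `y`, `height`.
#' @param radius corridor radius in metres (default 25).
#' @return total height (m) of buildings inside the corridor.
#' @export
corridorBuildingSum <- function(p1, p2, buildings, radius = 25) {
  if (radius <= 0) stop("corridor radius must be positive")
  if (is.null(buildings) || nrow(buildings) == 0) return(0)
  d <- pointSegmentDistance(buildings$x, buildings$y, p1, p2)
  sum(buildings$height[d <= radius])
}

#' 3D habitat connectivity of a focal patch
#'
#' A building-height-modified Hanski incidence-function connectivity index:
#' \deqn{S_i = \sum_{j \ne i} \exp(-\alpha \, d^{eff}_{ij}) \, A_j,\quad
#'       d^{eff}_{ij} = d_{ij} + \lambda H_{ij}}
#' where \eqn{A_j} are neighbour patch areas, \eqn{d_{ij}} inter-patch
#' distances and \eqn{H_{ij}} the summed building heights in the 25 m
#' corridor between the patches. With \eqn{\lambda = 0} this is exactly
#' Hanski's connectivity index; \eqn{\lambda} (default 1: one metre of
#' added effective distance per metre of summed building height) converts
#' vertical obstruction into isolation.
#'
#' @param neighbourAreas areas \eqn{A_j} in square metres.
#' @param edgeDistances distances \eqn{d_{ij}} in metres.
#' @param buildingHeightSums corridor height sums \eqn{H_{ij}} in metres
#'   (default 0: plain Hanski index).
#' @param alpha distance-decay parameter in 1/m (default 0.002, i.e. a mean
#'   effective dispersal distance of 500 m).
#' @param lambda height weighting (dimensionless).
#' @return the connectivity value \eqn{S_i}; 0 with a warning when there are
#'   no neighbours.
#' @export
connectivity3D <- function(neighbourAreas, edgeDistances,
                           buildingHeightSums = 0, alpha = 0.002, lambda = 1) {
  if (length(neighbourAreas) == 0) {
    warning("focal patch has no neighbours; connectivity is 0")
    return(0)
  }
  if (alpha <= 0) stop("alpha must be positive")
  stopifnot(all(neighbourAreas > 0), all(edgeDistances >= 0),
            all(buildingHeightSums >= 0))
  dEff <- edgeDistances + lambda * buildingHeightSums
  sum(exp(-alpha * dEff) * neighbourAreas)
}

#' Per-site 3D connectivity over a whole landscape
#'
#' Applies [connectivity3D()] to every patch of a [Landscape-class], with
#' corridor building-height sums computed from the landscape's building
#' table.
#'
#' @param landscape a [Landscape-class].
#' @param alpha,lambda,corridorRadius see [connectivity3D()] and
#'   [corridorBuildingSum()].
#' @return named numeric vector of \eqn{S_i} per site.
#' @export
siteConnectivity <- function(landscape, alpha = 0.002, lambda = 1,
                             corridorRadius = 25) {
  s <- landscapeSites(landscape)
  b <- landscapeBuildings(landscape)
  d <- siteDistances(landscape)
  n <- nrow(s)
  if (n < 2) stop("need at least 2 patches")
  out <- numeric(n)
  H <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      H[i, j] <- H[j, i] <- corridorBuildingSum(
        c(s$x[i], s$y[i]), c(s$x[j], s$y[j]), b, radius = corridorRadius)
    }
  }
  for (i in seq_len(n)) {
    out[i] <- connectivity3D(s$area[-i], d[i, -i], H[i, -i],
                             alpha = alpha, lambda = lambda)
  }
  setNames(out, s$site_id)
}

#' Scale-of-effect selection for a multi-radius landscape predictor
#'
#' Correlates a per-site response with the predictor measured at each
#' candidate radius and selects the radius with the highest absolute
#' Pearson correlation ("scale of effect"). Ties are broken toward the
#' smallest radius (the most local mechanism).
#'
#' @param response numeric per-site response values.
#' @param predictorTable data.frame/matrix, one column per radius, rows in
#'   the same site order as `response`; column names are parsed for the
#'   radius (e.g. `imperv_100`).
#' @param transform optional transform applied to the response before
#'   correlating (e.g. `log1p` for strongly skewed counts).
#' @return list with `radius` (numeric), `correlations` (named vector) and
#'   `selected` (column name).
#' @export
selectScale <- function(response, predictorTable, transform = identity) {
  pt <- as.data.frame(predictorTable)
  if (length(response) != nrow(pt)) stop("response/predictor length mismatch")
  if (length(response) < 3) stop("need at least 3 sites")
  if (sd(response) == 0) stop("constant response: correlation undefined")
  if (any(vapply(pt, sd, numeric(1)) == 0)) {
    stop("a predictor column is constant")
  }
  y <- transform(response)
  rs <- vapply(pt, function(p) cor(y, p), numeric(1))
  radii <- suppressWarnings(as.numeric(gsub("\\D", "", names(pt))))
  ord <- order(-abs(rs), radii)
  sel <- ord[1]
  list(radius = radii[sel], correlations = rs, selected = names(pt)[sel])
}
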