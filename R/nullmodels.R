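#' Fixed-margin random interaction networks (Patefield algorithm)
#'
#' Draws integer tables with exactly the given row and column totals from
#' the independence-conditional (multiple hypergeometric) distribution,
#' using Patefield's (1981) AS 159 sequential conditional sampler as
#' implemented in `stats::r2dtable`.
#'
#' @param rowTotals,colTotals integer margins with equal sums.
#' @param n number of draws.
#' @param seed optional integer seed (the caller's RNG stream is restored).
#' @return a list of `n` matrices with the requested margins.
#' @examples
#' tabs <- patefieldNull(c(3, 2), c(4, 1), n = 2, seed = 1)
#' rowSums(tabs[[1]])
#' @export
patefieldNull <- function(rowTotals, colTotals, n = 1, seed = NULL) {
  if (sum(rowTotals) != sum(colTotals)) {
    stop("row and column totals must have equal sums")
  }
  if (sum(rowTotals) < 1) stop("margins must sum to at least 1")
  if (length(rowTotals) == 1L || length(colTotals) == 1L) {
    # degenerate single-line table: the margins determine it completely
    tab <- if (length(rowTotals) == 1L) matrix(colTotals, nrow = 1)
           else matrix(rowTotals, ncol = 1)
    return(replicate(n, tab, simplify = FALSE))
  }
  withSeed(seed, r2dtable(n, as.integer(rowTotals), as.integer(colTotals)))
}

# Metric evaluators closed over precomputed standardisation bounds: the
# H2'/d' bounds depend only on the margins, which every Patefield draw
# shares with the observed network, so they are computed once and reused —
# observed and null values are standardised identically.
.marginBounds <- function(rowTotals, colTotals, metrics) {
  m <- sum(rowTotals)
  q <- rowTotals / m
  list(
    q = q,
    h2 = if ("h2prime" %in% metrics) h2Bounds(rowTotals, colTotals) else NULL,
    d = if ("mean_dprime" %in% metrics) {
      lapply(colTotals, function(A) dBounds(A, rowTotals, q))
    } else NULL)
}

.metricFunctions <- function(saParams, seed, bounds) {
  q <- bounds$q
  h2b <- bounds$h2
  dB <- bounds$d
  list(
    connectance = function(a, k) connectance(a),
    nodf        = function(a, k) nodf(a),
    modularity  = function(a, k) {
      bipartiteModularity(a, saParams = saParams, seed = seed + k)$Q
    },
    h2prime     = function(a, k) as.numeric(.h2FromBounds(a, h2b)),
    mean_dprime = function(a, k) {
      mean(vapply(seq_len(ncol(a)), function(j) {
        .dFromBounds(a[, j], q, dB[[j]])
      }, numeric(1)))
    }
  )
}

#' Delta-transformation of network metrics against Patefield null models
#'
#' Computes each requested metric on the observed network and on fixed-margin
#' null draws, and returns the null-standardised value
#' \eqn{\Delta = N - \bar N_r} (observed minus null mean). Defaults follow
#' common practice for site-level visitation networks: 1000 null draws per
#' metric, 100 for the annealing-based modularity. Null draws on which a
#' metric is undefined are rejected and resampled (counted in `n_rejected`).
#'
#' @param net a [BipartiteNetwork-class].
#' @param metrics character subset of `c("connectance", "nodf",
#'   "modularity", "h2prime", "mean_dprime")`.
#' @param nNull null draws for the non-annealing metrics.
#' @param nNullModularity null draws for modularity.
#' @param seed integer seed governing draws and the annealing chains.
#' @param saParams annealing settings for the observed network; null draws
#'   are budget-matched to a single restart of the same schedule unless
#'   `saParamsNull` is given.
#' @param saParamsNull optional annealing settings for null draws.
#' @return data.frame with one row per metric: observed, null mean, null sd,
#'   `n_null`, `delta`, `n_rejected`.
#' @export
deltaTransform <- function(net,
                           metrics = c("connectance", "nodf", "modularity",
                                       "h2prime", "mean_dprime"),
                           nNull = 1000L, nNullModularity = 100L,
                           seed = 1L,
                           saParams = saParameters(),
                           saParamsNull = NULL) {
  stopifnot(is(net, "BipartiteNetwork"))
  metrics <- match.arg(metrics, several.ok = TRUE)
  if (nNull < 1 || nNullModularity < 1) stop("need at least one null draw")
  a <- interactionMatrix(net)
  r <- rowSums(a); cc <- colSums(a)
  if (is.null(saParamsNull)) {
    saParamsNull <- saParams
    saParamsNull$restarts <- 1L
  }
  nMax <- max(if (any(metrics == "modularity")) nNullModularity else 0L,
              if (any(metrics != "modularity")) nNull else 0L)
  draws <- patefieldNull(r, cc, n = nMax, seed = seed)
  bounds <- .marginBounds(r, cc, metrics)
  obsFuns <- .metricFunctions(saParams, seed, bounds)
  nullFuns <- .metricFunctions(saParamsNull, seed, bounds)
  rows <- lapply(metrics, function(met) {
    nWant <- if (met == "modularity") nNullModularity else nNull
    obs <- obsFuns[[met]](a, 0L)
    vals <- numeric(nWant)
    rejected <- 0L
    k <- 0L
    for (d in seq_len(nWant)) {
      val <- tryCatch(nullFuns[[met]](draws[[d]], d), error = function(e) NA_real_)
      while (is.na(val)) {           # defensive resampling path
        rejected <- rejected + 1L
        k <- k + 1L
        redraw <- patefieldNull(r, cc, n = 1, seed = seed + 7777L + k)[[1]]
        val <- tryCatch(nullFuns[[met]](redraw, d), error = function(e) NA_real_)
        if (rejected > 100L * nWant) stop("metric undefined on all null draws")
      }
      vals[d] <- val
    }
    data.frame(metric = met, observed = obs, null_mean = mean(vals),
               null_sd = sd(vals), n_null = nWant,
               delta = obs - mean(vals), n_rejected = rejected,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$site_id <- siteId(net)
  out$resolution <- netResolution(net)
  out
}
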