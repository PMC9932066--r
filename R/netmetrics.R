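#' Connectance of a quantitative bipartite network
#'
#' The proportion of realised links: number of non-zero cells divided by the
#' number of cells of the plant x visitor matrix.
#'
#' @param net a [BipartiteNetwork-class] or a count matrix.
#' @return a number in \[0, 1\].
#' @export
connectance <- function(net) {
  a <- if (is(net, "BipartiteNetwork")) interactionMatrix(net) else as.matrix(net)
  sum(a > 0) / length(a)
}

#' NODF nestedness
#'
#' Nestedness based on Overlap and Decreasing Fill, computed on the
#' binarised matrix. For every pair of rows (and every pair of columns) with
#' strictly different fills, the pair contributes
#' \eqn{100 \cdot o / \min(f_1, f_2)} where \eqn{o} is the number of shared
#' presences; pairs with equal fills contribute 0 (the strict decreasing-fill
#' rule). NODF is the mean contribution over all row pairs and column pairs,
#' on a 0--100 scale.
#'
#' @param net a [BipartiteNetwork-class] or matrix.
#' @return NODF in \[0, 100\].
#' @export
nodf <- function(net) {
  a <- if (is(net, "BipartiteNetwork")) interactionMatrix(net) else as.matrix(net)
  b <- (a > 0) * 1
  if (nrow(b) == 1L && ncol(b) == 1L) {
    stop("NODF is undefined for a 1x1 network")
  }
  pairedSum <- function(m) {        # rows of m are the entities compared
    n <- nrow(m)
    if (n < 2L) return(c(sum = 0, npair = 0))
    fill <- rowSums(m)
    ov <- m %*% t(m)                # shared presences
    s <- 0
    for (i in seq_len(n - 1L)) {
      for (k in (i + 1L):n) {
        if (fill[i] != fill[k]) {
          s <- s + 100 * ov[i, k] / min(fill[i], fill[k])
        }
      }
    }
    c(sum = s, npair = n * (n - 1) / 2)
  }
  rows <- pairedSum(b)
  cols <- pairedSum(t(b))
  as.numeric((rows["sum"] + cols["sum"]) / (rows["npair"] + cols["npair"]))
}

# Entropy bounds attainable by integer tables with the given margins.
# Exact by constrained enumeration when the table space is small; otherwise
# the continuous maximum (outer product of the margins) and a greedy
# largest-cell minimum, both standard heuristics for the H2' standardisation.
h2Bounds <- function(rowTotals, colTotals, exactLimit = 2e4) {
  tabs <- enumerateMarginTables(rowTotals, colTotals, limit = exactLimit)
  if (!is.null(tabs)) {
    hs <- vapply(tabs, shannonEntropy, numeric(1))
    return(list(min = min(hs), max = max(hs), exact = TRUE))
  }
  list(min = greedyMinEntropy(rowTotals, colTotals),
       max = shannonEntropy(rowTotals) + shannonEntropy(colTotals),
       exact = FALSE)
}

# Fill the largest remaining row/column margin pair first; yields a
# low-entropy (near-diagonal) table honouring the margins.
greedyMinEntropy <- function(rowTotals, colTotals) {
  r <- as.numeric(rowTotals); c <- as.numeric(colTotals)
  m <- sum(r)
  cells <- numeric(0)
  while (sum(r) > 0) {
    i <- which.max(r); j <- which.max(c)
    v <- min(r[i], c[j])
    cells <- c(cells, v)
    r[i] <- r[i] - v; c[j] <- c[j] - v
  }
  shannonEntropy(cells)
}

#' Network-level specialisation H2'
#'
#' The two-dimensional Shannon entropy of the interaction matrix,
#' standardised between the extreme entropies attainable under the observed
#' row and column totals: \eqn{H_2' = (H_{max} - H_2)/(H_{max} - H_{min})}.
#' 0 indicates maximal generalisation (interactions proportional to partner
#' availability), 1 maximal specialisation given the margins. Bounds are
#' computed exactly by margin-constrained enumeration when feasible and by
#' standard heuristics otherwise (see `Details`).
#'
#' @details For large networks the maximum entropy is taken as the entropy
#'   of the outer product of the margins (the continuous maximum) and the
#'   minimum from a greedy largest-cell allocation; the result is clamped to
#'   \[0, 1\]. A degenerate 1x1 network has no room for specialisation and
#'   returns 0 with attribute `degenerate = TRUE`.
#'
#' @param net a [BipartiteNetwork-class] or count matrix.
#' @param exactLimit maximum number of margin-consistent tables enumerated
#'   for the exact bounds before falling back to heuristics.
#' @return H2' in \[0, 1\].
#' @export
h2prime <- function(net, exactLimit = 2e4) {
  a <- if (is(net, "BipartiteNetwork")) interactionMatrix(net) else as.matrix(net)
  m <- sum(a)
  if (m < 1) stop("empty network")
  if (nrow(a) == 1L && ncol(a) == 1L) {
    return(structure(0, degenerate = TRUE))
  }
  b <- h2Bounds(rowSums(a), colSums(a), exactLimit = exactLimit)
  .h2FromBounds(a, b)
}

# H2' of a matrix given precomputed entropy bounds (bounds depend only on
# the margins, so they can be shared across fixed-margin null draws)
.h2FromBounds <- function(a, b) {
  h2 <- shannonEntropy(a)
  if (b$max - b$min < 1e-12) return(structure(0, degenerate = TRUE))
  min(1, max(0, (b$max - h2) / (b$max - b$min)))
}

# Kullback-Leibler divergence of an allocation x (visits per plant) from the
# availability distribution q, after normalising x.
klToAvailability <- function(x, q) {
  p <- x / sum(x)
  keep <- p > 0
  sum(p[keep] * log(p[keep] / q[keep]))
}

#' Species-level specialisation d' of flower visitors
#'
#' For visitor \eqn{j} with column total \eqn{A_j}, the raw index is the
#' Kullback-Leibler divergence between the visitor's use of plants
#' (\eqn{p'_{ij} = a_{ij}/A_j}) and plant availability
#' (\eqn{q_i = r_i / m}, the row totals). It is standardised between the
#' minimum and maximum divergence attainable by an integer allocation of
#' \eqn{A_j} visits with per-plant capacity \eqn{r_i}:
#' \eqn{d'_j = (d_j - d_{min}) / (d_{max} - d_{min})}, clamped to \[0, 1\].
#'
#' Bounds are exact (enumeration over capped allocations) when the
#' allocation space is small; otherwise \eqn{d_{max}} allocates visits to
#' plants in increasing order of availability and \eqn{d_{min}} uses
#' proportional allocation rounded by largest remainder.
#'
#' @param net a [BipartiteNetwork-class] or count matrix.
#' @param visitor optional visitor label or column index; default all.
#' @param exactLimit enumeration cap before the heuristic fallback.
#' @return named numeric vector of d' values in \[0, 1\].
#' @export
dprime <- function(net, visitor = NULL, exactLimit = 5e4) {
  a <- if (is(net, "BipartiteNetwork")) interactionMatrix(net) else as.matrix(net)
  m <- sum(a)
  r <- rowSums(a)
  q <- r / m
  cols <- if (is.null(visitor)) seq_len(ncol(a)) else visitor
  res <- vapply(cols, function(j) {
    x <- a[, j]
    A <- sum(x)
    if (A < 1) stop("visitor column with zero total")
    bounds <- dBounds(A, r, q, exactLimit = exactLimit)
    .dFromBounds(x, q, bounds)
  }, numeric(1))
  names(res) <- colnames(a)[if (is.character(cols)) match(cols, colnames(a)) else cols]
  res
}

.dFromBounds <- function(x, q, bounds) {
  d <- klToAvailability(x, q)
  if (bounds$max - bounds$min < 1e-12) return(0)
  min(1, max(0, (d - bounds$min) / (bounds$max - bounds$min)))
}

dBounds <- function(A, rowTotals, q, exactLimit = 5e4) {
  alloc <- enumerateCompositions(A, caps = rowTotals, limit = exactLimit)
  if (!is.null(alloc)) {
    ds <- apply(alloc, 1, klToAvailability, q = q)
    return(list(min = min(ds), max = max(ds), exact = TRUE))
  }
  # d_max: fill the rarest plants first, capped at their totals
  ord <- order(q)
  xmax <- numeric(length(q))
  rem <- A
  for (i in ord) {
    take <- min(rem, rowTotals[i])
    xmax[i] <- take
    rem <- rem - take
    if (rem == 0) break
  }
  # d_min: proportional allocation, largest-remainder rounding under caps
  target <- A * q
  xmin <- floor(target)
  rem <- A - sum(xmin)
  if (rem > 0) {
    pref <- order(target - xmin, decreasing = TRUE)
    for (i in pref) {
      if (rem == 0) break
      if (xmin[i] < rowTotals[i]) { xmin[i] <- xmin[i] + 1; rem <- rem - 1 }
    }
  }
  list(min = klToAvailability(xmin, q), max = klToAvailability(xmax, q),
       exact = FALSE)
}

#' Mean flower-visitor specialisation of a network
#'
#' The arithmetic mean of d' over visitor columns (optionally weighted by
#' the visitors' interaction totals).
#'
#' @inheritParams dprime
#' @param weighted weight visitors by their column totals (default FALSE:
#'   plain average over species, the convention followed throughout).
#' @export
meanDprime <- function(net, weighted = FALSE, exactLimit = 5e4) {
  a <- if (is(net, "BipartiteNetwork")) interactionMatrix(net) else as.matrix(net)
  d <- dprime(a, exactLimit = exactLimit)
  if (weighted) sum(d * colSums(a)) / sum(a) else mean(d)
}

#' All five network metrics of one network
#'
#' Convenience wrapper returning connectance, NODF, modularity Q (simulated
#' annealing), H2' and mean d' as a one-row data.frame; the modularity
#' partition is attached as attribute `"partition"`. NODF is NA (with a
#' warning suppressed to a flag) where undefined.
#'
#' @param net a [BipartiteNetwork-class].
#' @param saParams simulated-annealing settings, see [saParameters()].
#' @param seed integer seed for the modularity optimiser.
#' @export
networkMetrics <- function(net, saParams = saParameters(), seed = 1L) {
  a <- interactionMatrix(net)
  nodfVal <- if (nrow(a) == 1L && ncol(a) == 1L) NA_real_ else nodf(a)
  mod <- bipartiteModularity(net, saParams = saParams, seed = seed)
  out <- data.frame(
    site_id = siteId(net), resolution = netResolution(net),
    n_plants = nrow(a), n_visitors = ncol(a), m = sum(a),
    connectance = connectance(a), nodf = nodfVal, modularity = mod$Q,
    h2prime = as.numeric(h2prime(a)), mean_dprime = meanDprime(a),
    stringsAsFactors = FALSE)
  attr(out, "partition") <- mod[c("rowModules", "colModules")]
  out
}
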