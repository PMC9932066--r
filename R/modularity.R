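# Weighted bipartite (Barber-type) modularity maximised by simulated
# annealing over joint row/column module assignments, in the spirit of the
# QuanBiMo algorithm. Q(partition) = (1/m) * sum_ij [a_ij - r_i c_j / m]
# over plant-visitor pairs assigned to the same module.

#' Simulated-annealing settings for the modularity optimiser
#'
#' @param tempInit initial temperature on the Q*m scale; default NULL picks
#'   the largest absolute entry of the modularity matrix, which accepts
#'   roughly half of typical uphill moves early in the chain.
#' @param cooling geometric cooling factor in (0, 1).
#' @param stepsPerLevel proposals per temperature level; default
#'   `5 * (n_plants + n_visitors)`.
#' @param maxLevels hard cap on temperature levels.
#' @param patience stop after this many levels without improving the best Q.
#' @param restarts independent annealing chains; the best result is kept.
#' @param mergeProb probability that a proposal merges two modules instead
#'   of reassigning a single node.
#' @return a validated list of settings.
#' @export
saParameters <- function(tempInit = NULL, cooling = 0.99, stepsPerLevel = NULL,
                         maxLevels = 200L, patience = 25L, restarts = 3L,
                         mergeProb = 0.05) {
  if (!is.null(tempInit) && tempInit <= 0) stop("tempInit must be positive")
  if (cooling <= 0 || cooling >= 1) stop("cooling must be in (0,1)")
  if (!is.null(stepsPerLevel) && stepsPerLevel <= 0) {
    stop("step budget must be positive")
  }
  if (maxLevels <= 0) stop("step budget must be positive")
  if (restarts < 1) stop("restarts must be >= 1")
  list(tempInit = tempInit, cooling = cooling, stepsPerLevel = stepsPerLevel,
       maxLevels = as.integer(maxLevels), patience = as.integer(patience),
       restarts = as.integer(restarts), mergeProb = mergeProb)
}

#' Quantitative bipartite modularity by simulated annealing
#'
#' Maximises Barber's weighted bipartite modularity over joint assignments
#' of plants (rows) and visitors (columns) to modules. A plant-visitor pair
#' contributes \eqn{a_{ij} - r_i c_j / m} when both sit in the same module;
#' Q is the summed contribution divided by m. Proposals are single-node
#' reassignments plus occasional module merges, followed by a greedy
#' refinement sweep (alternating optimal reassignment of columns given rows
#' and vice versa) that polishes each chain to a local optimum. Reproducible
#' given `seed`.
#'
#' @param net a [BipartiteNetwork-class] or count matrix.
#' @param saParams see [saParameters()].
#' @param seed integer seed; chains use fixed offsets from it.
#' @return list with `Q`, `rowModules`, `colModules` (named integer module
#'   ids, renumbered consecutively), and `nModules`.
#' @export
bipartiteModularity <- function(net, saParams = saParameters(), seed = 1L) {
  a <- if (is(net, "BipartiteNetwork")) interactionMatrix(net) else as.matrix(net)
  m <- sum(a)
  if (m < 2) stop("modularity needs at least 2 interactions")
  R <- nrow(a); C <- ncol(a)
  B <- a - outer(rowSums(a), colSums(a)) / m
  Kmax <- min(R, C) + 1L
  steps <- saParams$stepsPerLevel %||% (5L * (R + C))
  best <- NULL
  for (k in seq_len(saParams$restarts)) {
    res <- withSeed(seed + 104729L * (k - 1L),
                    .saChain(B, m, Kmax, steps, saParams))
    if (is.null(best) || res$Qm > best$Qm + 1e-12) best <- res
  }
  relabel <- function(gr, gc) {
    ids <- unique(c(gr, gc))
    map <- setNames(seq_along(ids), ids)
    list(gr = unname(map[as.character(gr)]), gc = unname(map[as.character(gc)]))
  }
  lab <- relabel(best$gr, best$gc)
  list(Q = best$Qm / m,
       rowModules = setNames(lab$gr, rownames(a)),
       colModules = setNames(lab$gc, colnames(a)),
       nModules = length(unique(c(lab$gr, lab$gc))))
}

.saChain <- function(B, m, Kmax, steps, par) {
  R <- nrow(B); C <- ncol(B)
  gr <- sample.int(Kmax, R, replace = TRUE)
  gc <- sample.int(Kmax, C, replace = TRUE)
  # Srow[i, g]: affinity of row i to the columns currently in module g
  indic <- function(g, K, n) {
    M <- matrix(0, n, K); M[cbind(seq_len(n), g)] <- 1; M
  }
  Srow <- B %*% indic(gc, Kmax, C)
  Scol <- t(B) %*% indic(gr, Kmax, R)
  Qm <- sum(Srow[cbind(seq_len(R), gr)])
  temp <- par$tempInit %||% max(max(abs(B)), 1e-6)
  bestQm <- Qm; bestGr <- gr; bestGc <- gc
  sinceImp <- 0L
  for (level in seq_len(par$maxLevels)) {
    levelBest <- bestQm
    for (s in seq_len(steps)) {
      if (runif(1) < par$mergeProb) {
        occ <- unique(c(gr, gc))
        if (length(occ) < 2L) next
        ab <- sample(occ, 2L)
        a1 <- ab[1L]; b1 <- ab[2L]
        gain <- sum(Srow[gr == a1, b1]) + sum(Scol[gc == a1, b1])
        if (gain > 0 || runif(1) < exp(gain / temp)) {
          ri <- gr == a1; ci <- gc == a1
          gr[ri] <- b1; gc[ci] <- b1
          Srow[, b1] <- Srow[, b1] + Srow[, a1]; Srow[, a1] <- 0
          Scol[, b1] <- Scol[, b1] + Scol[, a1]; Scol[, a1] <- 0
          Qm <- Qm + gain
        }
      } else {
        v <- sample.int(R + C, 1L)
        tgt <- sample.int(Kmax, 1L)
        if (v <= R) {
          cur <- gr[v]
          if (tgt == cur) next
          gain <- Srow[v, tgt] - Srow[v, cur]
          if (gain > 0 || runif(1) < exp(gain / temp)) {
            gr[v] <- tgt
            Scol[, cur] <- Scol[, cur] - B[v, ]
            Scol[, tgt] <- Scol[, tgt] + B[v, ]
            Qm <- Qm + gain
          }
        } else {
          j <- v - R
          cur <- gc[j]
          if (tgt == cur) next
          gain <- Scol[j, tgt] - Scol[j, cur]
          if (gain > 0 || runif(1) < exp(gain / temp)) {
            gc[j] <- tgt
            Srow[, cur] <- Srow[, cur] - B[, j]
            Srow[, tgt] <- Srow[, tgt] + B[, j]
            Qm <- Qm + gain
          }
        }
      }
      if (Qm > bestQm + 1e-12) {
        bestQm <- Qm; bestGr <- gr; bestGc <- gc
      }
    }
    temp <- temp * par$cooling
    sinceImp <- if (bestQm > levelBest + 1e-12) 0L else sinceImp + 1L
    if (sinceImp >= par$patience) break
  }
  # polish the best state with alternating greedy reassignment
  ref <- .refinePartition(B, bestGr, bestGc, Kmax)
  ref
}

.refinePartition <- function(B, gr, gc, Kmax) {
  R <- nrow(B); C <- ncol(B)
  indic <- function(g, K, n) {
    M <- matrix(0, n, K); M[cbind(seq_len(n), g)] <- 1; M
  }
  Srow <- B %*% indic(gc, Kmax, C)
  Scol <- t(B) %*% indic(gr, Kmax, R)
  Qm <- sum(Srow[cbind(seq_len(R), gr)])
  for (sweep in seq_len(100L)) {
    moved <- FALSE
    for (j in seq_len(C)) {
      g <- which.max(Scol[j, ])
      if (Scol[j, g] > Scol[j, gc[j]] + 1e-12) {
        cur <- gc[j]; gc[j] <- g
        Srow[, cur] <- Srow[, cur] - B[, j]
        Srow[, g] <- Srow[, g] + B[, j]
        Qm <- Qm + Scol[j, g] - Scol[j, cur]
        moved <- TRUE
      }
    }
    for (i in seq_len(R)) {
      g <- which.max(Srow[i, ])
      if (Srow[i, g] > Srow[i, gr[i]] + 1e-12) {
        cur <- gr[i]; gr[i] <- g
        Scol[, cur] <- Scol[, cur] - B[i, ]
        Scol[, g] <- Scol[, g] + B[i, ]
        Qm <- Qm + Srow[i, g] - Srow[i, cur]
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  list(Qm = Qm, gr = gr, gc = gc)
}
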