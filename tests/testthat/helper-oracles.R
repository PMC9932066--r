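# Independent brute-force oracles. These deliberately avoid the package's
# internal code paths: plain loops, direct formulae, full enumeration.

# NODF straight from the pairwise definition
oracleNodf <- function(mat) {
  b <- (mat > 0) * 1
  contrib <- function(bb) {
    n <- nrow(bb)
    if (n < 2) return(c(0, 0))
    tot <- 0
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        fi <- sum(bb[i, ]); fj <- sum(bb[j, ])
        if (fi != fj) {
          shared <- sum(bb[i, ] == 1 & bb[j, ] == 1)
          tot <- tot + 100 * shared / min(fi, fj)
        }
      }
    }
    c(tot, choose(n, 2))
  }
  r <- contrib(b); cl <- contrib(t(b))
  (r[1] + cl[1]) / (r[2] + cl[2])
}

# every integer table with the given margins, depth-first over cells
oracleAllTables <- function(rs, cs) {
  R <- length(rs); C <- length(cs)
  out <- list()
  fill <- function(cells, rRem, cRem) {
    idx <- length(cells) + 1
    if (idx > R * C) {
      if (all(rRem == 0) && all(cRem == 0)) {
        out[[length(out) + 1]] <<- matrix(unlist(cells), R, C, byrow = TRUE)
      }
      return()
    }
    i <- ((idx - 1) %/% C) + 1
    j <- ((idx - 1) %% C) + 1
    for (v in 0:min(rRem[i], cRem[j])) {
      rr <- rRem; rr[i] <- rr[i] - v
      cc <- cRem; cc[j] <- cc[j] - v
      # prune: a completed row must have used up its margin
      if (j == C && rr[i] != 0) next
      fill(c(cells, v), rr, cc)
    }
  }
  fill(list(), rs, cs)
  out
}

oracleEntropy <- function(tab) {
  p <- tab[tab > 0] / sum(tab)
  -sum(p * log(p))
}

# exact H2' via exhaustive integer-table entropy extremes
oracleH2prime <- function(mat) {
  tabs <- oracleAllTables(rowSums(mat), colSums(mat))
  hs <- sapply(tabs, oracleEntropy)
  h <- oracleEntropy(mat)
  if (max(hs) - min(hs) < 1e-12) return(0)
  max(0, min(1, (max(hs) - h) / (max(hs) - min(hs))))
}

# exact d' for one visitor column via exhaustive capped allocations
oracleDprime <- function(mat, j) {
  rs <- rowSums(mat); m <- sum(mat); q <- rs / m
  A <- sum(mat[, j])
  kl <- function(x) {
    p <- x[x > 0] / sum(x)
    sum(p * log(p / q[x > 0]))
  }
  allocs <- list()
  gen <- function(i, rem, acc) {
    if (i > length(rs)) {
      if (rem == 0) allocs[[length(allocs) + 1]] <<- acc
      return()
    }
    for (v in 0:min(rem, rs[i])) gen(i + 1, rem - v, c(acc, v))
  }
  gen(1, A, integer(0))
  ds <- sapply(allocs, kl)
  d <- kl(mat[, j])
  if (max(ds) - min(ds) < 1e-12) return(0)
  max(0, min(1, (d - min(ds)) / (max(ds) - min(ds))))
}

# set partitions of 1..n (restricted-growth strings)
oracleSetPartitions <- function(n) {
  out <- list()
  grow <- function(code, maxUsed) {
    k <- length(code)
    if (k == n) {
      out[[length(out) + 1]] <<- code
      return()
    }
    for (g in 1:(maxUsed + 1)) grow(c(code, g), max(maxUsed, g))
  }
  grow(1L, 1L)
  out
}

# exact optimal Barber modularity: enumerate row partitions; given a row
# partition, each column independently joins its best module (or none)
oracleModularity <- function(mat) {
  m <- sum(mat)
  B <- mat - outer(rowSums(mat), colSums(mat)) / m
  best <- -Inf
  for (part in oracleSetPartitions(nrow(mat))) {
    K <- max(part)
    qm <- 0
    for (j in seq_len(ncol(mat))) {
      gains <- sapply(seq_len(K), function(g) sum(B[part == g, j]))
      qm <- qm + max(0, max(gains))
    }
    if (qm > best) best <- qm
  }
  best / m
}

# point-to-segment distance by direct projection arithmetic
oracleSegDist <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  if (dx == 0 && dy == 0) return(sqrt((px - ax)^2 + (py - ay)^2))
  t <- ((px - ax) * dx + (py - ay) * dy) / (dx^2 + dy^2)
  t <- max(0, min(1, t))
  sqrt((px - ax - t * dx)^2 + (py - ay - t * dy)^2)
}

# random small quantitative network guaranteed free of zero margins
randomSmallNet <- function(R, C, m) {
  repeat {
    a <- matrix(0, R, C)
    idx <- cbind(sample.int(R, m, replace = TRUE),
                 sample.int(C, m, replace = TRUE))
    for (k in seq_len(m)) a[idx[k, 1], idx[k, 2]] <- a[idx[k, 1], idx[k, 2]] + 1
    if (all(rowSums(a) > 0) && all(colSums(a) > 0)) {
      dimnames(a) <- list(sprintf("P%02d", seq_len(R)),
                          sprintf("V%02d", seq_len(C)))
      return(a)
    }
  }
}
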