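# Constrained integer enumeration used by the exact standardisation bounds
# of H2' and d'. Both functions return NULL when the space is (or may be)
# too large — a cheap uncapped-count precheck plus a hard budget on
# recursion steps — so callers can fall back to heuristics.

# All vectors x with 0 <= x_k <= caps_k and sum(x) = total.
# Returns a matrix with one composition per row, or NULL if more than
# `limit` compositions exist (or the uncapped count bound exceeds it).
enumerateCompositions <- function(total, caps, limit = 2e5) {
  k <- length(caps)
  total <- as.integer(round(total))
  caps <- as.integer(round(caps))
  # uncapped composition count bounds the capped one from above
  if (lchoose(total + k - 1, k - 1) > log(limit) + 1e-9) return(NULL)
  out <- vector("list", 1024L)
  n <- 0L
  overflow <- FALSE
  suffixCap <- c(rev(cumsum(rev(caps))), 0L)  # max allocatable from pos k on
  rec <- function(pos, rem, acc) {
    if (overflow) return()
    if (pos > k) {
      if (rem == 0L) {
        n <<- n + 1L
        if (n > limit) { overflow <<- TRUE; return() }
        if (n > length(out)) out[[2L * n]] <<- NULL  # grow
        out[[n]] <<- acc
      }
      return()
    }
    if (rem > suffixCap[pos]) return()
    hi <- min(caps[pos], rem)
    lo <- max(0L, rem - suffixCap[pos + 1L])
    if (lo > hi) return()
    for (v in lo:hi) rec(pos + 1L, rem - v, c(acc, v))
  }
  rec(1L, total, integer(0))
  if (overflow) return(NULL)
  do.call(rbind, out[seq_len(n)])
}

# All non-negative integer matrices with the given margins, as a list.
# NULL when more than `limit` tables exist or the search exceeds its
# step budget.
enumerateMarginTables <- function(rowTotals, colTotals, limit = 2e5,
                                  stepBudget = 50L * limit) {
  rowTotals <- as.integer(round(rowTotals))
  colTotals <- as.integer(round(colTotals))
  stopifnot(sum(rowTotals) == sum(colTotals))
  R <- length(rowTotals)
  C <- length(colTotals)
  # product of uncapped per-row composition counts bounds the table count;
  # generous threshold, the step budget below is the hard stop
  if (sum(lchoose(rowTotals + C - 1, C - 1)) > log(1e4 * limit)) return(NULL)
  tables <- vector("list", 256L)
  n <- 0L
  steps <- 0L
  overflow <- FALSE
  rec <- function(rowIdx, remCols, acc) {
    if (overflow) return()
    steps <<- steps + 1L
    if (steps > stepBudget) { overflow <<- TRUE; return() }
    if (rowIdx > R) {
      n <<- n + 1L
      if (n > limit) { overflow <<- TRUE; return() }
      if (n > length(tables)) tables[[2L * n]] <<- NULL
      tables[[n]] <<- do.call(rbind, acc)
      return()
    }
    rows <- enumerateCompositions(rowTotals[rowIdx], remCols, limit = limit)
    if (is.null(rows)) { overflow <<- TRUE; return() }
    for (i in seq_len(nrow(rows))) {
      rec(rowIdx + 1L, remCols - rows[i, ], c(acc, list(rows[i, ])))
    }
  }
  rec(1L, colTotals, list())
  if (overflow) return(NULL)
  tables[seq_len(n)]
}
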