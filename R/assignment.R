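# Injective atom assignment between two molecules: exact Hungarian solver
# and the fast greedy heuristic.

# O(n^3) Hungarian algorithm (potentials + augmenting paths) for the square
# MINIMUM-cost assignment.  cost: n x n matrix.  Returns for each row the
# assigned column.
.hungarian_min <- function(cost) {
  n <- nrow(cost)
  INF <- Inf
  u <- numeric(n + 1L)
  v <- numeric(n + 1L)
  p <- integer(n + 1L)      # p[j]: row assigned to column j (0 = none)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 1L                # columns are offset by 1; column 1 is virtual
    minv <- rep(INF, n + 1L)
    used <- logical(n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- INF
      j1 <- 0L
      for (j in 2L:(n + 1L)) {
        if (used[j]) next
        cur <- cost[i0, j - 1L] - u[i0] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in seq_len(n + 1L)) {
        if (used[j]) {
          u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  assign_row <- integer(n)
  for (j in 2L:(n + 1L)) if (p[j] > 0L) assign_row[p[j]] <- j - 1L
  assign_row
}

# Maximum-sum injective assignment of rows to columns of a rectangular
# similarity matrix.  Pads to square with zeros; every row/column of the
# smaller side ends up matched.  Returns 2-column matrix (row, col) with
# min(dim) pairs, ordered by row index of the smaller dimension.
.assign_hungarian <- function(sim) {
  nr <- nrow(sim)
  nc <- ncol(sim)
  n <- max(nr, nc)
  cost <- matrix(0, n, n)
  cost[seq_len(nr), seq_len(nc)] <- -sim
  col_of <- .hungarian_min(cost)
  if (nr <= nc) {
    cbind(row = seq_len(nr), col = col_of[seq_len(nr)])
  } else {
    keep <- which(col_of <= nc)
    m <- cbind(row = keep, col = col_of[keep])
    m[order(m[, 1L]), , drop = FALSE]
  }
}

# Greedy heuristic: repeatedly map the two atoms with the highest remaining
# similarity, then delete that row and column.  Ties are broken by the
# order of the atoms in the input molecules: smallest row index first,
# then smallest column index.
.assign_greedy <- function(sim) {
  nr <- nrow(sim)
  nc <- ncol(sim)
  k <- min(nr, nc)
  pairs <- matrix(0L, k, 2L, dimnames = list(NULL, c("row", "col")))
  act_r <- rep(TRUE, nr)
  act_c <- rep(TRUE, nc)
  for (t in seq_len(k)) {
    sub <- sim[act_r, act_c, drop = FALSE]
    best <- max(sub)
    hits <- which(sub == best, arr.ind = TRUE)
    hits <- hits[order(hits[, 1L], hits[, 2L]), , drop = FALSE]
    r <- which(act_r)[hits[1L, 1L]]
    c <- which(act_c)[hits[1L, 2L]]
    pairs[t, ] <- c(r, c)
    act_r[r] <- FALSE
    act_c[c] <- FALSE
  }
  pairs[order(pairs[, 1L]), , drop = FALSE]
}

#' Map atoms between two molecules from their similarity matrix
#'
#' Finds an injective assignment of the atoms of the smaller molecule
#' (rows when `nrow <= ncol`) onto atoms of the larger one.
#' `method = "hungarian"` maximizes the summed atom-pair similarity exactly
#' (the assignment problem); `method = "greedy"` iteratively picks the
#' largest remaining matrix entry and removes its row and column, breaking
#' ties by input atom order (smallest row index, then smallest column
#' index).  The greedy sum is never larger than the Hungarian sum.
#'
#' @param sim Numeric matrix of atom-pair similarities (rows: molecule A,
#'   columns: molecule B), e.g. from [build_similarity_matrix()].
#' @param method `"greedy"` (default) or `"hungarian"`.
#' @return An `aap_mapping`: data frame with columns `a` (row index), `b`
#'   (column index) and `sim`, one row per mapped pair
#'   (`min(nrow, ncol)` pairs), plus attribute `method`.
#' @export
map_atoms <- function(sim, method = c("greedy", "hungarian")) {
  method <- match.arg(method)
  if (!is.matrix(sim) || !length(sim)) stop("sim must be a non-empty matrix")
  pairs <- if (method == "hungarian") .assign_hungarian(sim)
           else .assign_greedy(sim)
  out <- data.frame(a = as.integer(pairs[, 1L]), b = as.integer(pairs[, 2L]),
                    sim = sim[pairs])
  attr(out, "method") <- method
  class(out) <- c("aap_mapping", "data.frame")
  out
}
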