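## Square linear assignment by shortest augmenting paths (Jonker-Volgenant
## potentials), O(n^3). Written in-package because no assignment solver is
## available among the installed dependencies; oracle-tested against
## exhaustive enumeration of all permutations for small n.

#' Solve a square linear assignment problem
#'
#' @param cost square numeric cost matrix (finite entries).
#' @return integer vector `a` with `a[i]` the column assigned to row `i`,
#'   minimizing `sum(cost[cbind(seq_len(n), a)])`.
#' @keywords internal
solveLAP <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n, all(is.finite(cost)))
  if (n == 0) return(integer(0))
  u <- numeric(n)        # row potentials
  v <- numeric(n + 1)    # column potentials; index 1 is the virtual column
  p <- integer(n + 1)    # p[j]: row currently assigned to column j - 1
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf; j1 <- 0
      for (j in seq.int(2, n + 1)) {
        if (used[j]) next
        cur <- cost[i0, j - 1] - u[i0] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in seq_len(n + 1)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1) break
    }
  }
  a <- integer(n)
  for (j in seq.int(2, n + 1)) if (p[j] > 0) a[p[j]] <- j - 1L
  a
}

## Gated rectangular assignment with a non-link alternative: rows and
## columns may stay unassigned at cost `alt`; pairs with cost > gate2 are
## forbidden. Returns an integer vector: for each row, the matched column
## or NA.
gatedAssign <- function(cost, gate2) {
  n1 <- nrow(cost); n2 <- ncol(cost)
  if (n1 == 0 || n2 == 0) return(rep(NA_integer_, n1))
  BIG <- max(gate2, 1) * 1e6
  alt <- gate2 * 1.05
  M <- matrix(BIG, n1 + n2, n1 + n2)
  blocked <- cost > gate2
  top <- cost
  top[blocked] <- BIG
  M[seq_len(n1), seq_len(n2)] <- top
  M[seq_len(n1), n2 + seq_len(n1)] <- BIG
  for (i in seq_len(n1)) M[i, n2 + i] <- alt
  for (j in seq_len(n2)) M[n1 + j, j] <- alt
  M[n1 + seq_len(n2), n2 + seq_len(n1)] <- 0
  a <- solveLAP(M)
  match_ <- a[seq_len(n1)]
  match_[match_ > n2] <- NA_integer_
  ## safety: a forbidden pair must never be selected
  sel <- !is.na(match_)
  if (any(sel) && any(blocked[cbind(which(sel), match_[sel])]))
    match_[which(sel)[blocked[cbind(which(sel), match_[sel])]]] <- NA_integer_
  match_
}
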