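# Minimum-cost linear assignment (Kuhn-Munkres / Jonker-Volgenant style
# shortest augmenting paths with dual potentials).  Rectangular problems
# with nrow <= ncol assign every row; O(n * m^2).  Written here because no
# installed package exposes a min-cost LAP; cross-checked against a
# brute-force permutation oracle in the test suite.
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost)
  m <- ncol(cost)
  if (n == 0L) return(list(assignment = integer(0), cost = 0))
  if (n > m) stop("assignment needs nrow <= ncol")
  u <- numeric(n)
  v <- numeric(m + 1L)       # index 1 is the virtual column
  p <- integer(m + 1L)       # p[j]: row matched to column j-1 (0 = free)
  way <- integer(m + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 1L
    minv <- rep(Inf, m + 1L)
    used <- rep(FALSE, m + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      free_j <- which(!used)
      free_j <- free_j[free_j >= 2L]
      cur <- cost[i0, free_j - 1L] - u[i0] - v[free_j]
      upd <- cur < minv[free_j]
      if (any(upd)) {
        minv[free_j[upd]] <- cur[upd]
        way[free_j[upd]] <- j0
      }
      k <- which.min(minv[free_j])
      delta <- minv[free_j][k]
      j1 <- free_j[k]
      usel <- which(used)
      u[p[usel]] <- u[p[usel]] + delta
      v[usel] <- v[usel] - delta
      minv[!used] <- minv[!used] - delta
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
  assignment <- integer(n)
  for (j in 2:(m + 1L)) if (p[j] > 0L) assignment[p[j]] <- j - 1L
  list(assignment = assignment,
       cost = sum(cost[cbind(seq_len(n), assignment)]))
}
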