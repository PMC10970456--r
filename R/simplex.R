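# Dense two-phase primal simplex. The DEA programs solved here are small
# (at most a few hundred variables, a dozen rows in the envelopment form;
# the transpose shape in the multiplier form), so a tableau method with
# full artificial start is both adequate and easy to audit.

#' Solve a small linear program
#'
#' Minimizes `obj %*% x` subject to `A x (dir) rhs` and `x >= 0`, where each
#' element of `dir` is one of `"<="`, `">="`, `"="`. A two-phase tableau
#' simplex is used: phase 1 starts from a full artificial basis and drives the
#' infeasibility to zero, phase 2 optimizes the true objective. Dantzig
#' pricing switches to Bland's rule after half the iteration budget so cycling
#' cannot occur.
#'
#' @param obj numeric objective coefficients (length = number of variables).
#' @param A constraint matrix, one row per constraint.
#' @param dir character vector of constraint directions.
#' @param rhs numeric right-hand sides.
#' @param tol pivot / reduced-cost tolerance.
#' @param max_iter iteration budget shared by both phases.
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"` or
#'   `"iteration_limit"`), and for optimal solves `x` and `objval`.
#' @keywords internal
#' @noRd
lp_solve <- function(obj, A, dir, rhs, tol = 1e-9, max_iter = 20000L) {
  A <- as.matrix(A)
  m <- nrow(A)
  n <- ncol(A)
  stopifnot(length(obj) == n, length(dir) == m, length(rhs) == m,
            all(dir %in% c("<=", ">=", "=")))

  # slack / surplus columns
  n_slack <- sum(dir != "=")
  S <- matrix(0, m, n_slack)
  j <- 0L
  for (i in seq_len(m)) {
    if (dir[i] != "=") {
      j <- j + 1L
      S[i, j] <- if (dir[i] == "<=") 1 else -1
    }
  }
  Ae <- cbind(A, S)
  b <- rhs
  neg <- b < 0
  if (any(neg)) {
    Ae[neg, ] <- -Ae[neg, , drop = FALSE]
    b[neg] <- -b[neg]
  }
  nt <- ncol(Ae)

  tab <- cbind(Ae, diag(m), b)   # artificial basis start
  basis <- nt + seq_len(m)
  ncols <- nt + m

  # minimizes cost over the first `nv` columns of tab; rhs is the last column
  run <- function(tab, basis, cost, nv) {
    mm <- nrow(tab)
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > max_iter) return(list(status = "iteration_limit"))
      bland <- it > max_iter %/% 2L
      z <- drop(cost[basis] %*% tab[, seq_len(nv), drop = FALSE]) -
        cost[seq_len(nv)]
      cand <- which(z > tol)
      if (!length(cand)) {
        return(list(status = "optimal", tab = tab, basis = basis))
      }
      pc <- if (bland) cand[1L] else cand[which.max(z[cand])]
      col <- tab[, pc]
      pos <- which(col > tol)
      if (!length(pos)) return(list(status = "unbounded"))
      ratio <- tab[pos, ncol(tab)] / col[pos]
      pr <- pos[which.min(ratio)]
      tab[pr, ] <- tab[pr, ] / tab[pr, pc]
      oth <- setdiff(seq_len(mm), pr)
      if (length(oth)) {
        tab[oth, ] <- tab[oth, ] - outer(tab[oth, pc], tab[pr, ])
      }
      basis[pr] <- pc
    }
  }

  cost1 <- c(rep(0, nt), rep(1, m))
  r1 <- run(tab, basis, cost1, ncols)
  if (r1$status != "optimal") {
    return(list(status = if (r1$status == "unbounded") "infeasible" else r1$status))
  }
  infeas <- sum(cost1[r1$basis] * r1$tab[, ncols + 1L])
  if (infeas > 1e-7) return(list(status = "infeasible"))
  tab <- r1$tab
  basis <- r1$basis

  # pivot any zero-level artificials out on a structural column when possible
  for (i in which(basis > nt)) {
    row <- tab[i, seq_len(nt)]
    pc <- which(abs(row) > tol)
    if (length(pc)) {
      pc <- pc[1L]
      tab[i, ] <- tab[i, ] / tab[i, pc]
      oth <- setdiff(seq_len(nrow(tab)), i)
      if (length(oth)) {
        tab[oth, ] <- tab[oth, ] - outer(tab[oth, pc], tab[i, ])
      }
      basis[i] <- pc
    }
  }
  keep <- basis <= nt     # rows still pinned to an artificial are redundant
  tab <- tab[keep, , drop = FALSE]
  basis <- basis[keep]

  tab2 <- tab[, c(seq_len(nt), ncols + 1L), drop = FALSE]
  cost2 <- c(obj, rep(0, nt - n))
  r2 <- run(tab2, basis, cost2, nt)
  if (r2$status != "optimal") return(list(status = r2$status))
  x <- numeric(nt)
  x[r2$basis] <- r2$tab[, nt + 1L]
  x <- x[seq_len(n)]
  list(status = "optimal", x = x, objval = sum(obj * x))
}
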