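#' Dense two-phase simplex solver
#'
#' Solves `maximize c'x subject to A x (dir) b, x >= 0` with a dense
#' two-phase tableau simplex using Bland's anti-cycling pivot rule, so the
#' method terminates on every input and repeated runs are bit-identical.
#' This is the linear-programming engine underneath [fba_solve()]; it is
#' exported because the brute-force oracles in the test suite and the
#' epsilon-constraint sampler drive it directly.
#'
#' Bland's rule is slower than Dantzig pricing but immune to degeneracy
#' cycling, which matters here: stoichiometric equality blocks make flux
#' polytopes highly degenerate.
#'
#' @param c_obj numeric objective coefficients (maximized).
#' @param A constraint matrix (dense).
#' @param b right-hand sides.
#' @param dir character vector of `"<="`, `">="`, `"="` per row.
#' @param tol pivot tolerance.
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`),
#'   `x` (primal solution, `NULL` unless optimal) and `value`.
#' @keywords internal
#' @export
simplex_solve <- function(c_obj, A, b, dir, tol = 1e-9) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(b) == m, length(dir) == m, length(c_obj) == n,
            all(dir %in% c("<=", ">=", "=")))
  neg <- b < 0
  if (any(neg)) {
    A[neg, ] <- -A[neg, , drop = FALSE]
    b[neg] <- -b[neg]
    dir[neg] <- c("<=" = ">=", ">=" = "<=", "=" = "=")[dir[neg]]
  }
  n_slack <- sum(dir != "=")
  S <- matrix(0, m, n_slack)
  j <- 0L
  slack_basic <- rep(NA_integer_, m)
  for (i in seq_len(m)) {
    if (dir[i] == "<=") { j <- j + 1L; S[i, j] <- 1;  slack_basic[i] <- n + j }
    else if (dir[i] == ">=") { j <- j + 1L; S[i, j] <- -1 }
  }
  Af <- cbind(A, S)
  nf <- n + n_slack
  need_art <- which(is.na(slack_basic))
  n_art <- length(need_art)
  Art <- matrix(0, m, n_art)
  basis <- slack_basic
  for (k in seq_along(need_art)) {
    Art[need_art[k], k] <- 1
    basis[need_art[k]] <- nf + k
  }
  Tm <- cbind(Af, Art)
  ntot <- nf + n_art
  rhs <- b

  pivot <- function(r, s) {
    piv <- Tm[r, s]
    Tm[r, ] <<- Tm[r, ] / piv
    rhs[r] <<- rhs[r] / piv
    hit <- which(abs(Tm[, s]) > 0)
    hit <- hit[hit != r]
    if (length(hit)) {
      f <- Tm[hit, s]
      Tm[hit, ] <<- Tm[hit, , drop = FALSE] - outer(f, Tm[r, ])
      rhs[hit] <<- rhs[hit] - f * rhs[r]
    }
    basis[r] <<- s
    invisible(NULL)
  }
  run_phase <- function(obj, allowed) {
    repeat {
      red <- as.numeric(obj[basis] %*% Tm) - obj
      red[basis] <- 0
      enter <- which(allowed & red < -tol)
      if (!length(enter)) return("optimal")
      s <- min(enter)                              # Bland: smallest index enters
      col <- Tm[, s]
      pos <- which(col > tol)
      if (!length(pos)) return("unbounded")
      ratio <- rhs[pos] / col[pos]
      rmin <- min(ratio)
      tie <- pos[ratio <= rmin + tol]
      pivot(tie[which.min(basis[tie])], s)         # Bland: smallest basis leaves
    }
  }

  allowed <- rep(TRUE, ntot)
  if (n_art > 0) {
    st1 <- run_phase(c(rep(0, nf), rep(-1, n_art)), allowed)
    infeas <- sum(rhs[basis > nf])
    if (st1 != "optimal" || infeas > 1e-7 * max(1, max(abs(b))))
      return(list(status = "infeasible", x = NULL, value = NA_real_))
    for (i in which(basis > nf)) {                 # drive artificials out
      s_cand <- which(abs(Tm[i, seq_len(nf)]) > tol)
      if (length(s_cand)) pivot(i, min(s_cand))
    }
    allowed[(nf + 1):ntot] <- FALSE
  }
  st2 <- run_phase(c(c_obj, rep(0, ntot - n)), allowed)
  if (st2 == "unbounded")
    return(list(status = "unbounded", x = NULL, value = NA_real_))
  x <- numeric(ntot)
  x[basis] <- rhs
  x <- x[seq_len(n)]
  list(status = "optimal", x = x, value = sum(c_obj * x))
}
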