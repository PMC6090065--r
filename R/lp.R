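# Dense bounded-variable revised simplex:
#   minimize c'x  subject to  A x = b,  l <= x <= u  (l, u finite).
# Phase 1 adds signed artificial columns and drives their sum to zero; the
# artificials then stay in the problem with bounds fixed at 0, so no
# pivot-out step is needed even when they remain basic at zero level
# (degenerate problems). Pricing is Dantzig for speed, switching to Bland's
# rule after `bland_after` iterations to guarantee termination; the basis
# inverse is kept by rank-1 updates and refactorized periodically. Model
# sizes here are tens of variables, so dense O(m^2) updates are fine.

lp_bounded <- function(A, b, cost, l, u, tol = 1e-9, max_iter = 20000L,
                       bland_after = 2000L, refactor_every = 60L) {
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(b) == m, length(cost) == n, length(l) == n, length(u) == n)
  if (any(l > u + tol))
    return(list(status = "infeasible", x = NULL, value = NA_real_))

  # start structural variables at the bound of smaller magnitude
  x0 <- ifelse(abs(l) <= abs(u), l, u)
  r <- as.vector(b - A %*% x0)
  sgn <- ifelse(r >= 0, 1, -1)
  Af <- cbind(A, diag(sgn, m))
  nf <- n + m
  state <- list(
    xf = c(x0, abs(r)),
    at_upper = c(abs(l) > abs(u), rep(FALSE, m)),
    basis = n + seq_len(m),
    Binv = diag(1 / sgn, m))
  lf <- c(l, rep(0, m))
  uf <- c(u, pmax(abs(r), 0))

  run <- function(cvec, st, lf, uf) {
    xf <- st$xf; at_upper <- st$at_upper; basis <- st$basis; Binv <- st$Binv
    since <- 0L
    for (it in seq_len(max_iter)) {
      if (since >= refactor_every) {
        Binv <- tryCatch(solve(Af[, basis, drop = FALSE]),
                         error = function(e) NULL)
        if (is.null(Binv)) return(list(status = "singular"))
        xf[basis] <- as.vector(
          Binv %*% (b - Af[, -basis, drop = FALSE] %*% xf[-basis]))
        since <- 0L
      }
      y <- as.vector(crossprod(Binv, cvec[basis]))
      nb <- setdiff(seq_len(nf), basis)
      nb <- nb[uf[nb] - lf[nb] > tol]            # fixed vars never enter
      if (length(nb)) {
        d <- cvec[nb] - as.vector(y %*% Af[, nb, drop = FALSE])
        elig <- which((!at_upper[nb] & d < -tol) | (at_upper[nb] & d > tol))
      } else elig <- integer()
      if (!length(elig))
        return(list(status = "optimal", xf = xf, at_upper = at_upper,
                    basis = basis, Binv = Binv))
      pick <- if (it > bland_after) elig[which.min(nb[elig])]
      else elig[which.max(abs(d[elig]))]
      e <- nb[pick]
      dir <- if (at_upper[e]) -1 else 1           # entering moves off its bound
      w <- as.vector(Binv %*% Af[, e]) * dir      # x_B changes by -w * t
      # ratio test
      t_i <- rep(Inf, m)
      to_upper <- logical(m)
      pos <- w > tol; neg <- w < -tol
      t_i[pos] <- (xf[basis[pos]] - lf[basis[pos]]) / w[pos]
      t_i[neg] <- (uf[basis[neg]] - xf[basis[neg]]) / (-w[neg])
      to_upper[neg] <- TRUE
      t_bound <- uf[e] - lf[e]
      t_star <- min(t_bound, t_i)
      if (!is.finite(t_star)) return(list(status = "unbounded"))
      t_star <- max(t_star, 0)
      blockers <- which(t_i <= t_star + tol)
      if (length(blockers) == 0L || t_bound < min(t_i) - tol) {
        # entering variable flips to its other bound; basis unchanged
        xf[basis] <- xf[basis] - w * t_bound
        xf[e] <- if (at_upper[e]) lf[e] else uf[e]
        at_upper[e] <- !at_upper[e]
        next
      }
      leave <- if (it > bland_after) blockers[which.min(basis[blockers])]
      else blockers[which.max(abs(w[blockers]))]
      xf[basis] <- xf[basis] - w * t_star
      xf[e] <- xf[e] + dir * t_star
      lv <- basis[leave]
      xf[lv] <- if (to_upper[leave]) uf[lv] else lf[lv]
      at_upper[lv] <- to_upper[leave]
      basis[leave] <- e
      wcol <- w * dir                             # Binv %*% Af[, e]
      piv <- wcol[leave]
      if (abs(piv) < 1e-11) {
        Binv <- tryCatch(solve(Af[, basis, drop = FALSE]),
                         error = function(er) NULL)
        if (is.null(Binv)) return(list(status = "singular"))
        since <- 0L
      } else {
        Brow <- Binv[leave, ] / piv
        Binv <- Binv - outer(wcol, Brow)
        Binv[leave, ] <- Brow
        since <- since + 1L
      }
    }
    list(status = "maxiter")
  }

  p1 <- run(c(rep(0, n), rep(1, m)), state, lf, uf)
  if (p1$status != "optimal")
    return(list(status = p1$status, x = NULL, value = NA_real_))
  if (sum(p1$xf[n + seq_len(m)]) > 1e-7)
    return(list(status = "infeasible", x = NULL, value = NA_real_))
  uf[n + seq_len(m)] <- 0                         # artificials pinned at 0
  p1$xf[n + seq_len(m)] <- 0
  p2 <- run(c(cost, rep(0, m)), p1, lf, uf)
  if (p2$status != "optimal")
    return(list(status = p2$status, x = NULL, value = NA_real_))
  x_out <- p2$xf[seq_len(n)]
  list(status = "optimal", x = pmin(pmax(x_out, l), u),
       value = sum(cost * x_out))
}
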