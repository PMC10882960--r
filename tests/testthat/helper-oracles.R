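# Independent numerical oracles used by the tests. These never call the code
# paths they check.

# Marginal log-likelihood of the NB mixed model by Gauss-Hermite product
# quadrature over the random effects, for two grouping factors with at most
# two levels each. The likelihood decomposes over (factor1 level, factor2
# level) cells, each depending only on the sum of its two intercepts, so the
# quadrature grid is assembled from per-cell curves.
gh_marginal_loglik <- function(y, eta_fixed, f1, f2, theta, sd1, sd2,
                               ngh = 40) {
  stopifnot(nlevels(f1) <= 2, nlevels(f2) <= 2)
  gh <- pracma::gaussHermite(ngh)
  z <- gh$x * sqrt(2)
  lw <- log(gh$w / sqrt(pi))
  n1 <- nlevels(f1); n2 <- nlevels(f2)
  # per-cell loglik on the (u-node, v-node) grid
  cell <- function(a, b) {
    idx <- which(as.integer(f1) == a & as.integer(f2) == b)
    m <- matrix(0, ngh, ngh)
    if (!length(idx)) return(m)
    for (i in seq_len(ngh)) {
      eta <- outer(eta_fixed[idx], z[i] * sd1 + z * sd2, "+")
      m[i, ] <- colSums(dnbinom(matrix(y[idx], length(idx), ngh),
                                mu = exp(eta), size = theta, log = TRUE))
    }
    m
  }
  cells <- lapply(seq_len(n1), function(a) {
    lapply(seq_len(n2), function(b) cell(a, b))
  })
  # sum over all node combinations of the u-vector (length n1) and v-vector
  # (length n2); with <= 2 levels each this is at most ngh^4 terms
  u_idx <- as.matrix(do.call(expand.grid, rep(list(seq_len(ngh)), n1)))
  v_idx <- as.matrix(do.call(expand.grid, rep(list(seq_len(ngh)), n2)))
  total <- -Inf
  for (r in seq_len(nrow(u_idx))) {
    ll_rows <- matrix(0, nrow(v_idx), 1)
    for (a in seq_len(n1)) {
      for (b in seq_len(n2)) {
        ll_rows <- ll_rows + cells[[a]][[b]][u_idx[r, a], v_idx[, b]]
      }
    }
    lw_v <- rowSums(matrix(lw[v_idx], nrow(v_idx), n2))
    ll_all <- ll_rows + lw_v + sum(lw[u_idx[r, ]])
    m <- max(ll_all, total)
    total <- m + log(exp(total - m) + sum(exp(ll_all - m)))
  }
  total
}

# Closed-form normal-equations solution of the zero-intercept quadratic
# regression mass ~ c1 * money + c2 * money^2.
backcast_normal_equations <- function(money, mass) {
  X <- cbind(money, money^2)
  solve(t(X) %*% X, t(X) %*% mass)[, 1]
}

# Exhaustive weighted check-loss minimisation over all point-pair lines,
# written independently of the package solver (loop form, explicit loss).
wqr_brute_force <- function(x, y, w, tau) {
  check_loss <- function(a, b) {
    r <- y - a - b * x
    sum(w * r * (tau - as.numeric(r < 0)))
  }
  best <- list(loss = Inf)
  n <- length(x)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (x[i] == x[j]) next
      b <- (y[j] - y[i]) / (x[j] - x[i])
      a <- y[i] - b * x[i]
      l <- check_loss(a, b)
      if (l < best$loss - 1e-12 ||
          (abs(l - best$loss) <= 1e-12 && b < best$slope)) {
        best <- list(loss = l, intercept = a, slope = b)
      }
    }
  }
  best
}

# Transformed design recomputed from scratch (log1p trade, raw distance,
# log species counts, then the stored scaling constants).
panel_design_oracle <- function(panel, scaling) {
  raw <- data.frame(
    log_tr = log1p(panel$TR), distance = panel$D,
    log_s_e = log(panel$S_e), log_s_i = log(panel$S_i)
  )
  for (v in names(raw)) {
    s <- scaling[[v]]
    raw[[v]] <- (raw[[v]] - s[["mean"]]) / s[["sd"]]
  }
  raw
}
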