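# Independent oracles used across tests. These deliberately take different
# algorithmic routes from the package code they check.

# Cormack-Jolly-Seber likelihood via the classical chi ("never seen again")
# closed form, written against y-vectors only. Parameters: survival S
# (scalar) and recapture p (scalar or per-period vector, p[1] unused).
cjs_loglik <- function(histories, S, p) {
  T <- attr(histories, "n_periods")
  p <- rep_len(p, T)
  chi <- numeric(T)
  chi[T] <- 1
  if (T >= 2) {
    for (t in (T - 1):1) chi[t] <- 1 - S + S * (1 - p[t + 1]) * chi[t + 1]
  }
  ll <- 0
  for (i in seq_len(nrow(histories))) {
    y <- as.integer(strsplit(histories$y[i], "")[[1]])
    occ <- which(y == 1)
    f <- occ[1]
    last <- occ[length(occ)]
    pr <- 1
    if (last > f) {
      for (t in (f + 1):last) {
        pr <- pr * S * (if (y[t] == 1) p[t] else 1 - p[t])
      }
    }
    pr <- pr * chi[last]
    ll <- ll + histories$n[i] * log(pr)
  }
  ll
}

# Maximize the CJS likelihood over constant S and constant or per-period p.
cjs_fit <- function(histories, p_structure = c("constant", "year")) {
  p_structure <- match.arg(p_structure)
  T <- attr(histories, "n_periods")
  n_p <- if (p_structure == "year") T - 1 else 1
  nll <- function(theta) {
    S <- plogis(theta[1])
    p <- plogis(theta[1 + seq_len(n_p)])
    p_full <- c(NA, rep_len(p, T - 1))
    -cjs_loglik(histories, S, p_full)
  }
  opt <- optim(rep(0, 1 + n_p), nll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  list(S = plogis(opt$par[1]), p = plogis(opt$par[1 + seq_len(n_p)]),
       logLik = -opt$value, convergence = opt$convergence)
}

# All possible (y, z) completions of a history released at period f.
enumerate_completions <- function(T, f) {
  n_y <- T - f
  n_z <- T - f
  out <- list()
  for (iy in 0:(2^n_y - 1)) {
    for (iz in 0:(2^n_z - 1)) {
      y <- integer(T)
      y[f] <- 1L
      if (n_y > 0) y[(f + 1):T] <- as.integer(intToBits(iy))[seq_len(n_y)]
      z <- integer(max(T - 1, 0))
      if (n_z > 0) z[f:(T - 1)] <- as.integer(intToBits(iz))[seq_len(n_z)]
      out[[length(out) + 1L]] <- list(f = f, y = y, z = z)
    }
  }
  out
}

# Sum of history probabilities over every completion; 1 for a proper model.
completion_total <- function(T, f, params) {
  sum(vapply(
    enumerate_completions(T, f),
    function(h) history_probability(h, params),
    numeric(1)
  ))
}
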