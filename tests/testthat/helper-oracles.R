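# Independent brute-force oracles used by both the unit and acceptance tests.
# These recompute the quantities under test from their definitions, with no
# shared code paths with the package internals.

# median of all pairwise slopes (y_j - y_i)/(t_j - t_i), i < j, t_i != t_j
oracle_theil_sen <- function(t, y) {
  n <- length(t)
  slopes <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (t[j] != t[i]) slopes <- c(slopes, (y[j] - y[i]) / (t[j] - t[i]))
    }
  }
  stats::median(slopes)
}

# dense-matrix Gaussian log-likelihood of a single AR(1) series:
# V = sigma2 * R(phi), R_ij = phi^|t_i - t_j|
oracle_ar1_loglik <- function(y, X, beta, sigma2, phi, times) {
  r <- y - as.numeric(X %*% beta)
  R <- phi^abs(outer(times, times, "-"))
  V <- sigma2 * R
  n <- length(y)
  -n / 2 * log(2 * pi) - 0.5 * determinant(V, logarithm = TRUE)$modulus -
    0.5 * as.numeric(t(r) %*% solve(V) %*% r)
}

# powerset of mains and interactions, filtered by the marginality rule
oracle_enumerate <- function(mains, interactions, marginality = TRUE) {
  terms <- c(mains, interactions)
  parents <- strsplit(interactions, ":", fixed = TRUE)
  out <- list()
  for (mask in 0:(2^length(terms) - 1)) {
    present <- terms[bitwAnd(mask, 2^(seq_along(terms) - 1)) > 0]
    if (marginality) {
      ok <- TRUE
      for (k in seq_along(interactions)) {
        if (interactions[k] %in% present && !all(parents[[k]] %in% present)) {
          ok <- FALSE
          break
        }
      }
      if (!ok) next
    }
    out[[length(out) + 1]] <- present
  }
  out
}

# canonical string form of a model term set, for set comparison
model_key <- function(terms) paste(sort(terms), collapse = "|")

# exact bootstrap tail probability by enumerating all n^n equally likely
# resamples of the slopes: P(fraction positive <= 0.5)
oracle_boot_exact <- function(slopes) {
  n <- length(slopes)
  grids <- rep(list(seq_len(n)), n)
  combos <- as.matrix(expand.grid(grids))
  frac <- apply(combos, 1, function(ix) mean(slopes[ix] > 0))
  mean(frac <= 0.5)
}

# PMVD by direct enumeration of orderings with the data-dependent weights
# w(ordering) proportional to prod_{i=1..p-1} (R2_full - R2(first i))^{-1}
oracle_pmvd <- function(y, X, w = rep(1, length(y))) {
  p <- ncol(X)
  ybar <- weighted.mean(y, w)
  ss_tot <- sum(w * (y - ybar)^2)
  r2 <- function(cols) {
    if (length(cols) == 0) return(0)
    f <- lm.wfit(cbind(1, X[, cols, drop = FALSE]), y, w)
    1 - sum(w * f$residuals^2) / ss_tot
  }
  r2_full <- r2(seq_len(p))
  perms <- asplit(fluxtrend_all_perms(p), 1)
  shares <- setNames(numeric(p), colnames(X))
  total <- 0
  for (ord in perms) {
    r2_seq <- vapply(0:p, function(i) r2(ord[seq_len(i)]), numeric(1))
    inc <- diff(r2_seq)
    wgt <- if (p == 1) 1 else 1 / prod(r2_full - r2_seq[2:p])
    total <- total + wgt
    shares[ord] <- shares[ord] + wgt * inc
  }
  shares / total
}

# all permutations of 1..n (independent of the package's implementation)
fluxtrend_all_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- fluxtrend_all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

# small synthetic panel used by several fast tests
small_panel <- function(seed = 42, n_sites = 6) {
  simulate_panel(sim_config(n_sites = n_sites, seed = seed))
}
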