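# Independent oracles used across the suite. These deliberately avoid the
# implementation paths they check.

# Damped fixed-point iteration for the 1:1 mass-action bound fraction:
# f = g(f) with g(f) = Lfree / (K + Lfree), Lfree = max(L - R f, 0).
# |g'| <= R/K, so a damping factor alpha = K / (K + R) makes the damped map
# a contraction; iterate until the fixed-point residual is at machine level.
oracle_bound_fraction <- function(R, L, K, tol = 1e-13, max_iter = 2e6) {
  g <- function(f) {
    free_l <- max(L - R * f, 0)
    free_l / (K + free_l)
  }
  alpha <- K / (K + R)
  f <- 0
  for (i in seq_len(max_iter)) {
    gf <- g(f)
    if (abs(gf - f) < tol) return(f)
    f <- (1 - alpha) * f + alpha * gf
  }
  stop("fixed-point iteration did not converge")
}

# Analytic density of a two-Gaussian mixture after convolution with a
# Gaussian KDE kernel: component widths become sqrt(sigma^2 + kernel^2).
oracle_mixture_density <- function(x, mus, weights, sigma, kernel_sigma) {
  s <- sqrt(sigma^2 + kernel_sigma^2)
  w <- weights / sum(weights)
  rowSums(vapply(seq_along(mus),
                 function(i) w[i] * dnorm(x, mus[i], s),
                 numeric(length(x))))
}

# Nested-refinement grid search for the constrained two-Gaussian fit. At
# fixed centers the optimal areas solve a 2x2 linear system (unconstrained;
# clamped at 0 afterwards), so only the two centers are searched. Five
# zoom rounds take the center precision to ~1e-4 kDa.
oracle_two_component <- function(x, y, mu1_box, mu2_box, sigma_curve,
                                 rounds = 5, pts = 21) {
  lo1 <- mu1_box[1]; hi1 <- mu1_box[2]
  lo2 <- mu2_box[1]; hi2 <- mu2_box[2]
  best <- NULL; best_val <- Inf
  for (r in seq_len(rounds)) {
    g1 <- seq(lo1, hi1, length.out = pts)
    g2 <- seq(lo2, hi2, length.out = pts)
    for (m1 in g1) for (m2 in g2) {
      A <- cbind(dnorm(x, m1, sigma_curve), dnorm(x, m2, sigma_curve))
      co <- tryCatch(solve(crossprod(A), crossprod(A, y)),
                     error = function(e) NULL)
      if (is.null(co)) next
      co <- pmax(as.numeric(co), 0)
      v <- sum((A %*% co - y)^2)
      if (v < best_val) { best_val <- v; best <- c(m1, m2, co) }
    }
    step1 <- (hi1 - lo1) / (pts - 1)
    step2 <- (hi2 - lo2) / (pts - 1)
    lo1 <- max(mu1_box[1], best[1] - step1); hi1 <- min(mu1_box[2], best[1] + step1)
    lo2 <- max(mu2_box[1], best[2] - step2); hi2 <- min(mu2_box[2], best[2] + step2)
  }
  list(mu = best[1:2], areas = best[3:4], rss = best_val,
       fraction = best[4] / (best[3] + best[4]))
}

# Brute-force stoichiometry assignment with explicit loops and the stated
# tie-breaks (error, then total copies, then lexicographic order).
oracle_assign <- function(species_mass, masses, max_count, rel_tol) {
  best <- NULL
  n <- length(masses)
  counts <- rep(0L, n)
  repeat {
    # odometer increment over the count grid
    i <- 1L
    while (i <= n) {
      counts[i] <- counts[i] + 1L
      if (counts[i] <= max_count) break
      counts[i] <- 0L
      i <- i + 1L
    }
    if (i > n) break
    pred <- sum(counts * masses)
    err <- abs(species_mass - pred) / pred
    cand <- list(counts = counts, pred = pred, err = err,
                 total = sum(counts))
    if (is.null(best)) { best <- cand; next }
    better <- err < best$err ||
      (err == best$err && cand$total < best$total) ||
      (err == best$err && cand$total == best$total &&
         {
           cmp <- which(counts != best$counts)[1]
           !is.na(cmp) && counts[cmp] < best$counts[cmp]
         })
    if (better) best <- cand
  }
  if (is.null(best) || best$err > rel_tol) return(NULL)
  best
}

trapz_test <- function(x, y) {
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

# shared fixture: a seeded receptor/complex event table
sim_mixture <- function(fraction, n = 5000, seed = 1, sigma = 12,
                        receptor_mass = 208, ligand_mass = 29.4) {
  inst <- instrument_model(mass_sigma = sigma, detection_limit = 40)
  simulate_sample(
    species_spec(c("receptor", "complex"),
                 c(receptor_mass, receptor_mass + ligand_mass),
                 c(1 - fraction, fraction)),
    inst, n_events = n, seed = seed)
}
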