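# Independent brute-force / enumeration oracles. Deliberately written with
# different code paths from the package implementation they check.

# nearest neighbour / radius counts by full pairwise scan
oracle_nnd <- function(ref, tgt) {
  apply(ref, 1, function(p) min(sqrt((tgt[, 1] - p[1])^2 + (tgt[, 2] - p[2])^2)))
}
oracle_count <- function(ref, tgt, radius) {
  apply(ref, 1, function(p) {
    sum(sqrt((tgt[, 1] - p[1])^2 + (tgt[, 2] - p[2])^2) <= radius)
  })
}

# exact point-to-segment distance, scalar formulation
oracle_dist_ring <- function(px, py, poly) {
  n <- nrow(poly)
  dmin <- Inf
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ax <- poly[i, 1]; ay <- poly[i, 2]; bx <- poly[j, 1]; by <- poly[j, 2]
    dx <- bx - ax; dy <- by - ay
    L2 <- dx^2 + dy^2
    t <- if (L2 == 0) 0 else max(0, min(1, ((px - ax) * dx + (py - ay) * dy) / L2))
    dmin <- min(dmin, sqrt((px - ax - t * dx)^2 + (py - ay - t * dy)^2))
  }
  dmin
}

# two-sided Fisher exact p by full enumeration of tables with fixed margins
oracle_fisher_2x2 <- function(m) {
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  a <- max(0, c1 - (n - r1)):min(r1, c1)
  p <- stats::dhyper(a, r1, n - r1, c1)
  pobs <- stats::dhyper(m[1, 1], r1, n - r1, c1)
  min(1, sum(p[p <= pobs * (1 + 1e-7)]))
}

# exact two-sided Mann-Whitney p by enumeration of all group labelings
oracle_mw_exact <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a); nb <- length(b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  labelings <- utils::combn(na + nb, na)
  u_all <- apply(labelings, 2, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# signed standardized log-rank statistic via survdiff (sign from O-E of the
# TRUE group)
oracle_logrank_z <- function(times, events, g) {
  sd <- survival::survdiff(survival::Surv(times, events) ~ g)
  z <- sqrt(sd$chisq)
  idx <- which(names(sd$n) == "g=TRUE")
  if (length(idx) && (sd$obs[idx] - sd$exp[idx]) < 0) z <- -z
  z
}

# Breslow log partial likelihood for a single covariate, no ties assumed
oracle_cox_loglik <- function(beta, x, times, events) {
  ll <- numeric(length(beta))
  for (i in which(events == 1)) {
    risk <- times >= times[i]
    ll <- ll + beta * x[i] -
      vapply(beta, function(b) log(sum(exp(b * x[risk]))), numeric(1))
  }
  ll
}

# exhaustive maximally-selected cutpoint via the survdiff oracle
oracle_cutpoint <- function(values, times, events, minprop) {
  sv <- sort(unique(values))
  cuts <- sv[-length(sv)]
  n <- length(values)
  keep <- vapply(cuts, function(cc) {
    nl <- sum(values <= cc)
    nl >= minprop * n && (n - nl) >= minprop * n
  }, logical(1))
  cuts <- cuts[keep]
  if (!length(cuts)) return(NULL)
  az <- vapply(cuts, function(cc) {
    abs(oracle_logrank_z(times, events, values <= cc))
  }, numeric(1))
  az[is.na(az)] <- -Inf
  list(cutpoint = cuts[which.max(az)], abs_statistic = max(az))
}
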