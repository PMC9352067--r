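# Independent oracles, kept deliberately separate from the package's
# implementation paths: a haversine written from the half-angle formula,
# spherical-triangle bearings, full hypergeometric enumeration for the
# Fisher test, permutation enumeration for the rank-sum test, and
# exhaustive medoid-set search for PAM.

oracle_haversine_km <- function(lat1, lon1, lat2, lon2, R = 6371) {
  to_rad <- pi / 180
  la1 <- lat1 * to_rad; la2 <- lat2 * to_rad
  dlat <- (lat2 - lat1) * to_rad; dlon <- (lon2 - lon1) * to_rad
  h <- sin(dlat / 2)^2 + cos(la1) * cos(la2) * sin(dlon / 2)^2
  2 * R * asin(pmin(1, sqrt(h)))
}

oracle_bearing_deg <- function(lat1, lon1, lat2, lon2) {
  to_rad <- pi / 180
  la1 <- lat1 * to_rad; la2 <- lat2 * to_rad; dl <- (lon2 - lon1) * to_rad
  y <- sin(dl) * cos(la2)
  x <- cos(la1) * sin(la2) - sin(la1) * cos(la2) * cos(dl)
  (atan2(y, x) / to_rad) %% 360
}

# two-sided Fisher p by full enumeration over the hypergeometric support,
# probability-mass criterion with the customary 1e-7 relative tie slack
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# two-sided exact rank-sum p by enumeration of all group assignments
# (no-ties samples), using the doubled-tail definition
oracle_wilcox_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  sets <- utils::combn(n1 + n2, n1)
  u_all <- apply(sets, 2, function(s) sum(r[s]) - n1 * (n1 + 1) / 2)
  lo <- mean(u_all <= u_obs); hi <- mean(u_all >= u_obs)
  min(1, 2 * min(lo, hi))
}

# exhaustive k-medoid optimum
oracle_pam_cost <- function(D, k) {
  n <- nrow(D)
  sets <- utils::combn(n, k)
  best <- Inf
  for (j in seq_len(ncol(sets))) {
    cost <- sum(apply(D[, sets[, j], drop = FALSE], 1, min))
    if (cost < best) best <- cost
  }
  best
}

# a random small clustering instance shaped like the data this pipeline
# clusters: stationary estimates scattered (geolocator-scale, ~2 deg sd)
# around a few staging centers
clumped_instance <- function() {
  n <- sample(6:12, 1)
  k <- min(sample(1:3, 1), n - 1)
  c_lat <- runif(k, 20, 60); c_lon <- runif(k, 100, 180)
  g <- sample(k, n, replace = TRUE)
  list(lat = c_lat[g] + rnorm(n, 0, 2),
       lon = c_lon[g] + rnorm(n, 0, 2), k = k)
}

# verify that no single medoid <-> non-medoid exchange reduces total cost
is_swap_optimal <- function(D, medoids) {
  n <- nrow(D)
  cost_of <- function(med) sum(apply(D[, med, drop = FALSE], 1, min))
  base <- cost_of(medoids)
  for (m in medoids) for (o in setdiff(seq_len(n), medoids)) {
    if (cost_of(c(setdiff(medoids, m), o)) < base - 1e-9) return(FALSE)
  }
  TRUE
}
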