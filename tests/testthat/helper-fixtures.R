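# Shared fixtures. The facebow dimensions here are test fixtures, not
# clinical values: d_ns 23 mm, hinge axis at the porion anchor.

fixture_facebow <- function() facebow_spec(d_ns_mm = 23)

# Rigidly rotate (radians, about the origin) and translate a calibrated
# landmark set, preserving its attributes.
transform_landmarks <- function(lm, theta = 0, shift = c(0, 0)) {
  x <- cos(theta) * lm$x - sin(theta) * lm$y + shift[1]
  y <- sin(theta) * lm$x + cos(theta) * lm$y + shift[2]
  lm$x <- x
  lm$y <- y
  lm
}

# Table-3 cluster centres (alpha, AxV, AxH) and sizes of the study cohort.
table3_centers <- function() {
  tibble::tibble(
    cluster = 1:3,
    phenotype = c("balanced", "vertical_II", "horizontal_III"),
    alpha_deg = c(7.8, 11.1, 2.4),
    axv_mm = c(36.2, 26.5, 35.9),
    axh_mm = c(98.9, 88.1, 85.6)
  )
}

# Quarter-size generator spec (same means/SDs, ~n/4) for fast tests.
small_spec <- function(ceph = NULL) {
  sp <- generator_spec(ceph = ceph)
  sp$clusters$n_female <- pmax(2L, as.integer(round(sp$clusters$n_female / 4)))
  sp$clusters$n_male <- pmax(2L, as.integer(round(sp$clusters$n_male / 4)))
  sp
}

# Exhaustive minimum within-cluster sum of squares over all 2-partitions.
brute_force_wss_k2 <- function(x) {
  n <- nrow(x)
  best <- Inf
  for (code in 1:(2^(n - 1) - 1)) {
    grp <- as.integer(intToBits(code))[1:n]
    wss <- 0
    for (g in 0:1) {
      xi <- x[grp == g, , drop = FALSE]
      wss <- wss + sum(sweep(xi, 2, colMeans(xi))^2)
    }
    best <- min(best, wss)
  }
  best
}

# Exact two-sided permutation p-value for the Mann-Whitney U statistic.
exact_mw_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  mu <- na * length(b) / 2
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - na * (na + 1) / 2
  }
  obs <- abs(u_of(seq_len(na)) - mu)
  combs <- utils::combn(length(pooled), na)
  hits <- sum(apply(combs, 2, function(idx) abs(u_of(idx) - mu) >= obs - 1e-12))
  hits / ncol(combs)
}
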