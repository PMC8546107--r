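# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity from first principles (loops, direct formulas)
# rather than reusing package internals.

oracle_velocity <- function(dphi, lambda, n, tau, dalpha, beta_rad) {
  abs(dphi * lambda / (4 * pi * n * tau * dalpha * cos(beta_rad)))
}

oracle_flow_ul_min <- function(d_um, v_m_s) {
  r_m <- d_um * 1e-6 / 2
  (pi * r_m^2 * v_m_s) * 1e9 * 60
}

# recursive biggest-with-smallest pairing, written as explicit loops
oracle_knudtson <- function(widths, k) {
  w <- sort(widths, decreasing = TRUE)
  if (length(w) > 6) w <- w[1:6]
  while (length(w) > 1) {
    combined <- c()
    while (length(w) >= 2) {
      combined <- c(combined, k * sqrt(w[1]^2 + w[length(w)]^2))
      w <- w[-c(1, length(w))]
    }
    w <- sort(c(combined, w), decreasing = TRUE)
  }
  w
}

# textbook sums-of-squares one-way ANOVA
oracle_anova <- function(groups) {
  all_vals <- unlist(groups)
  grand <- mean(all_vals)
  ssb <- 0; ssw <- 0
  for (g in groups) {
    ssb <- ssb + length(g) * (mean(g) - grand)^2
    for (x in g) ssw <- ssw + (x - mean(g))^2
  }
  df1 <- length(groups) - 1
  df2 <- length(all_vals) - length(groups)
  f <- (ssb / df1) / (ssw / df2)
  list(f = f, p = stats::pf(f, df1, df2, lower.tail = FALSE),
       df = c(df1, df2))
}

# pooled-variance two-sample t by hand
oracle_pooled_t <- function(g1, g2) {
  n1 <- length(g1); n2 <- length(g2)
  sp2 <- ((n1 - 1) * var(g1) + (n2 - 1) * var(g2)) / (n1 + n2 - 2)
  t <- (mean(g1) - mean(g2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = n1 + n2 - 2,
       p = 2 * stats::pt(-abs(t), n1 + n2 - 2))
}

# pixel-by-pixel density loop (mean binarization, >= is white)
oracle_density_percent <- function(pixels, keep) {
  vals <- c()
  for (i in seq_len(nrow(pixels))) {
    for (j in seq_len(ncol(pixels))) {
      if (keep[i, j]) vals <- c(vals, pixels[i, j])
    }
  }
  thr <- mean(vals)
  100 * sum(vals >= thr) / length(vals)
}

# pixel loop annulus membership
oracle_annulus_count <- function(dim_px, center, scale, d_in, d_out) {
  r_in <- d_in / 2 / scale; r_out <- d_out / 2 / scale
  cnt <- 0
  for (i in seq_len(dim_px[1])) {
    for (j in seq_len(dim_px[2])) {
      d <- sqrt((i - center[1])^2 + (j - center[2])^2)
      if (d >= r_in && d < r_out) cnt <- cnt + 1
    }
  }
  cnt
}

# small deterministic vessel table used by several tests
fixture_vessel_table <- function() {
  data.frame(
    vessel_id = c("A1", "A2", "A3", "V1", "V2", "V3"),
    kind = c("A", "A", "A", "V", "V", "V"),
    diameter_um = c(110, 95, 84, 130, 118, 102),
    velocity_m_s = c(0.014, 0.012, 0.010, 0.009, 0.008, 0.007),
    sat_measured = c(0.95, 0.94, 0.96, 0.55, 0.58, 0.53),
    dist_mm = c(1.2, 0.8, 2.0, 1.5, 1.0, 2.4),
    stringsAsFactors = FALSE
  )
}
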