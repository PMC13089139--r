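# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths: plain loops, direct formulas, or a
# third-party implementation (bio3d) where one exists.

# exhaustive H-C-center path scan over the raw bond table
oracle_site_count <- function(g) {
  bonds <- g$bonds
  nbr <- function(a) c(bonds$j[bonds$i == a], bonds$i[bonds$j == a])
  cc <- g$cation_center
  n <- 0L
  for (c1 in nbr(cc)) {
    if (g$atoms$element[match(c1, g$atoms$id)] != "C") next
    for (h in nbr(c1)) {
      if (g$atoms$element[match(h, g$atoms$id)] == "H") n <- n + 1L
    }
  }
  n
}

oracle_product_count <- function(g) {
  bonds <- g$bonds
  nbr <- function(a) c(bonds$j[bonds$i == a], bonds$i[bonds$j == a])
  cc <- g$cation_center
  k <- 0L
  for (c1 in nbr(cc)) {
    if (g$atoms$element[match(c1, g$atoms$id)] != "C") next
    hs <- sum(g$atoms$element[match(nbr(c1), g$atoms$id)] == "H")
    if (hs >= 1) k <- k + 1L
  }
  k
}

# direct piecewise flat-bottom evaluation
oracle_penalty <- function(lower, upper, sd, weight, x) {
  if (x >= lower && x <= upper) return(0)
  v <- if (x < lower) lower - x else x - upper
  (v / sd)^2 * weight
}

# signed-volume face label via the explicit cross/dot formula
oracle_face <- function(s1, s2, s3, center, probe) {
  a <- s2 - s1; b <- s3 - s1; c <- probe - center
  v <- (a[2] * b[3] - a[3] * b[2]) * c[1] +
       (a[3] * b[1] - a[1] * b[3]) * c[2] +
       (a[1] * b[2] - a[2] * b[1]) * c[3]
  if (v > 0) "alpha" else "beta"
}

# independent optimal-superposition RMSD: Horn's closed-form quaternion
# method (a different algorithm from the SVD route under test)
oracle_rmsd <- function(x, y) {
  xc <- sweep(x, 2, colMeans(x)); yc <- sweep(y, 2, colMeans(y))
  S <- t(yc) %*% xc
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lmax <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(xc^2) + sum(yc^2) - 2 * lmax) / nrow(x)
  sqrt(max(0, msd))
}

# third-party cross-check (bio3d rounds its result to 3 decimals)
oracle_rmsd_bio3d <- function(x, y) {
  bio3d::rmsd(as.numeric(t(x)), as.numeric(t(y)), fit = TRUE)
}

# naive double-loop soft-sphere / shell-contact energies (no vectorisation)
oracle_body_energy <- function(bx, rx) {
  rep_e <- 0; att_e <- 0
  for (i in seq_len(nrow(bx))) {
    contacts <- 0L
    for (j in seq_len(nrow(rx))) {
      d <- sqrt(sum((bx[i, ] - rx[j, ])^2))
      if (d < 3.0) rep_e <- rep_e + ((3.0 - d) / 3.0)^2
      if (d >= 3.2 && d <= 4.5) contacts <- contacts + 1L
    }
    att_e <- att_e - min(4L, contacts)
  }
  c(rep = rep_e, att = att_e)
}

# nearest labeled oxygen by explicit argmin
oracle_water_label <- function(water, pp, cutoff = 3.5) {
  ox <- rownames(pp)[startsWith(rownames(pp), "O")]
  best <- NULL; bestd <- Inf
  for (nm in ox) {
    d <- sqrt(sum((pp[nm, ] - water)^2))
    if (d < bestd) { bestd <- d; best <- nm }
  }
  if (bestd > cutoff) "none" else if (best == "OB") "bridging" else "terminal"
}

# exhaustive per-hydrogen geometric classification re-check
oracle_classify <- function(lig_xyz, bo, sites, products,
                            dist_gate = 2.8, angle_gate = 100) {
  best <- "unassigned"; bestd <- Inf
  for (s in seq_len(nrow(sites))) {
    h <- lig_xyz[sites$hydrogen_name[s], ]
    cc <- lig_xyz[sites$carbon_name[s], ]
    d <- sqrt(sum((h - bo)^2))
    u1 <- (cc - h) / sqrt(sum((cc - h)^2))
    u2 <- (bo - h) / sqrt(sum((bo - h)^2))
    ang <- acos(max(-1, min(1, sum(u1 * u2)))) * 180 / pi
    if (d <= dist_gate && ang >= angle_gate && d < bestd) {
      bestd <- d; best <- products$product_id[s]
    }
  }
  best
}

unitv_test <- function(v) v / sqrt(sum(v^2))

cross_test <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}
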