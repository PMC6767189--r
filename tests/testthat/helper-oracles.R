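# Independent oracles used across the suite. Each is deliberately written as
# a direct, naive transcription of the rule or formula it checks, sharing no
# code path with the implementation.

# Position-by-position trypsin rule scan: cut after K/R unless next is P.
oracle_cut_sites <- function(residues) {
  res <- strsplit(residues, "")[[1]]
  sites <- integer(0)
  for (i in seq_along(res)) {
    if (i == length(res)) next
    if ((res[i] == "K" || res[i] == "R") && res[i + 1] != "P") {
      sites <- c(sites, i - 1L)   # 0-based, cut after this index
    }
  }
  sites
}

# Full N^2 Debye sum, explicit outer loop over atoms (self terms included),
# minimum image + half-box cutoff when periodic.
oracle_debye <- function(frame, two_theta, wavelength) {
  theta <- two_theta * pi / 360
  s <- 2 * sin(theta) / wavelength
  q <- 4 * pi * sin(theta) / wavelength
  n <- nrow(frame$coords)
  f <- sapply(frame$elements, function(e) form_factor(e, s))
  f <- matrix(f, nrow = length(s))
  periodic <- !is.null(frame$box) && frame$box$periodic
  cutoff <- if (periodic) min(frame$box$lengths) / 2 else Inf
  I <- numeric(length(s))
  for (k in seq_len(n)) {
    d3 <- sweep(frame$coords, 2, frame$coords[k, ])
    if (periodic) {
      L <- frame$box$lengths
      for (c in 1:3) d3[, c] <- d3[, c] - L[c] * round(d3[, c] / L[c])
    }
    r <- sqrt(rowSums(d3^2))
    keep <- r <= cutoff
    for (g in seq_along(s)) {
      x <- q[g] * r[keep]
      sinc <- ifelse(x == 0, 1, sin(x) / x)
      I[g] <- I[g] + sum(f[g, k] * f[g, keep] * sinc)
    }
  }
  I
}

# Monte-Carlo occupied volume: uniform points, minimum-image sphere test.
oracle_mc_volume <- function(frame, radii, n_points = 1e6, seed = 42) {
  L <- frame$box$lengths
  withr::with_seed(seed, {
    pts <- cbind(runif(n_points, 0, L[1]), runif(n_points, 0, L[2]),
                 runif(n_points, 0, L[3]))
    occ <- rep(FALSE, n_points)
    for (i in seq_len(nrow(frame$coords))) {
      d3 <- sweep(pts, 2, frame$coords[i, ])
      for (k in 1:3) d3[, k] <- d3[, k] - L[k] * round(d3[, k] / L[k])
      occ <- occ | (rowSums(d3^2) <= radii[i]^2)
    }
    mean(occ) * prod(L)
  })
}

# ANOVA from the explicit textbook sum formulas.
oracle_anova <- function(x, y) {
  n <- length(x)
  sxx <- sum(x^2) - sum(x)^2 / n
  syy <- sum(y^2) - sum(y)^2 / n
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  ssm <- sxy^2 / sxx
  sse <- syy - ssm
  f <- ssm / (sse / (n - 2))
  list(slope = sxy / sxx, sse_model = ssm, sse_error = sse, sse_total = syy,
       f_value = f, p_value = pf(f, 1, n - 2, lower.tail = FALSE))
}

random_aa_string <- function(len, seed) {
  withr::with_seed(seed, paste(
    sample(strsplit("ACDEFGHIKLMNPQRSTVWYX", "")[[1]], len, replace = TRUE),
    collapse = ""))
}

frag_strings <- function(digest) {
  vapply(digest$fragments, function(f) as.character(f$residues), "")
}
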