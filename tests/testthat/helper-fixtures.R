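# Shared fixtures: small landscapes and expansions built once per test run.

tiny_landscape <- function(seed = 1, ...) {
  generate_landscape(n_rows = 20, n_cols = 24, seed = seed, ...)
}

# a landscape + expansion + genotype bundle at reduced size
tiny_world <- function(seed = 1, n_pops = 12, l_neutral = 150,
                       l_adaptive = 30, drift_scale = 0.01, beta = 5) {
  ls <- tiny_landscape(seed)
  tband <- quantile(ls$temp[ls$land], 0.2)
  suit <- ls$land & ls$temp >= tband
  pool <- which(suit)
  org <- pool[which.max(ls$temp_lgm[pool])]
  tr <- simulate_expansion(ls, org, suitable = suit, d_per_step_km = 25)
  gen <- suppressWarnings(simulate_allele_frequencies(
    tr, ls, n_pops = n_pops, l_neutral = l_neutral,
    l_adaptive = l_adaptive, beta = beta, drift_scale = drift_scale,
    seed = seed + 100))
  list(landscape = ls, truth = tr, genotypes = gen, origin = org)
}

# mean pairwise difference count, computed directly from haplotypes:
# independent oracle for theta_pi
pairwise_pi_oracle <- function(h) {
  n <- nrow(h)
  tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      tot <- tot + sum(h[i, ] != h[j, ])
    }
  }
  tot / choose(n, 2)
}

random_haplotypes <- function(n, sites) {
  matrix(rbinom(n * sites, 1, runif(sites, 0.05, 0.95)[rep(1:sites, each = n)]),
         n, sites)
}

# independent transcription of the published variance normalisations
# (Tajima 1989; Fu & Li 1993; Zeng et al. 2006), coded directly from the
# formulas as a cross-check on the implementation
neutrality_oracle <- function(xi, n) {
  i <- 1:(n - 1)
  S <- sum(xi[i + 1])
  an <- sum(1 / i); bn <- sum(1 / i^2)
  tw <- S / an
  tpi <- sum(2 * i * (n - i) * xi[i + 1]) / (n * (n - 1))
  tl <- sum(i * xi[i + 1]) / (n - 1)
  th <- sum(2 * i^2 * xi[i + 1]) / (n * (n - 1))
  theta <- S / an
  theta2 <- S * (S - 1) / (an^2 + bn)
  # Tajima's D
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / an; c2 <- b2 - (n + 2) / (an * n) + bn / an^2
  vD <- (c1 / an) * S + (c2 / (an^2 + bn)) * S * (S - 1)
  D <- (tpi - tw) / sqrt(vD)
  # normalised H (on theta_pi - theta_L)
  bn1 <- sum(1 / (1:n)^2)
  vH <- theta * (n - 2) / (6 * (n - 1)) +
    theta2 * (18 * n^2 * (3 * n + 2) * bn1 - (88 * n^3 + 9 * n^2 - 13 * n + 6)) /
      (9 * n * (n - 1)^2)
  H <- (tpi - tl) / sqrt(vH)
  # Zeng's E
  vE <- theta * (n / (2 * (n - 1)) - 1 / an) +
    theta2 * (bn / an^2 + 2 * (n / (n - 1))^2 * bn -
                2 * (n * bn - n + 1) / ((n - 1) * an) - (3 * n + 1) / (n - 1))
  E <- (tl - tw) / sqrt(vE)
  # Fu & Li's F with derived singletons
  an1 <- sum(1 / (1:n))
  cn <- 2 * (n * an - 2 * (n - 1)) / ((n - 1) * (n - 2))
  vF <- (cn + 2 * (n^2 + n + 3) / (9 * n * (n - 1)) - 2 / (n - 1)) / (an^2 + bn)
  uF <- (1 + (n + 1) / (3 * (n - 1)) -
           4 * (n + 1) / (n - 1)^2 * (an1 - 2 * n / (n + 1))) / an - vF
  F <- (tpi - xi[2]) / sqrt(uF * S + vF * S^2)
  list(D = D, H = H, E = E, F = F)
}
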