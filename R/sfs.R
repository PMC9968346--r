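# Site-frequency-spectrum construction, theta estimators, neutrality
# statistics, and the directionality index psi.

#' Unfolded site frequency spectrum from a haplotype matrix
#'
#' Tallies derived-allele counts per site into an unfolded SFS. Rows are
#' haplotypes, columns are sites; entries are 0 (ancestral) or 1 (derived).
#'
#' @param h Binary matrix (haplotypes x sites). Columns with any `NA` are
#'   treated as unpolarised and dropped.
#' @return A `sieve_sfs` object: integer vector `xi` of length `n + 1` where
#'   `xi[i + 1]` counts sites carrying `i` derived copies, with attribute `n`
#'   (sample size).
#' @examples
#' h <- rbind(c(0, 1, 0), c(0, 1, 1))
#' sfs_from_haplotypes(h)
#' @export
sfs_from_haplotypes <- function(h) {
  h <- as.matrix(h)
  if (nrow(h) < 2) abort("need at least 2 haplotypes")
  keep <- colSums(is.na(h)) == 0
  h <- h[, keep, drop = FALSE]
  if (!all(h %in% c(0, 1))) abort("haplotype matrix must be binary (0/1)")
  n <- nrow(h)
  counts <- colSums(h)
  xi <- tabulate(counts + 1L, nbins = n + 1L)
  new_sfs(xi, n)
}

new_sfs <- function(xi, n) {
  structure(as.integer(xi), n = as.integer(n), class = "sieve_sfs")
}

#' Construct an unfolded SFS from counts
#'
#' @param xi Vector of length `n + 1`: counts of sites with `0..n` derived
#'   copies.
#' @param n Sample size (number of haplotypes).
#' @export
as_sfs <- function(xi, n = length(xi) - 1L) {
  if (length(xi) != n + 1L) abort("xi must have length n + 1")
  if (any(xi < 0)) abort("SFS counts must be non-negative")
  new_sfs(xi, n)
}

#' @export
print.sieve_sfs <- function(x, ...) {
  cat("<unfolded SFS> n =", attr(x, "n"),
      " sites =", sum(x), "\n")
  print(as.integer(x))
  invisible(x)
}

#' Joint two-population site frequency spectrum
#'
#' @param h1,h2 Binary haplotype matrices over the same (aligned) sites.
#' @return A `sieve_sfs2d` object: `(n1 + 1) x (n2 + 1)` count matrix with
#'   attributes `n1`, `n2`.
#' @export
joint_sfs_from_haplotypes <- function(h1, h2) {
  h1 <- as.matrix(h1); h2 <- as.matrix(h2)
  if (ncol(h1) != ncol(h2)) abort("haplotype matrices must cover the same sites")
  keep <- colSums(is.na(h1)) == 0 & colSums(is.na(h2)) == 0
  h1 <- h1[, keep, drop = FALSE]; h2 <- h2[, keep, drop = FALSE]
  n1 <- nrow(h1); n2 <- nrow(h2)
  if (n1 < 2 || n2 < 2) abort("need at least 2 haplotypes per population")
  i <- colSums(h1); j <- colSums(h2)
  xi2 <- matrix(0L, n1 + 1L, n2 + 1L)
  tab <- table(factor(i, levels = 0:n1), factor(j, levels = 0:n2))
  xi2[] <- as.integer(tab)
  as_sfs2d(xi2, n1, n2)
}

#' @rdname joint_sfs_from_haplotypes
#' @param xi2 Count matrix of dimension `(n1 + 1) x (n2 + 1)`.
#' @param n1,n2 Sample sizes.
#' @export
as_sfs2d <- function(xi2, n1 = nrow(xi2) - 1L, n2 = ncol(xi2) - 1L) {
  xi2 <- as.matrix(xi2)
  if (!all(dim(xi2) == c(n1 + 1L, n2 + 1L))) abort("xi2 dimensions must be (n1+1) x (n2+1)")
  if (any(xi2 < 0)) abort("SFS counts must be non-negative")
  structure(xi2, n1 = as.integer(n1), n2 = as.integer(n2), class = "sieve_sfs2d")
}

# Watterson's a1 and related constants
harmonic <- function(n, power = 1) sum(1 / (seq_len(n)^power))

#' Theta estimators from an unfolded SFS
#'
#' Computes the classical frequency-weighted estimators of the population
#' mutation rate: Watterson's \eqn{\theta_W = S / a_1}, pairwise diversity
#' \eqn{\theta_\pi = \sum_i 2 i (n - i) \xi_i / (n (n - 1))}, Fay and Wu's
#' \eqn{\theta_H = \sum_i 2 i^2 \xi_i / (n (n - 1))} and Zeng's
#' \eqn{\theta_L = \sum_i i \xi_i / (n - 1)}, all summed over `0 < i < n`.
#'
#' @param sfs A `sieve_sfs` object (see [sfs_from_haplotypes()], [as_sfs()]).
#' @return A one-row tibble with columns `n`, `S`, `singletons`, `theta_w`,
#'   `theta_pi`, `theta_h`, `theta_l`.
#' @export
theta_estimators <- function(sfs) {
  stopifnot(inherits(sfs, "sieve_sfs"))
  n <- attr(sfs, "n")
  if (n < 2) abort("sample size must be at least 2")
  xi <- as.integer(sfs)
  i <- seq_len(n - 1)           # segregating classes 0 < i < n
  xi_seg <- xi[i + 1L]
  S <- sum(xi_seg)
  tibble(
    n = n,
    S = S,
    singletons = xi[2L],
    theta_w = S / harmonic(n - 1),
    theta_pi = sum(2 * i * (n - i) * xi_seg) / (n * (n - 1)),
    theta_h = sum(2 * i^2 * xi_seg) / (n * (n - 1)),
    theta_l = sum(i * xi_seg) / (n - 1)
  )
}

#' Per-site contributions to the theta estimators
#'
#' For each polarised site with derived count `i` (out of `n`), returns the
#' additive contribution of that site to each theta estimator; summing any
#' column over sites reproduces [theta_estimators()]. The substrate of the
#' weighted (environment-association-centred) statistics.
#'
#' @param h Binary haplotype matrix (haplotypes x sites).
#' @return A tibble with one row per retained site: `site`, `count`,
#'   `theta_w`, `theta_pi`, `theta_h`, `theta_l`, `singleton`.
#' @export
per_site_theta <- function(h) {
  h <- as.matrix(h)
  n <- nrow(h)
  if (n < 2) abort("need at least 2 haplotypes")
  cnt <- colSums(h)
  seg <- cnt > 0 & cnt < n
  i <- cnt
  tibble(
    site = seq_len(ncol(h)),
    count = as.integer(cnt),
    theta_w = as.numeric(seg) / harmonic(n - 1),
    theta_pi = ifelse(seg, 2 * i * (n - i) / (n * (n - 1)), 0),
    theta_h = ifelse(seg, 2 * i^2 / (n * (n - 1)), 0),
    theta_l = ifelse(seg, i / (n - 1), 0),
    singleton = as.numeric(cnt == 1L)
  )
}

#' Weighted theta estimators
#'
#' Weight-normalised sums of per-site estimator contributions, so uniform
#' weights reproduce the unweighted estimators exactly. Used to centre
#' diversity and neutrality statistics on environmentally associated sites by
#' weighting each site with the R-squared of its gene-environment association.
#'
#' @param contribs Per-site contribution tibble from [per_site_theta()].
#' @param weights Non-negative per-site weights aligned with `contribs`.
#' @return A one-row tibble with the same columns as [theta_estimators()].
#' @export
weighted_theta <- function(contribs, weights) {
  if (nrow(contribs) != length(weights)) abort("weights must align with contribs")
  if (any(!is.finite(weights)) || any(weights < 0)) abort("weights must be finite and non-negative")
  if (sum(weights) <= 0) abort("at least one weight must be positive")
  wbar <- mean(weights)
  agg <- function(v) sum(weights * v) / wbar
  tibble(
    n = NA_integer_,
    S = agg(as.numeric(contribs$theta_w > 0)),
    singletons = agg(contribs$singleton),
    theta_w = agg(contribs$theta_w),
    theta_pi = agg(contribs$theta_pi),
    theta_h = agg(contribs$theta_h),
    theta_l = agg(contribs$theta_l)
  )
}

#' SFS-based neutrality statistics
#'
#' Variance-standardised statistics contrasting theta estimators: Tajima's D,
#' Fu and Li's F (within-sample derived singletons), Fay and Wu's H
#' (normalised following Zeng and colleagues, computed on
#' \eqn{\theta_\pi - \theta_L}; the classical unnormalised
#' \eqn{\theta_\pi - \theta_H} is also returned) and Zeng's E. An excess of
#' high-frequency derived variants -- the footprint of a selective sweep or of
#' allele surfing during expansion -- drives H negative and E positive.
#'
#' @param sfs A `sieve_sfs` object.
#' @return A one-row tibble: `n`, `S`, `D`, `F`, `H_norm`, `H_unnorm`, `E`,
#'   `defined`. With `S = 0` all statistics are `NA` and `defined` is `FALSE`.
#' @export
neutrality_stats <- function(sfs) {
  th <- theta_estimators(sfs)
  neutrality_from_thetas(th$n, th$S, th$singletons, th$theta_w, th$theta_pi,
                         th$theta_h, th$theta_l)
}

# Variance-standardised statistics from (possibly weighted) summaries.
# S may be non-integer for the weighted variants; the variance formulas are
# evaluated at the same (real) S.
neutrality_from_thetas <- function(n, S, singletons, theta_w, theta_pi,
                                   theta_h, theta_l) {
  if (S < 1e-12) {
    return(tibble(n = n, S = S, D = NA_real_, F = NA_real_, H_norm = NA_real_,
                  H_unnorm = NA_real_, E = NA_real_, defined = FALSE))
  }
  an <- harmonic(n - 1)
  bn <- harmonic(n - 1, 2)
  # unbiased moment plug-ins for theta and theta^2
  th_hat <- S / an
  th2_hat <- S * (S - 1) / (an^2 + bn)

  # Tajima (1989)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / an
  c2 <- b2 - (n + 2) / (an * n) + bn / an^2
  e1 <- c1 / an
  e2 <- c2 / (an^2 + bn)
  var_d <- e1 * S + e2 * S * (S - 1)
  D <- if (var_d > 0) (theta_pi - theta_w) / sqrt(var_d) else NA_real_

  # Zeng et al. (2006): H on theta_pi - theta_l
  bn1 <- harmonic(n, 2) # sum_{i=1}^{n} 1/i^2
  var_h <- th_hat * (n - 2) / (6 * (n - 1)) +
    th2_hat * (18 * n^2 * (3 * n + 2) * bn1 -
                 (88 * n^3 + 9 * n^2 - 13 * n + 6)) / (9 * n * (n - 1)^2)
  H_norm <- if (is.finite(var_h) && var_h > 0)
    (theta_pi - theta_l) / sqrt(var_h) else NA_real_

  # Zeng et al. (2006): E
  var_e <- th_hat * (n / (2 * (n - 1)) - 1 / an) +
    th2_hat * (bn / an^2 + 2 * (n / (n - 1))^2 * bn -
                 2 * (n * bn - n + 1) / ((n - 1) * an) - (3 * n + 1) / (n - 1))
  E <- if (is.finite(var_e) && var_e > 0)
    (theta_l - theta_w) / sqrt(var_e) else NA_real_

  # Fu & Li (1993) F with derived (external) singletons xi_1
  F_stat <- NA_real_
  if (n > 2) {
    an1 <- harmonic(n) # sum_{i=1}^{n} 1/i
    cn <- 2 * (n * an - 2 * (n - 1)) / ((n - 1) * (n - 2))
    vF <- (cn + 2 * (n^2 + n + 3) / (9 * n * (n - 1)) - 2 / (n - 1)) / (an^2 + bn)
    uF <- (1 + (n + 1) / (3 * (n - 1)) -
             4 * (n + 1) / (n - 1)^2 * (an1 - 2 * n / (n + 1))) / an - vF
    var_f <- uF * S + vF * S^2
    if (is.finite(var_f) && var_f > 0)
      F_stat <- (theta_pi - singletons) / sqrt(var_f)
  }

  tibble(n = n, S = S, D = D, F = F_stat, H_norm = H_norm,
         H_unnorm = theta_pi - theta_h, E = E, defined = TRUE)
}

#' Directionality index psi from a joint 2D-SFS
#'
#' The directionality index of a population pair measures the asymmetry in
#' shared derived allele frequencies left behind by serial founder events: the
#' population farther along an expansion shows elevated frequencies of shared
#' derived alleles. Computed over the support of cells with at least one
#' derived copy in each population, excluding only the cell fixed derived in
#' both:
#' \deqn{\psi_{12} = \frac{\sum \xi_{ij} (j/n_2 - i/n_1)}{\sum \xi_{ij}}.}
#' Positive \eqn{\psi_{12}} indicates population 2 lies farther from the
#' expansion origin than population 1.
#'
#' @param j A `sieve_sfs2d` object.
#' @return Scalar psi with attribute `n_sites_used` (support size); `NA` with
#'   `n_sites_used = 0` when the support is empty.
#' @examples
#' xi2 <- matrix(0, 3, 3)
#' xi2[2, 2] <- 4; xi2[2, 3] <- 3; xi2[3, 2] <- 1
#' psi_from_joint_sfs(as_sfs2d(xi2)) # 0.125
#' @export
psi_from_joint_sfs <- function(j) {
  stopifnot(inherits(j, "sieve_sfs2d"))
  n1 <- attr(j, "n1"); n2 <- attr(j, "n2")
  if (n1 < 2 || n2 < 2) abort("sample sizes must be at least 2")
  xi2 <- unclass(j)
  ii <- matrix(0:n1, n1 + 1L, n2 + 1L)
  jj <- matrix(0:n2, n1 + 1L, n2 + 1L, byrow = TRUE)
  support <- ii >= 1 & jj >= 1 & !(ii == n1 & jj == n2)
  tot <- sum(xi2[support])
  if (tot <= 0) {
    return(structure(NA_real_, n_sites_used = 0L))
  }
  psi <- sum(xi2[support] * (jj[support] / n2 - ii[support] / n1)) / tot
  structure(psi, n_sites_used = as.integer(tot))
}

#' Read and write the plain-text SFS formats
#'
#' A 1D SFS is stored as a header line `n=<n>` followed by one count per
#' line; a 2D SFS as a header `n1=<n1> n2=<n2>` followed by a dense
#' whitespace-separated count matrix. Both round-trip exactly.
#'
#' @param sfs,path Object and file path.
#' @export
write_sfs <- function(sfs, path) {
  if (inherits(sfs, "sieve_sfs")) {
    writeLines(c(paste0("n=", attr(sfs, "n")), as.character(as.integer(sfs))), path)
  } else if (inherits(sfs, "sieve_sfs2d")) {
    hdr <- paste0("n1=", attr(sfs, "n1"), " n2=", attr(sfs, "n2"))
    rows <- apply(unclass(sfs), 1, paste, collapse = " ")
    writeLines(c(hdr, rows), path)
  } else abort("not an SFS object")
  invisible(path)
}

#' @rdname write_sfs
#' @export
read_sfs <- function(path) {
  lines <- readLines(path)
  hdr <- lines[[1]]
  if (grepl("^n=", hdr)) {
    n <- as.integer(sub("^n=", "", hdr))
    as_sfs(as.integer(lines[-1]), n)
  } else if (grepl("^n1=", hdr)) {
    parts <- strsplit(hdr, " ")[[1]]
    n1 <- as.integer(sub("n1=", "", parts[[1]]))
    n2 <- as.integer(sub("n2=", "", parts[[2]]))
    xi2 <- do.call(rbind, lapply(lines[-1], function(l)
      as.integer(strsplit(trimws(l), "\\s+")[[1]])))
    as_sfs2d(xi2, n1, n2)
  } else abort("unrecognised SFS header")
}
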