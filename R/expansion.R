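# Expansion-signal inference: pairwise directionality index psi, the
# psi-distance Mantel test, TDOA origin inference and founder-effect
# strength.

#' Pairwise directionality index matrix
#'
#' Computes psi for every ordered population pair from per-population
#' haplotype matrices (via their joint 2D-SFS). Antisymmetry is enforced
#' structurally: the lower triangle is the negated upper triangle.
#'
#' @param haplotypes Named list of binary haplotype matrices over aligned,
#'   commonly polarised sites (e.g. `sieve_genotypes$haplotypes`).
#' @param pop_table Tibble with at least `id`, `lon`, `lat`, ordered as the
#'   desired matrix order; defaults to the haplotype list names.
#' @return A `sieve_psi` object: list with `psi` (antisymmetric matrix),
#'   `n_sites` (per-pair support size), `pop_table`.
#' @export
pairwise_psi <- function(haplotypes, pop_table = NULL) {
  if (is.null(pop_table)) {
    pop_table <- tibble(id = names(haplotypes))
  }
  ids <- pop_table$id
  if (length(ids) < 3) abort("need at least 3 populations")
  if (!all(ids %in% names(haplotypes))) abort("pop_table ids missing from haplotypes")
  k <- length(ids)
  psi <- matrix(0, k, k, dimnames = list(ids, ids))
  nsites <- matrix(0L, k, k, dimnames = list(ids, ids))
  for (a in seq_len(k - 1)) {
    for (b in (a + 1):k) {
      j2 <- joint_sfs_from_haplotypes(haplotypes[[ids[a]]], haplotypes[[ids[b]]])
      p <- psi_from_joint_sfs(j2)
      psi[a, b] <- as.numeric(p)
      psi[b, a] <- -as.numeric(p)
      nsites[a, b] <- nsites[b, a] <- attr(p, "n_sites_used")
    }
  }
  structure(list(psi = psi, n_sites = nsites, pop_table = pop_table),
            class = "sieve_psi")
}

#' @export
print.sieve_psi <- function(x, ...) {
  cat("<psi matrix>", nrow(x$psi), "populations; mean |psi| =",
      signif(mean(abs(x$psi[upper.tri(x$psi)])), 3), "\n")
  invisible(x)
}

#' @export
tidy.sieve_psi <- function(x, ...) {
  ids <- rownames(x$psi)
  idx <- which(upper.tri(x$psi), arr.ind = TRUE)
  tibble(pop1 = ids[idx[, 1]], pop2 = ids[idx[, 2]],
         psi = x$psi[idx], n_sites = x$n_sites[idx])
}

#' Mantel test of psi against geographic distance
#'
#' Permutation test of the matrix correlation between the directionality
#' index and great-circle distance. Without an origin the statistic is the
#' upper-triangle Pearson correlation of |psi| with pairwise distance; with
#' an origin supplied, signed psi is correlated with signed differences of
#' distance-from-origin. Population labels are permuted jointly in rows and
#' columns; the observed statistic is included in the null set, so the
#' smallest attainable p is `1 / (n_perm + 1)`.
#'
#' @param psi A `sieve_psi` object.
#' @param distances Optional pairwise distance matrix (km); computed from
#'   `psi$pop_table` coordinates when omitted.
#' @param origin Optional `c(lon, lat)` of an inferred origin; switches to
#'   the signed statistic.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed for the permutations.
#' @return Tibble with `r`, `p`, `n_perm`, `statistic` ("abs" or "signed").
#' @export
mantel_psi <- function(psi, distances = NULL, origin = NULL,
                       n_perm = 10000, seed = 1) {
  if (n_perm < 100) warn("fewer than 100 permutations: p-value is coarse")
  if (is.null(distances)) distances <- gc_dist_km(psi$pop_table)
  k <- nrow(psi$psi)
  if (!all(dim(distances) == k)) abort("distance matrix not conformable with psi")
  if (is.null(origin)) {
    x <- distances
    y <- abs(psi$psi)
    stat_name <- "abs"
  } else {
    d0 <- gc_dist_km(psi$pop_table, tibble(lon = origin[[1]], lat = origin[[2]]))[, 1]
    x <- outer(d0, d0, function(a, b) b - a) # d_jo - d_io
    y <- psi$psi
    stat_name <- "signed"
  }
  ut <- upper.tri(x)
  corr <- function(perm) {
    yy <- y[perm, perm]
    suppressWarnings(cor(x[ut], yy[ut]))
  }
  r_obs <- corr(seq_len(k))
  if (!is.finite(r_obs)) {
    warn("zero-variance psi: Mantel correlation undefined")
    return(tibble(r = NA_real_, p = NA_real_, n_perm = n_perm,
                  statistic = stat_name))
  }
  set.seed(seed)
  r_null <- replicate(n_perm, corr(sample(k)))
  p <- (sum(r_null >= r_obs, na.rm = TRUE) + 1) / (n_perm + 1)
  tibble(r = r_obs, p = p, n_perm = n_perm, statistic = stat_name)
}

#' TDOA inference of the expansion origin
#'
#' For each candidate origin cell o, regresses psi_ij through the origin on
#' the difference in great-circle distances `d(j, o) - d(i, o)` over all
#' ordered population pairs; the candidate maximising the regression
#' R-squared is the inferred origin. Under a clean expansion, psi grows
#' linearly with how much farther one population is from the source than the
#' other.
#'
#' @param psi A `sieve_psi` object.
#' @param candidates Tibble of candidate origins (`lon`, `lat`, optionally
#'   `cell`); e.g. the land cells of a `sieve_landscape`, or a lon/lat grid
#'   from [candidate_grid()].
#' @return A `sieve_origin` object: tibble of candidates with `r2` and
#'   `slope`, attributes `best` (row of the best candidate), `no_signal`.
#' @export
tdoa_origin <- function(psi, candidates) {
  pt <- psi$pop_table
  if (nrow(pt) < 5) abort("need at least 5 populations for a stable TDOA fit")
  if (nrow(candidates) == 0) abort("no candidate origin cells (all masked?)")
  y <- psi$psi[upper.tri(psi$psi)]
  dmat <- gc_dist_km(pt, candidates) # pops x candidates
  k <- nrow(pt)
  iu <- which(upper.tri(psi$psi), arr.ind = TRUE)
  ssy <- sum(y^2)
  r2 <- slope <- numeric(nrow(candidates))
  for (cc in seq_len(nrow(candidates))) {
    x <- dmat[iu[, 2], cc] - dmat[iu[, 1], cc]
    sxx <- sum(x^2)
    if (sxx == 0 || ssy == 0) { r2[cc] <- 0; slope[cc] <- 0; next }
    b <- sum(x * y) / sxx
    r2[cc] <- (sum(x * y))^2 / (sxx * ssy)
    slope[cc] <- b
  }
  out <- as_tibble(candidates)
  out$r2 <- r2
  out$slope <- slope
  # R^2 alone is blind to direction (the antipode of the origin fits with a
  # negated slope); an origin must show psi increasing away from it
  out$score <- ifelse(slope > 0, r2, 0)
  no_signal <- ssy == 0 || all(out$score == 0)
  if (no_signal) warn("no directional signal: flat TDOA score surface")
  best <- out[which.max(out$score), ]
  structure(out, best = best, no_signal = no_signal,
            class = c("sieve_origin", class(tibble())))
}

#' @export
print.sieve_origin <- function(x, ...) {
  b <- attr(x, "best")
  cat("<TDOA origin surface>", nrow(x), "candidates; best at (",
      signif(b$lon, 5), ",", signif(b$lat, 5), ") R2 =", signif(b$r2, 3), "\n")
  invisible(x)
}

#' @export
glance.sieve_origin <- function(x, ...) {
  b <- attr(x, "best")
  tibble(lon = b$lon, lat = b$lat, r2 = b$r2, slope = b$slope,
         no_signal = attr(x, "no_signal"))
}

#' Rectangular candidate grid over a landscape's land mask
#'
#' @param landscape A `sieve_landscape`.
#' @param resolution Approximate number of candidates along the longer axis
#'   (default uses every land cell).
#' @export
candidate_grid <- function(landscape, resolution = NULL) {
  land <- dplyr::filter(landscape, .data$land)
  if (is.null(resolution)) {
    return(dplyr::select(land, "cell", "lon", "lat"))
  }
  g <- attr(landscape, "grid")
  by_r <- max(1L, floor(g[["rows"]] / resolution))
  by_c <- max(1L, floor(g[["cols"]] / resolution))
  dplyr::select(
    dplyr::filter(land, .data$row %% by_r == 0, .data$col %% by_c == 0),
    "cell", "lon", "lat")
}

#' Founder-effect strength along the expansion
#'
#' Slope of psi against pairwise differences in distance from the inferred
#' origin, re-expressed as the number of kilometres over which a 1% founder
#' effect (0.01 units of psi) accumulates.
#'
#' @param psi A `sieve_psi` object.
#' @param origin `c(lon, lat)` of the inferred origin (e.g.
#'   `glance(tdoa_origin(...))`).
#' @return Tibble with `slope_per_km` and `km_per_percent`
#'   (`0.01 / slope`; `NA` when the slope is not positive).
#' @export
founder_strength <- function(psi, origin) {
  d0 <- gc_dist_km(psi$pop_table,
                   tibble(lon = origin[[1]], lat = origin[[2]]))[, 1]
  x <- outer(d0, d0, function(a, b) b - a)[upper.tri(psi$psi)]
  y <- psi$psi[upper.tri(psi$psi)]
  slope <- sum(x * y) / sum(x^2)
  km <- if (is.finite(slope) && slope > 0) 0.01 / slope else NA_real_
  if (!is.na(slope) && slope <= 0) warn("non-positive founder slope: km_per_percent undefined")
  tibble(slope_per_km = slope, km_per_percent = km)
}
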