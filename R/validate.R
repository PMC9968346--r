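# Validation of the glacial genomic offset against SFS-based diversity and
# neutrality statistics, genome-wide and weighted by each site's
# gene-environment association, plus the elevation-contrast analyses.

#' Per-population diversity and neutrality statistics
#'
#' Computes, for every population's haplotype sample, nucleotide diversity
#' (theta-pi), Tajima's D, Fu and Li's F, Fay and Wu's H and Zeng's E --
#' genome-wide (`_gw` columns) and, when per-locus weights are given,
#' centred on environmentally associated loci (`_gf` columns) by weighting
#' each site's estimator contribution with the R-squared of its
#' gene-environment association. The weighted statistics reuse the same
#' variance normalisations evaluated at the weight-normalised S.
#'
#' @param genotypes A `sieve_genotypes` (or any named list of binary
#'   haplotype matrices in `$haplotypes` plus `$pop_table`).
#' @param weights Optional non-negative per-locus weights aligned with the
#'   haplotype columns (e.g. `pmax(fit$r2, 0)`).
#' @return Tibble with one row per population.
#' @export
population_genetics_stats <- function(genotypes, weights = NULL) {
  pt <- genotypes$pop_table
  rows <- lapply(pt$id, function(pid) {
    h <- genotypes$haplotypes[[pid]]
    sfs <- sfs_from_haplotypes(h)
    th <- theta_estimators(sfs)
    ns <- neutrality_stats(sfs)
    out <- tibble(id = pid, pi_gw = th$theta_pi, S_gw = th$S,
                  D_gw = ns$D, F_gw = ns$F, H_gw = ns$H_norm, E_gw = ns$E)
    if (!is.null(weights)) {
      contribs <- per_site_theta(h)
      wt <- weighted_theta(contribs, weights)
      nsw <- neutrality_from_thetas(nrow(h), wt$S, wt$singletons, wt$theta_w,
                                    wt$theta_pi, wt$theta_h, wt$theta_l)
      out$pi_gf <- wt$theta_pi
      out$D_gf <- nsw$D; out$F_gf <- nsw$F
      out$H_gf <- nsw$H_norm; out$E_gf <- nsw$E
    }
    out
  })
  bind_rows(rows)
}

#' Correlate the glacial genomic offset with population statistics
#'
#' Ordinary least squares of each statistic on the offset, reporting the
#' Pearson correlation, R-squared, adjusted R-squared and the F-test
#' p-value of the regression. Constant statistics are flagged and skipped.
#'
#' @param offsets A `sieve_offset` (or tibble with `id`, `offset`).
#' @param stats Tibble with `id` and one column per statistic (e.g. from
#'   [population_genetics_stats()]).
#' @return A `sieve_validation` tibble: `statistic`, `n`, `r`,
#'   `r_squared`, `adj_r_squared`, `slope`, `p_value`, `flagged`.
#' @export
correlate_offset <- function(offsets, stats) {
  merged <- dplyr::inner_join(as_tibble(offsets)[c("id", "offset")],
                              as_tibble(stats), by = "id")
  if (nrow(merged) < 10) warn("fewer than 10 populations: weak inference")
  stat_cols <- setdiff(names(merged), c("id", "offset"))
  rows <- lapply(stat_cols, function(sc) {
    y <- merged[[sc]]
    ok <- is.finite(y) & is.finite(merged$offset)
    if (sum(ok) < 3 || sd(y[ok]) == 0) {
      return(tibble(statistic = sc, n = sum(ok), r = NA_real_,
                    r_squared = NA_real_, adj_r_squared = NA_real_,
                    slope = NA_real_, p_value = NA_real_, flagged = TRUE))
    }
    fit <- lm(y[ok] ~ merged$offset[ok])
    sm <- summary(fit)
    fstat <- sm$fstatistic
    p <- pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
    tibble(statistic = sc, n = sum(ok),
           r = cor(merged$offset[ok], y[ok]),
           r_squared = sm$r.squared, adj_r_squared = sm$adj.r.squared,
           slope = unname(coef(fit)[2]), p_value = unname(p), flagged = FALSE)
  })
  structure(bind_rows(rows),
            class = c("sieve_validation", class(tibble())))
}

#' @export
print.sieve_validation <- function(x, ...) {
  cat("<offset validation>", nrow(x), "statistics\n")
  NextMethod()
}

#' Elevation-contrast analysis of nucleotide diversity
#'
#' Splits populations into low- (< `low_max` m) and high- (> `high_min` m)
#' elevation bins, forms geographically proximate high/low pairs (within
#' `pairing_radius_km`, elevation contrast at least `min_contrast_m`), and
#' compares diversity between bins with a two-sided Mann-Whitney U test.
#' When a `pi_gf` column is present, the weighted-vs-genome-wide contrast
#' (`pi_gf` vs `pi_gw` across all populations) is tested as well.
#'
#' @param pop_table Tibble with `id`, `lon`, `lat`, `elevation`.
#' @param stats Tibble with `id`, `pi_gw` and optionally `pi_gf`.
#' @param low_max,high_min Bin boundaries in metres (defaults 1000, 1500).
#' @param pairing_radius_km Maximum pair separation (default 20).
#' @param min_contrast_m Minimum elevation contrast within a pair
#'   (default 900).
#' @return List with `pairs` (per-pair diversities and deltas), `bins`
#'   (per-population bin table) and `tests` (Mann-Whitney results).
#' @export
elevation_contrast <- function(pop_table, stats, low_max = 1000,
                               high_min = 1500, pairing_radius_km = 20,
                               min_contrast_m = 900) {
  d <- dplyr::left_join(pop_table, stats, by = "id")
  d$bin <- dplyr::case_when(
    d$elevation < low_max ~ "low",
    d$elevation > high_min ~ "high",
    TRUE ~ "intermediate")
  lows <- dplyr::filter(d, .data$bin == "low")
  highs <- dplyr::filter(d, .data$bin == "high")
  if (nrow(lows) == 0 || nrow(highs) == 0) abort("both elevation bins must be non-empty")
  pairs <- list()
  if (nrow(lows) > 0 && nrow(highs) > 0) {
    dm <- gc_dist_km(highs, lows)
    for (i in seq_len(nrow(highs))) {
      j <- which.min(dm[i, ])
      contrast <- highs$elevation[i] - lows$elevation[j]
      if (dm[i, j] <= pairing_radius_km && contrast >= min_contrast_m) {
        pr <- tibble(high_id = highs$id[i], low_id = lows$id[j],
                     distance_km = dm[i, j], elevation_contrast_m = contrast,
                     pi_gw_high = highs$pi_gw[i], pi_gw_low = lows$pi_gw[j],
                     delta_pi_gw = highs$pi_gw[i] - lows$pi_gw[j])
        if ("pi_gf" %in% names(d)) {
          pr$pi_gf_high <- highs$pi_gf[i]
          pr$pi_gf_low <- lows$pi_gf[j]
          pr$delta_pi_gf <- highs$pi_gf[i] - lows$pi_gf[j]
        }
        pairs[[length(pairs) + 1]] <- pr
      }
    }
  }
  pairs <- if (length(pairs)) bind_rows(pairs) else {
    warn("no proximate high/low pairs within the pairing radius")
    tibble()
  }
  tests <- list()
  mw <- function(a, b, label) {
    wt <- suppressWarnings(wilcox.test(a, b))
    tibble(test = label, statistic = unname(wt$statistic),
           p_value = wt$p.value,
           median_a = stats::median(a, na.rm = TRUE),
           median_b = stats::median(b, na.rm = TRUE))
  }
  tests[[1]] <- mw(lows$pi_gw, highs$pi_gw, "pi_gw: low vs high")
  if ("pi_gf" %in% names(d)) {
    tests[[2]] <- mw(lows$pi_gf, highs$pi_gf, "pi_gf: low vs high")
    tests[[3]] <- mw(d$pi_gf, d$pi_gw, "all pops: pi_gf vs pi_gw")
  }
  list(pairs = pairs,
       bins = dplyr::select(d, "id", "elevation", "bin",
                            dplyr::any_of(c("pi_gw", "pi_gf"))),
       tests = bind_rows(tests))
}
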