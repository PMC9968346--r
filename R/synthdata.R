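# Synthetic landscape / expansion / allele-frequency generator with known
# ground truth. Emulates (i) a gridded, elevation-driven environment in two
# time slices, (ii) expansion out of a single glacial refugium with serial
# founder effects, and (iii) adaptive loci whose frequencies respond
# logistically to the local environment ("sieving"), plus finite haplotype
# samples per population.

smooth_field <- function(rows, cols, n_waves = 6, length_scale = 0.5) {
  # sum of random low-frequency plane waves; smooth and deterministic under
  # the caller's RNG state
  r <- matrix(seq(0, 1, length.out = rows), rows, cols)
  c_ <- matrix(seq(0, 1, length.out = cols), rows, cols, byrow = TRUE)
  f <- matrix(0, rows, cols)
  for (w in seq_len(n_waves)) {
    kx <- rnorm(1, 0, 1 / length_scale)
    ky <- rnorm(1, 0, 1 / length_scale)
    ph <- runif(1, 0, 2 * pi)
    amp <- rnorm(1, 0, 1) / sqrt(n_waves)
    f <- f + amp * sin(kx * r + ky * c_ + ph)
  }
  f / max(sd(as.vector(f)), 1e-12)
}

#' Generate a synthetic two-slice landscape
#'
#' Builds a gridded landscape with a smooth elevation surface, a land mask
#' (cells above sea level), and `n_env` environmental variables for two time
#' slices: the present and the Last Glacial Maximum (LGM). The first variable
#' (`temp`) decreases with elevation and latitude, mimicking temperature; the
#' LGM slice is the present slice shifted by a smooth, elevation- and
#' latitude-dependent cooling field scaled by `warming_amplitude` (present
#' minus LGM is positive for `temp` when the amplitude is positive).
#'
#' @param n_rows,n_cols Grid dimensions (at least 20 x 20 for simulations).
#' @param n_env Number of environmental variables (>= 2).
#' @param warming_amplitude Magnitude of the LGM-to-present shift, in units
#'   of the (unit-variance) environmental fields. 0 makes both slices equal.
#' @param cell_size_km Grid cell edge length in kilometres.
#' @param origin Longitude/latitude of the grid's north-west corner.
#' @param seed Integer seed; the landscape is a deterministic function of it.
#' @return A `sieve_landscape`: a tibble with one row per cell (`cell`,
#'   `row`, `col`, `lon`, `lat`, `elevation`, `land`, one column per
#'   environmental variable and its `_lgm` counterpart) carrying attributes
#'   `grid` (rows, cols), `cell_size_km` and `env_vars`.
#' @export
generate_landscape <- function(n_rows = 30, n_cols = 40, n_env = 3,
                               warming_amplitude = 3, cell_size_km = 10,
                               origin = c(lon = 6, lat = 47), seed = 1) {
  if (n_rows <= 0 || n_cols <= 0) abort("grid dimensions must be positive")
  if (n_env < 2) abort("need at least 2 environmental variables")
  set.seed(seed)
  rows <- n_rows; cols <- n_cols
  lat <- origin[["lat"]] - (seq_len(rows) - 1) * cell_size_km / 111.32
  lon0 <- origin[["lon"]]
  grid <- tidyr::expand_grid(row = seq_len(rows), col = seq_len(cols))
  grid$lat <- lat[grid$row]
  grid$lon <- lon0 + (grid$col - 1) * cell_size_km /
    (111.32 * cos(grid$lat * pi / 180))
  grid$cell <- seq_len(nrow(grid))

  elev_f <- smooth_field(rows, cols, n_waves = 8, length_scale = 0.35)
  # tilt so a coherent massif emerges; sea level sits at the 15th
  # percentile of the surface, leaving a coastal margin on every landscape
  elev <- 1200 + 900 * elev_f - 600 * outer(seq(0, 1, length.out = rows),
                                            seq(0, 1, length.out = cols), "+")
  elev <- elev - quantile(elev, 0.15)
  grid$elevation <- elev[cbind(grid$row, grid$col)]
  grid$land <- grid$elevation > 0

  env_names <- c("temp", "prec", paste0("env", seq_len(max(0, n_env - 2)) + 2))[seq_len(n_env)]
  lat_norm <- (grid$lat - min(grid$lat)) / max(diff(range(grid$lat)), 1e-9)
  elev_norm <- (grid$elevation - min(grid$elevation)) /
    max(diff(range(grid$elevation)), 1e-9)
  for (k in seq_len(n_env)) {
    f <- smooth_field(rows, cols, n_waves = 6, length_scale = 0.5)
    base <- f[cbind(grid$row, grid$col)]
    if (k == 1) {
      v <- 12 - 6.5 * elev_norm * 2 + 4 * lat_norm + 0.8 * base # temperature-like
    } else if (k == 2) {
      v <- 900 + 400 * elev_norm + 150 * base                   # precipitation-like
    } else {
      v <- base
    }
    shift_scale <- if (k == 1) 1 else 0.3
    shift <- warming_amplitude * shift_scale *
      (0.6 + 0.25 * lat_norm + 0.15 * elev_norm) * sd(v)
    grid[[env_names[k]]] <- v
    grid[[paste0(env_names[k], "_lgm")]] <- v - shift
  }
  structure(
    as_tibble(grid[c("cell", "row", "col", "lon", "lat", "elevation", "land",
                     env_names, paste0(env_names, "_lgm"))]),
    grid = c(rows = rows, cols = cols),
    cell_size_km = cell_size_km,
    env_vars = env_names,
    class = c("sieve_landscape", class(tibble()))
  )
}

#' Environmental variable names of a landscape
#' @param landscape A `sieve_landscape`.
#' @export
env_vars <- function(landscape) attr(landscape, "env_vars")

#' Great-circle distance matrix (km) between coordinate sets
#'
#' Haversine distances via [geosphere::distHaversine()].
#'
#' @param a,b Data frames with `lon` and `lat` columns; `b` defaults to `a`.
#' @export
gc_dist_km <- function(a, b = a) {
  m1 <- as.matrix(a[, c("lon", "lat")])
  m2 <- as.matrix(b[, c("lon", "lat")])
  out <- matrix(0, nrow(m1), nrow(m2))
  for (i in seq_len(nrow(m1))) {
    out[i, ] <- geosphere::distHaversine(m1[i, ], m2) / 1000
  }
  out
}

#' Simulate a stepping-stone range expansion over a landscape
#'
#' Starting from a single refugial origin cell, colonises suitable land cells
#' in discrete waves: at each step every uncolonised suitable cell within
#' `d_per_step_km` (great-circle) of an already-colonised cell is founded
#' from its nearest colonised source. The realised founding chain defines the
#' cumulative founding distance of each cell.
#'
#' @param landscape A `sieve_landscape`.
#' @param origin_cell Cell index of the refugium; must be land and suitable.
#' @param suitable Optional logical vector (per cell) of habitat suitability;
#'   defaults to the land mask.
#' @param d_per_step_km Dispersal reach per step in kilometres.
#' @param n_steps Maximum number of waves.
#' @return A `sieve_expansion` tibble: `cell`, `founded`, `founding_order`
#'   (0 at the origin), `founding_distance_km`, `source_cell`, `lineage`;
#'   attributes `origin_cell`, `d_per_step_km`.
#' @export
simulate_expansion <- function(landscape, origin_cell, suitable = NULL,
                               d_per_step_km = 25, n_steps = 1000) {
  if (is.null(suitable)) suitable <- landscape$land
  if (!isTRUE(suitable[origin_cell]) || !isTRUE(landscape$land[origin_cell])) {
    abort(paste0("origin cell ", origin_cell, " is not suitable land"))
  }
  n <- nrow(landscape)
  founded <- rep(FALSE, n)
  order_ <- rep(NA_integer_, n)
  distk <- rep(NA_real_, n)
  src <- rep(NA_integer_, n)
  founded[origin_cell] <- TRUE
  order_[origin_cell] <- 0L
  distk[origin_cell] <- 0
  dmat <- gc_dist_km(landscape) # cell-to-cell great-circle distances
  step <- 0L
  while (step < n_steps) {
    step <- step + 1L
    open <- which(!founded & suitable & landscape$land)
    if (length(open) == 0) break
    occ <- which(founded)
    dd <- dmat[occ, open, drop = FALSE]
    nearest <- apply(dd, 2, which.min)
    mind <- dd[cbind(nearest, seq_along(open))]
    newly <- mind <= d_per_step_km
    if (!any(newly)) break
    cells <- open[newly]
    sources <- occ[nearest[newly]]
    founded[cells] <- TRUE
    order_[cells] <- step
    src[cells] <- sources
    distk[cells] <- distk[sources] + mind[newly]
  }
  structure(
    tibble(cell = landscape$cell, founded = founded, founding_order = order_,
           founding_distance_km = distk, source_cell = src,
           lineage = ifelse(founded, 1L, NA_integer_)),
    origin_cell = origin_cell, d_per_step_km = d_per_step_km,
    class = c("sieve_expansion", class(tibble()))
  )
}

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))
clamp01 <- function(p, eps = 0) pmin(1 - eps, pmax(eps, p))

#' Simulate sieved allele frequencies along an expansion
#'
#' Neutral loci drift along the realised founding chain: each colonisation
#' edge adds an independent Gaussian increment with variance
#' `drift_scale * p(1-p)` (truncated to `[0, 1]`), so heterozygosity decays
#' with founding order (the serial founder effect). Adaptive loci are
#' additionally sieved by the environment: their expected frequency at a
#' population is `plogis(logit(p_drift) + beta * dz)` where `dz` is the
#' standardised displacement of the causal variable from its refugial value.
#' Finite samples of haplotypes are drawn per population.
#'
#' @param truth A `sieve_expansion`.
#' @param landscape The `sieve_landscape` the expansion ran on.
#' @param n_pops Number of sampled populations (colonised cells; the origin
#'   is always included).
#' @param n_haplotypes Haplotypes sampled per population.
#' @param l_neutral,l_adaptive Locus counts.
#' @param beta Mean selection (sieving) strength of adaptive loci; per-locus
#'   magnitudes are exponential with this mean and signs are randomised.
#'   `beta = 0` with `l_adaptive > 0` warns.
#' @param drift_scale Per-colonisation-step drift variance multiplier.
#' @param causal_var Environmental variable driving adaptive loci (defaults
#'   to the first landscape variable).
#' @param reference Which time slice defines the refugial (ancestral)
#'   environment the sieving displacement is measured from: `"lgm"` (the
#'   refugium's glacial climate, the ancestral condition; default) or
#'   `"present"`.
#' @param seed Integer seed.
#' @return A `sieve_genotypes` list: `pop_table` tibble, `freqs` (true
#'   populations x loci frequencies), `est_freqs` (frequencies estimated
#'   from the finite haplotype samples -- what an empirical analysis would
#'   see), `locus_info` tibble (`locus`, `class`, `causal_env`, `beta`),
#'   `haplotypes` (named list of binary matrices), `ancestral` frequencies,
#'   and `refugial_env` (named vector).
#' @export
simulate_allele_frequencies <- function(truth, landscape, n_pops = 30,
                                        n_haplotypes = 20, l_neutral = 1800,
                                        l_adaptive = 200, beta = 5,
                                        drift_scale = 0.005,
                                        causal_var = NULL,
                                        reference = c("lgm", "present"),
                                        seed = 1) {
  reference <- match.arg(reference)
  founded_cells <- truth$cell[truth$founded]
  if (length(founded_cells) < 10) abort("expansion must cover at least 10 cells")
  if (l_adaptive > 0 && beta == 0) {
    warn("beta = 0: adaptive loci are indistinguishable from neutral loci")
  }
  set.seed(seed)
  if (is.null(causal_var)) causal_var <- env_vars(landscape)[[1]]
  origin_cell <- attr(truth, "origin_cell")
  pops <- unique(c(origin_cell,
                   sample(setdiff(founded_cells, origin_cell),
                          min(n_pops - 1, length(founded_cells) - 1))))
  L <- l_neutral + l_adaptive
  p0 <- runif(L, 0.1, 0.9)
  locus_class <- rep(c("neutral", "adaptive"), c(l_neutral, l_adaptive))
  # polygenic sweep-from-standing-variation architecture: the derived allele
  # of an adaptive locus is a variant rare in the refugium (polarisation:
  # ancestral = refugial major state) and favoured where the environment is
  # displaced from the refugial condition; per-locus effect sizes are
  # exponential around the mean `beta`, so the aggregate response stays
  # graded along the gradient instead of saturating at one logistic scale
  adapt_idx <- locus_class == "adaptive"
  p0[adapt_idx] <- runif(sum(adapt_idx), 0.05, 0.35)
  beta_l <- ifelse(adapt_idx, stats::rexp(L, 1 / max(beta, 1e-12)), 0)
  if (beta == 0) beta_l[] <- 0

  # drift along the founding chain; shared path segments share increments
  ord <- order(truth$founding_order[match(founded_cells, truth$cell)])
  chain <- founded_cells[ord]
  freq_cell <- matrix(NA_real_, nrow(landscape), L)
  freq_cell[origin_cell, ] <- p0
  if (drift_scale > 0) {
    for (cl in chain) {
      if (cl == origin_cell) next
      s <- truth$source_cell[truth$cell == cl]
      ps <- freq_cell[s, ]
      inc <- rnorm(L, 0, sqrt(drift_scale * ps * (1 - ps)))
      freq_cell[cl, ] <- clamp01(ps + inc)
    }
  } else {
    freq_cell[chain, ] <- matrix(p0, length(chain), L, byrow = TRUE)
  }

  # environmental sieving of adaptive loci
  env_land <- landscape[[causal_var]][landscape$land]
  env_sd <- max(sd(env_land), 1e-12)
  ref_col <- if (reference == "lgm") paste0(causal_var, "_lgm") else causal_var
  # niche conservatism: the refugial optimum survives in the most
  # refugium-like colonised habitat, so when post-glacial warming pushes
  # every occupied cell beyond the refugial value, selection is measured
  # from the coldest occupied environment rather than an unrealised state
  ref_env <- max(landscape[[ref_col]][origin_cell],
                 min(landscape[[causal_var]][founded_cells]))
  freqs <- matrix(NA_real_, length(pops), L)
  for (k in seq_along(pops)) {
    cl <- pops[k]
    p <- freq_cell[cl, ]
    adapt <- locus_class == "adaptive"
    if (any(adapt) && beta != 0) {
      dz <- (landscape[[causal_var]][cl] - ref_env) / env_sd
      pa <- clamp01(p[adapt], 1e-9)
      p[adapt] <- inv_logit(logit(pa) + beta_l[adapt] * dz)
    }
    freqs[k, ] <- clamp01(p)
  }

  # drop loci ancestrally fixed (derived absent) in every population
  keep <- colSums(freqs > 0) > 0
  freqs <- freqs[, keep, drop = FALSE]
  locus_class <- locus_class[keep]
  beta_l <- beta_l[keep]
  p0 <- p0[keep]
  loci <- sprintf("L%05d", seq_len(ncol(freqs)))
  colnames(freqs) <- loci

  pop_ids <- sprintf("P%02d", seq_along(pops))
  rownames(freqs) <- pop_ids
  idx <- match(pops, landscape$cell)
  pop_table <- tibble(
    id = pop_ids, cell = pops,
    lon = landscape$lon[idx], lat = landscape$lat[idx],
    elevation = landscape$elevation[idx],
    n_haplotypes = n_haplotypes,
    founding_order = truth$founding_order[match(pops, truth$cell)],
    founding_distance_km = truth$founding_distance_km[match(pops, truth$cell)]
  )
  haplotypes <- lapply(seq_along(pops), function(k) {
    m <- matrix(rbinom(n_haplotypes * ncol(freqs), 1, rep(freqs[k, ],
                                                          each = n_haplotypes)),
                n_haplotypes, ncol(freqs))
    colnames(m) <- loci
    m
  })
  names(haplotypes) <- pop_ids
  est_freqs <- do.call(rbind, lapply(haplotypes, colMeans))
  rownames(est_freqs) <- pop_ids
  structure(
    list(pop_table = pop_table, freqs = freqs, est_freqs = est_freqs,
         locus_info = tibble(locus = loci, class = locus_class,
                             causal_env = ifelse(locus_class == "adaptive",
                                                 causal_var, NA_character_),
                             beta = beta_l),
         haplotypes = haplotypes, ancestral = p0,
         refugial_env = setNames(ref_env, causal_var)),
    class = "sieve_genotypes"
  )
}

#' @export
print.sieve_genotypes <- function(x, ...) {
  cat("<synthetic genotypes>", nrow(x$freqs), "populations x",
      ncol(x$freqs), "loci (",
      sum(x$locus_info$class == "adaptive"), "adaptive )\n")
  invisible(x)
}

#' True sieving displacement of adaptive allele frequencies
#'
#' Mean absolute displacement, per population, of adaptive-locus frequencies
#' from their ancestral (refugial) values -- the ground-truth quantity that
#' the glacial genomic offset is designed to track.
#'
#' @param genotypes A `sieve_genotypes` object.
#' @return Tibble with `id` and `true_displacement`.
#' @export
true_adaptive_displacement <- function(genotypes) {
  adapt <- genotypes$locus_info$class == "adaptive"
  if (!any(adapt)) abort("no adaptive loci in this dataset")
  d <- abs(sweep(genotypes$freqs[, adapt, drop = FALSE], 2,
                 genotypes$ancestral[adapt]))
  tibble(id = genotypes$pop_table$id, true_displacement = rowMeans(d))
}
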