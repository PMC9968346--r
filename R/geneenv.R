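# Gene-environment turnover modelling: per-SNP random forests, combination
# into monotone cumulative-importance (turnover) functions, transformation
# of environments into "biological space", composition PCA, and the
# LGM-vs-present environmental-space shift summary.

#' Fit per-SNP random-forest regressions of allele frequency on environment
#'
#' One random-forest regression per SNP (response: population allele
#' frequency; predictors: selected environmental variables plus spatial
#' co-variates such as `lon`/`lat` or `MEM1`). Harvests every split's
#' predictor, split value and impurity (SSE) improvement, binned along each
#' predictor's observed range, together with the out-of-bag R-squared of
#' each SNP. SNPs are processed in batches; batches are statistically
#' independent so batching only bounds memory.
#'
#' @param freqs Populations x SNPs matrix (or data frame) of allele
#'   frequencies; column names identify SNPs.
#' @param predictors Tibble/data frame of predictors, rows aligned with
#'   `freqs` rows.
#' @param n_trees Trees per SNP forest (field default 500).
#' @param mtry Predictors tried per split (default `ceiling(2p / 3)`,
#'   suited to small pre-screened predictor sets).
#' @param min_node Smallest splittable node (default 5).
#' @param n_bins Number of split-record bins per predictor (default 200,
#'   i.e. 201 knots).
#' @param batch_size SNPs per batch (default 10000).
#' @param seed Integer seed.
#' @return A `sieve_gf_fit` object: `r2` (per-SNP out-of-bag R-squared),
#'   `importance` (SNP x predictor raw importance), `binned` (SNP x
#'   predictor x bin split-improvement array), `breaks`, `density`
#'   (per-predictor kernel density at bin midpoints), `predictors`,
#'   `snp_ids`, `active` (R-squared > 0).
#' @export
fit_snp_forests <- function(freqs, predictors, n_trees = 500, mtry = NULL,
                            min_node = 5, n_bins = 200, batch_size = 10000,
                            seed = 1) {
  X <- as.matrix(as.data.frame(predictors))
  Y <- as.matrix(freqs)
  if (nrow(X) != nrow(Y)) abort("predictors and freqs must have aligned rows")
  if (nrow(Y) < 2 * ncol(X)) {
    warn("fewer populations than twice the predictor count: unstable fits")
  }
  p <- ncol(X)
  # with small, pre-screened predictor sets a large feature sample per
  # split prevents importance from diluting across correlated predictors
  if (is.null(mtry)) mtry <- max(1L, ceiling(2 * p / 3))
  snp_ids <- colnames(Y)
  if (is.null(snp_ids)) snp_ids <- sprintf("S%05d", seq_len(ncol(Y)))
  breaks <- lapply(seq_len(p), function(j) {
    r <- range(X[, j])
    if (diff(r) == 0) r <- r + c(-0.5, 0.5)
    seq(r[1], r[2], length.out = n_bins + 1)
  })
  names(breaks) <- colnames(X)
  dens <- lapply(seq_len(p), function(j) {
    mids <- (breaks[[j]][-1] + breaks[[j]][-(n_bins + 1)]) / 2
    d <- density(X[, j], from = min(mids), to = max(mids), n = n_bins)
    dv <- approx(d$x, d$y, xout = mids, rule = 2)$y
    dv / mean(dv) # mean-1 normalisation keeps importance scale
  })
  names(dens) <- colnames(X)

  set.seed(seed)
  S <- ncol(Y)
  batches <- split(seq_len(S), ceiling(seq_len(S) / batch_size))
  r2 <- numeric(S)
  importance <- matrix(0, S, p, dimnames = list(snp_ids, colnames(X)))
  binned <- array(0, dim = c(S, p, n_bins))
  for (b in batches) {
    res <- snp_forest_cpp(X, Y[, b, drop = FALSE], n_trees, mtry, min_node,
                          breaks)
    r2[b] <- res$r2
    importance[b, ] <- res$importance
    binned[b, , ] <- res$binned
  }
  structure(list(r2 = setNames(r2, snp_ids), importance = importance,
                 binned = binned, breaks = breaks, density = dens,
                 predictors = colnames(X), snp_ids = snp_ids,
                 active = r2 > 0 & !is.na(r2), n_trees = n_trees),
            class = "sieve_gf_fit")
}

#' @export
print.sieve_gf_fit <- function(x, ...) {
  cat("<gene-environment forest fit>", length(x$snp_ids), "SNPs x",
      length(x$predictors), "predictors;", sum(x$active),
      "active (out-of-bag R2 > 0)\n")
  invisible(x)
}

#' Combine per-SNP fits into monotone turnover functions
#'
#' Per predictor, each active SNP's binned split improvements are first
#' density-standardised (divided by the predictor's data density in the bin,
#' the "standardise before" convention), cumulated into a monotone curve and
#' rescaled to conserve that SNP's raw total importance for the predictor.
#' SNP curves are then combined as the weighted mean with weights
#' `w_s = max(R2_s, 0)` (the coefficient of determination of the SNP's
#' environmental association), so the combined curve rises from 0 at the
#' predictor's observed minimum to the weighted total importance at its
#' maximum.
#'
#' @param fit A `sieve_gf_fit`.
#' @param spatial_vars Predictor names regarded as spatial co-variates
#'   (default: any of `lon`, `lat`, `MEM1` present).
#' @return A `sieve_turnover` object: `predictors`, `knots` (list),
#'   `cumimp` (list of cumulative-importance values at the knots),
#'   `total_importance`, `weights`, `spatial_vars`.
#' @export
build_turnover <- function(fit, spatial_vars = NULL) {
  w <- pmax(fit$r2, 0)
  w[!fit$active] <- 0
  if (sum(w) == 0) abort("no gene-environment signal: no active SNP")
  if (is.null(spatial_vars)) {
    spatial_vars <- intersect(c("lon", "lat", "MEM1"), fit$predictors)
  }
  p <- length(fit$predictors)
  n_bins <- dim(fit$binned)[3]
  knots <- lapply(fit$breaks, identity)
  cumimp <- vector("list", p)
  total <- numeric(p)
  n_snps <- dim(fit$binned)[1]
  for (j in seq_len(p)) {
    bj <- matrix(fit$binned[, j, ], nrow = n_snps)
    std <- sweep(bj, 2, fit$density[[j]], "/")
    raw_tot <- rowSums(bj)
    std_tot <- rowSums(std)
    scale <- ifelse(std_tot > 0, raw_tot / std_tot, 0)
    std <- std * scale
    comb <- colSums(std * w) / sum(w) # weighted mean curve increments
    cumimp[[j]] <- c(0, cumsum(comb)) # values at the n_bins + 1 knots
    total[j] <- sum(comb)
  }
  names(cumimp) <- fit$predictors
  structure(list(predictors = fit$predictors, knots = knots, cumimp = cumimp,
                 total_importance = setNames(total, fit$predictors),
                 weights = w, snp_r2 = fit$r2, spatial_vars = spatial_vars),
            class = "sieve_turnover")
}

#' @export
print.sieve_turnover <- function(x, ...) {
  cat("<turnover model>", length(x$predictors), "predictors; total importance:\n")
  print(signif(sort(x$total_importance, decreasing = TRUE), 3))
  invisible(x)
}

#' @export
tidy.sieve_turnover <- function(x, ...) {
  bind_rows(lapply(x$predictors, function(p) {
    tibble(predictor = p, knot = x$knots[[p]], cumimp = x$cumimp[[p]])
  }))
}

#' Transform an environment into biological (turnover) space
#'
#' Maps each predictor value through its cumulative-importance curve by
#' linear interpolation between knots; values outside the fitted range clamp
#' to the endpoint values. Differences in the transformed space measure
#' expected allele-frequency turnover.
#'
#' @param model A `sieve_turnover`.
#' @param env Tibble with the model's predictors (a `cell` or `id` column is
#'   carried through).
#' @return Tibble of transformed predictor values.
#' @export
transform_environment <- function(model, env) {
  missing <- setdiff(model$predictors, names(env))
  if (length(missing) > 0) {
    abort(paste("missing predictor(s):", paste(missing, collapse = ", ")))
  }
  keep <- intersect(c("cell", "id"), names(env))
  out <- as_tibble(env[keep])
  for (p in model$predictors) {
    out[[p]] <- approx(model$knots[[p]], model$cumimp[[p]],
                       xout = env[[p]], rule = 2)$y
  }
  out
}

#' Principal components of a transformed composition grid
#'
#' Centred, unscaled PCA of the turnover-transformed variables (unscaled so
#' the gene-environment importances are retained in the ordination). Spatial
#' co-variates can be excluded to visualise only the adaptive component.
#'
#' @param composition Output of [transform_environment()].
#' @param spatial_vars Spatial co-variate columns (excluded when
#'   `exclude_spatial`).
#' @param exclude_spatial Drop spatial co-variates before the PCA.
#' @return Tibble of the first three PC scores (columns `PC1..PC3`, plus any
#'   `cell`/`id` column); attribute `pca` holds the `prcomp` fit.
#' @export
composition_pca <- function(composition, spatial_vars = c("lon", "lat", "MEM1"),
                            exclude_spatial = TRUE) {
  keep <- intersect(c("cell", "id"), names(composition))
  vars <- setdiff(names(composition), keep)
  if (exclude_spatial) vars <- setdiff(vars, spatial_vars)
  if (length(vars) < 2) warn("fewer than 2 variables: PCA is degenerate")
  M <- as.matrix(composition[vars])
  nz <- apply(M, 2, function(col) var(col) > 0)
  pc <- prcomp(M, center = TRUE, scale. = FALSE)
  k <- min(3, ncol(pc$x))
  out <- as_tibble(composition[keep])
  for (i in seq_len(k)) out[[paste0("PC", i)]] <- pc$x[, i]
  for (i in seq_len(3 - k)) out[[paste0("PC", k + i)]] <- 0
  structure(out, pca = pc)
}

# axial (pointy-top) hexagon index for a point, hexagon "size" = circumradius
hex_index <- function(x, y, size) {
  qf <- (sqrt(3) / 3 * x - 1 / 3 * y) / size
  rf <- (2 / 3 * y) / size
  # cube rounding
  xf <- qf; zf <- rf; yf <- -xf - zf
  rx <- round(xf); ry <- round(yf); rz <- round(zf)
  dx <- abs(rx - xf); dy <- abs(ry - yf); dz <- abs(rz - zf)
  fix_x <- dx > dy & dx > dz
  fix_z <- !fix_x & dz > dy
  rx[fix_x] <- -ry[fix_x] - rz[fix_x]
  rz[fix_z] <- -rx[fix_z] - ry[fix_z]
  tibble(hex_q = as.integer(rx), hex_r = as.integer(rz))
}

#' Shift of the environmental space between the LGM and the present
#'
#' Fits a centred, scaled PCA on the present-day land-cell environment and
#' applies the same transformation (centring, scaling, rotation) to both
#' slices. Cell density in the shared PC1/PC2 plane is summarised by
#' hexagonal binning, each cell contributing its geographic area, so the
#' binned area per slice totals the land area. An optional occurrence set is
#' projected likewise and summarised by its convex-hull niche envelope.
#'
#' @param landscape A `sieve_landscape`.
#' @param occurrences Optional occurrence tibble (`lon`, `lat`) defining the
#'   realised-niche envelope.
#' @param hex_size Hexagon circumradius in PC units (default: 1/20 of the
#'   present PC1 range).
#' @return A `sieve_envshift` list: `scores` (tibble: slice, cell, PC1,
#'   PC2), `bins` (tibble: slice, hex_q, hex_r, count, area), `envelope`
#'   (convex-hull vertices of projected occurrence environments, or NULL),
#'   `cell_area_km2`, `pca`.
#' @export
env_space_shift <- function(landscape, occurrences = NULL, hex_size = NULL) {
  vars <- env_vars(landscape)
  land <- dplyr::filter(landscape, .data$land)
  pres <- as.matrix(env_slice(landscape, "present")[match(land$cell, landscape$cell), vars])
  lgm <- as.matrix(env_slice(landscape, "lgm")[match(land$cell, landscape$cell), vars])
  pc <- prcomp(pres, center = TRUE, scale. = TRUE)
  proj <- function(M) {
    scale(M, pc$center, pc$scale) %*% pc$rotation[, 1:2, drop = FALSE]
  }
  sp <- proj(pres); sl <- proj(lgm)
  if (is.null(hex_size)) hex_size <- diff(range(sp[, 1])) / 20
  cell_area <- attr(landscape, "cell_size_km")^2
  scores <- bind_rows(
    tibble(slice = "present", cell = land$cell, PC1 = sp[, 1], PC2 = sp[, 2]),
    tibble(slice = "lgm", cell = land$cell, PC1 = sl[, 1], PC2 = sl[, 2])
  )
  bins <- dplyr::summarise(
    dplyr::group_by(
      bind_cols(scores, hex_index(scores$PC1, scores$PC2, hex_size)),
      .data$slice, .data$hex_q, .data$hex_r),
    count = dplyr::n(), .groups = "drop")
  bins$area <- bins$count * cell_area
  envelope <- NULL
  if (!is.null(occurrences) && nrow(occurrences) > 2) {
    d <- gc_dist_km(occurrences, land)
    occ_env <- pres[apply(d, 1, which.min), , drop = FALSE]
    so <- proj(occ_env)
    hull <- grDevices::chull(so)
    envelope <- tibble(PC1 = so[hull, 1], PC2 = so[hull, 2])
  }
  structure(list(scores = scores, bins = bins, envelope = envelope,
                 cell_area_km2 = cell_area, pca = pc, hex_size = hex_size),
            class = "sieve_envshift")
}

#' @export
print.sieve_envshift <- function(x, ...) {
  a <- dplyr::summarise(dplyr::group_by(x$bins, .data$slice),
                        area = sum(.data$area), .groups = "drop")
  cat("<environmental-space shift>", nrow(x$bins), "hex bins; area per slice:",
      paste(a$slice, signif(a$area, 4), collapse = ", "), "km2\n")
  invisible(x)
}
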