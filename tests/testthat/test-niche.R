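# Variable selection, thinning, ensemble SDM, refugia clustering, climate
# interpolation, colonisation simulation.

test_that("select_variables drops duplicates and collinear pairs by importance", {
  set.seed(1)
  n <- 200
  a <- rnorm(n)
  b <- rnorm(n)
  resp <- as.integer(a + rnorm(n, 0, 0.5) > 0) # a is informative
  env <- tibble::tibble(a = a, a_copy = a, b = b)
  kept <- select_variables(env, resp, seed = 1)
  expect_true("b" %in% kept)
  expect_equal(sum(c("a", "a_copy") %in% kept), 1)

  # orthogonal variables all survive
  env2 <- tibble::tibble(x = rnorm(n), y = rnorm(n), z = rnorm(n))
  expect_setequal(select_variables(env2, resp, seed = 1), c("x", "y", "z"))

  # correlated pair: the less important member goes
  x1 <- rnorm(n)
  x2 <- x1 + rnorm(n, 0, 0.3) # r > 0.9
  x3 <- rnorm(n)
  resp2 <- as.integer(x1 + rnorm(n, 0, 0.3) > 0) # x1 drives the response
  kept2 <- select_variables(tibble::tibble(x1 = x1, x2 = x2, x3 = x3),
                            resp2, seed = 2)
  expect_true("x1" %in% kept2)
  expect_false("x2" %in% kept2)

  # constant variable warned and dropped
  expect_warning(
    k3 <- select_variables(tibble::tibble(c = rep(1, n), x = rnorm(n),
                                          y = rnorm(n)), resp, seed = 1),
    "constant")
  expect_false("c" %in% k3)
})

test_that("thin_occurrences enforces the minimum spacing", {
  set.seed(3)
  occ <- tibble::tibble(lon = runif(100, 6, 10), lat = runif(100, 44, 47))
  expect_identical(thin_occurrences(occ, 0), occ)

  two <- tibble::tibble(lon = c(7, 7), lat = c(45, 45))
  expect_equal(nrow(thin_occurrences(two, 1, seed = 1)), 1)

  th <- thin_occurrences(occ, 50, seed = 2)
  d <- gc_dist_km(th)
  expect_true(all(d[upper.tri(d)] >= 50))

  # deterministic under the seed
  expect_identical(thin_occurrences(occ, 50, seed = 2), th)
  expect_error(thin_occurrences(occ[0, ], 10), "no occurrences")
})

test_that("the ensemble separates a clean niche and weights sum to one", {
  ls <- tiny_landscape(4)
  # presences strictly in the warm half
  warm <- ls[ls$land & ls$temp > stats::median(ls$temp[ls$land]), ]
  set.seed(8)
  occ <- warm[sample(nrow(warm), 60), c("lon", "lat")]
  ens <- suppressWarnings(fit_ensemble(occ, ls, background_ratio = 4, seed = 1))
  expect_equal(sum(ens$weights), 1)
  expect_true(all(ens$auc > 0.6)) # separable by temperature
  expect_gt(mean(ens$auc), 0.7)

  suit <- project_suitability(ens, env_slice(ls, "present")[ls$land, ])
  expect_true(all(suit$suitability >= 0 & suit$suitability <= 1))
  # ensemble probability bounded by component extremes per cell
  nd <- as.data.frame(env_slice(ls, "present")[ls$land, ens$vars])
  preds <- vapply(ens$components, function(f) f(nd), numeric(nrow(nd)))
  expect_true(all(suit$suitability >= apply(preds, 1, min) - 1e-9))
  expect_true(all(suit$suitability <= apply(preds, 1, max) + 1e-9))

  expect_error(project_suitability(ens, tibble::tibble(cell = 1, temp = 1)),
               "lacks model variable")
})

test_that("shuffled labels give chance-level AUC", {
  ls <- tiny_landscape(14)
  land <- ls[ls$land, ]
  aucs <- numeric(10)
  for (s in 1:10) {
    set.seed(s)
    occ <- land[sample(nrow(land), 40), c("lon", "lat")] # no niche structure
    ens <- suppressWarnings(fit_ensemble(occ, ls, background_ratio = 4,
                                         seed = s))
    aucs[s] <- mean(ens$auc)
  }
  expect_lt(abs(mean(aucs) - 0.5), 0.06)
})

test_that("climate interpolation hits its endpoints and midpoint", {
  ls <- tiny_landscape(6)
  e0 <- interpolate_climate(ls, 0)
  e1 <- interpolate_climate(ls, 1)
  eh <- interpolate_climate(ls, 0.5)
  for (v in env_vars(ls)) {
    expect_equal(e0[[v]], ls[[paste0(v, "_lgm")]])
    expect_equal(e1[[v]], ls[[v]])
    expect_equal(eh[[v]], (ls[[v]] + ls[[paste0(v, "_lgm")]]) / 2,
                 tolerance = 1e-12)
  }
  expect_error(interpolate_climate(ls, 1.2), "\\[0, 1\\]")
})

test_that("DBSCAN refugia clustering separates blobs and labels noise", {
  ls <- generate_landscape(n_rows = 30, n_cols = 30, seed = 2)
  ls$land <- TRUE
  # two compact blobs far apart plus one isolated cell
  blob1 <- ls$cell[ls$row <= 4 & ls$col <= 4]
  blob2 <- ls$cell[ls$row >= 27 & ls$col >= 27]
  lone <- ls$cell[ls$row == 15 & ls$col == 15]
  pres <- c(blob1, blob2, lone)
  suit <- structure(tibble::tibble(cell = ls$cell,
                                   suitability = as.numeric(ls$cell %in% pres),
                                   presence = ls$cell %in% pres),
                    class = c("sieve_suitability", class(tibble::tibble())))
  ref <- cluster_refugia(suit, ls, min_pts = 5)
  expect_equal(max(ref$cluster), 2)
  expect_equal(ref$cluster[match(lone, ref$cell)], 0L) # noise
  # one blob per cluster, each pure
  cl1 <- unique(ref$cluster[match(blob1, ref$cell)])
  cl2 <- unique(ref$cluster[match(blob2, ref$cell)])
  expect_length(cl1, 1)
  expect_length(cl2, 1)
  expect_false(cl1 == cl2)

  # single contiguous blob: one cluster
  suit1 <- suit
  suit1$presence <- suit1$cell %in% blob1
  expect_equal(max(cluster_refugia(suit1, ls, min_pts = 5)$cluster), 1)

  suit0 <- suit
  suit0$presence <- FALSE
  expect_error(cluster_refugia(suit0, ls), "no refugium")
})

test_that("three glacial blobs give three refugia", {
  ls <- generate_landscape(n_rows = 30, n_cols = 36, seed = 3)
  ls$land <- TRUE
  blobs <- list(ls$cell[ls$row <= 5 & ls$col <= 5],
                ls$cell[ls$row <= 5 & ls$col >= 32],
                ls$cell[ls$row >= 26 & ls$col >= 16 & ls$col <= 20])
  pres <- unlist(blobs)
  suit <- structure(tibble::tibble(cell = ls$cell,
                                   suitability = as.numeric(ls$cell %in% pres),
                                   presence = ls$cell %in% pres),
                    class = c("sieve_suitability", class(tibble::tibble())))
  ref <- cluster_refugia(suit, ls, min_pts = 5)
  expect_equal(max(ref$cluster), 3)
})

test_that("colonisation obeys dispersal caps, exclusivity, and saturation", {
  ls <- generate_landscape(n_rows = 20, n_cols = 20, warming_amplitude = 0,
                           seed = 10)
  # a fake ensemble whose suitability is a fixed temperature rule
  thr <- stats::median(ls$temp[ls$land])
  fake <- structure(list(
    components = list(rule = function(nd) as.numeric(nd$temp > thr)),
    auc = c(rule = 1), weights = c(rule = 1), vars = "temp",
    threshold = 0.5, train = NULL), class = "sieve_ensemble")
  suit_cells <- ls$land & ls$temp > thr
  seeds <- list(L1 = which(suit_cells)[1])

  # d = Inf, static climate: final occupancy equals thresholded suitability
  hist_inf <- simulate_colonisation(list(L1 = fake), seeds, ls, n_steps = 3,
                                    d_km = 1e9)
  final <- hist_inf$occupancy[[length(hist_inf$occupancy)]]
  expect_setequal(which(final == 1L), which(suit_cells))

  # bounded dispersal: the audit finds no violation, and occupancy never
  # exceeds one lineage per cell
  hist_d <- simulate_colonisation(list(L1 = fake), seeds, ls, n_steps = 6,
                                  d_km = 15)
  expect_equal(nrow(audit_colonisation(hist_d, ls)), 0)
  for (occ in hist_d$occupancy) {
    expect_true(all(occ %in% c(0L, 1L)))
  }
  expect_error(simulate_colonisation(list(L1 = fake), seeds, ls, d_km = 0),
               "positive")
})

test_that("two symmetric refugia meet at an equidistant contact front", {
  # flat, fully suitable landscape; two seeds mirrored about the vertical
  # midline meet in the middle (up to the lowest-lineage tie-break)
  ls <- generate_landscape(n_rows = 11, n_cols = 21, warming_amplitude = 0,
                           seed = 12)
  ls$land <- TRUE
  always <- structure(list(
    components = list(one = function(nd) rep(1, nrow(nd))),
    auc = c(one = 1), weights = c(one = 1), vars = "temp",
    threshold = 0.5, train = NULL), class = "sieve_ensemble")
  left <- ls$cell[ls$row == 6 & ls$col == 1]
  right <- ls$cell[ls$row == 6 & ls$col == 21]
  hist2 <- simulate_colonisation(list(A = always, B = always),
                                 list(A = left, B = right), ls,
                                 n_steps = 30, d_km = 12)
  final <- hist2$occupancy[[length(hist2$occupancy)]]
  expect_equal(nrow(audit_colonisation(hist2, ls)), 0)
  # every A-cell is (weakly) closer to the A seed than the B seed, within
  # one cell of slack for the tie-break at the front
  dA <- gc_dist_km(ls, ls[ls$cell == left, ])[, 1]
  dB <- gc_dist_km(ls, ls[ls$cell == right, ])[, 1]
  csize <- attr(ls, "cell_size_km")
  expect_true(all(dA[final == 1L] <= dB[final == 1L] + csize))
  expect_true(all(dB[final == 2L] <= dA[final == 2L] + csize))
  # both lineages persist
  expect_true(all(c(1L, 2L) %in% final))
})
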