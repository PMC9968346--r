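# Refugial assignment, least-cost paths, path divergence, MEM, and the
# glacial genomic offset metric.

flat_resistance <- function(nr = 12, nc = 12, seed = 1, value = 1) {
  ls <- generate_landscape(n_rows = nr, n_cols = nc, seed = seed)
  ls$land <- TRUE
  suit <- structure(tibble::tibble(cell = ls$cell,
                                   suitability = rep(value, nrow(ls)),
                                   presence = TRUE),
                    class = c("sieve_suitability", class(tibble::tibble())))
  list(landscape = ls, resistance = resistance_surface(suit, ls))
}

test_that("least-cost paths follow uniform-cost geometry and route around walls", {
  fr <- flat_resistance(10, 10, seed = 2)
  ls <- fr$landscape
  src <- ls$cell[ls$row == 5 & ls$col == 2]
  tgt <- ls$cell[ls$row == 5 & ls$col == 9]
  lp <- least_cost_paths(fr$resistance, src, tgt)
  # uniform resistance: cost proportional to straight-line grid distance
  res_unit <- 1 / (1 + 1e-3)
  expect_equal(lp$cost, 7 * attr(ls, "cell_size_km") * res_unit,
               tolerance = 1e-6)

  # an impassable wall with one gap forces the path through the gap
  suit <- tibble::tibble(cell = ls$cell, suitability = 1, presence = TRUE)
  wall <- ls$col == 6 & ls$row != 9
  suit$suitability[wall] <- 1e-9 # effectively infinite resistance
  class(suit) <- c("sieve_suitability", class(tibble::tibble()))
  res_w <- resistance_surface(suit, ls)
  lp_w <- least_cost_paths(res_w, src, tgt)
  path_cells <- lp_w$path[[1]]
  gap <- ls$cell[ls$row == 9 & ls$col == 6]
  crossing <- intersect(path_cells, ls$cell[ls$col == 6])
  expect_equal(crossing, gap)

  # Dijkstra oracle on the same graph
  g <- res_w$graph
  oracle <- igraph::distances(g, v = match(src, res_w$cells),
                              to = match(tgt, res_w$cells))
  expect_equal(lp_w$cost, as.numeric(oracle))
})

test_that("refugial assignment picks the nearest source with documented tie-breaks", {
  ls <- generate_landscape(n_rows = 12, n_cols = 24, seed = 3)
  ls$land <- TRUE
  # two refugia: a large western blob and a small eastern blob
  west <- ls$cell[ls$row %in% 5:8 & ls$col %in% 2:4]
  east <- ls$cell[ls$row %in% 6:7 & ls$col %in% 21:22]
  ref <- structure(tibble::tibble(
    cell = c(west, east),
    lon = ls$lon[match(c(west, east), ls$cell)],
    lat = ls$lat[match(c(west, east), ls$cell)],
    cluster = rep(c(1L, 2L), c(length(west), length(east)))),
    class = c("sieve_refugia", class(tibble::tibble())))

  # a population inside a refugium is its own source
  inside <- tibble::tibble(id = "IN", cell = west[1],
                           lon = ls$lon[west[1]], lat = ls$lat[west[1]])
  a_in <- assign_refugial_source(inside, ref, ls)
  expect_equal(a_in$source_cell, west[1])
  expect_equal(a_in$distance_km, 0)

  # clearly nearer the eastern refugium
  near_e <- tibble::tibble(id = "E", cell = ls$cell[ls$row == 6 & ls$col == 19],
                           lon = ls$lon[ls$row == 6 & ls$col == 19],
                           lat = ls$lat[ls$row == 6 & ls$col == 19])
  expect_equal(assign_refugial_source(near_e, ref, ls)$source_cluster, 2L)

  # path mode with a barrier: the geographically nearer refugium loses
  suit <- tibble::tibble(cell = ls$cell, suitability = 1, presence = TRUE)
  barrier <- ls$col == 20 # wall between the population at col 19 and east
  suit$suitability[barrier] <- 1e-9
  class(suit) <- c("sieve_suitability", class(tibble::tibble()))
  res <- resistance_surface(suit, ls)
  a_path <- assign_refugial_source(near_e, ref, ls, mode = "path",
                                   resistance = res)
  expect_equal(a_path$source_cluster, 1L)
})

test_that("path divergence follows its set arithmetic", {
  expect_equal(path_divergence(1:10, 1:10), 0)
  expect_equal(path_divergence(1:5, 6:10), 1)
  expect_equal(path_divergence(2:4, 1:10), 0) # nested
  expect_equal(path_divergence(1:4, 3:6), 1 - 2 / 4)
  expect_error(path_divergence(integer(0), 1:3), "empty")
})

test_that("MEM basis is centred, orthogonal, and gradient-like on a line", {
  # populations on a line: MEM1 is a monotone gradient along it
  k <- 8
  pops <- tibble::tibble(id = sprintf("P%d", 1:k),
                         lon = seq(6, 8, length.out = k), lat = rep(45, k))
  mem <- build_mem(pops)
  v <- mem$vectors
  expect_true(all(abs(colMeans(v)) < 1e-9))
  gram <- unname(crossprod(v))
  expect_equal(gram, diag(diag(gram)), tolerance = 1e-9)
  # a smooth gradient along the transect (sign is arbitrary; the analytic
  # sine-family eigenvectors carry slight end inflections)
  m1 <- mem$mem1$MEM1
  expect_gt(abs(cor(m1, seq_len(k))), 0.85)
  expect_gt(abs(cor(m1, seq_len(k), method = "spearman")), 0.85)

  # permutation equivariance
  perm <- c(3, 1, 4, 2, 8, 6, 5, 7)
  mem_p <- build_mem(pops[perm, ])
  m1p <- mem_p$mem1$MEM1[match(pops$id, mem_p$mem1$id)]
  expect_equal(abs(m1p), abs(m1), tolerance = 1e-9)

  expect_error(build_mem(pops[1:3, ]), "at least 4")
})

test_that("MEM interpolation is exact at data points and bounded", {
  fr <- flat_resistance(8, 16, seed = 5)
  ls <- fr$landscape
  cells <- ls$cell[ls$row == 4 & ls$col %in% c(2, 6, 10, 14)]
  pops <- tibble::tibble(id = sprintf("P%d", 1:4), cell = cells,
                         lon = ls$lon[cells], lat = ls$lat[cells])
  mem <- build_mem(pops)
  ip <- interpolate_mem(mem, fr$resistance, pops)
  at_pop <- ip$MEM1[match(pops$cell, ip$cell)]
  expect_equal(at_pop, mem$mem1$MEM1, tolerance = 1e-9)
  expect_true(all(ip$MEM1 >= min(mem$mem1$MEM1) - 1e-9))
  expect_true(all(ip$MEM1 <= max(mem$mem1$MEM1) + 1e-9))

  # uniform resistance reduces to inverse-distance weighting on path costs
  # proportional to geographic distance: compare against a plain IDW oracle
  # built from the same least-cost distances
  dc <- igraph::distances(fr$resistance$graph,
                          v = match(pops$cell, fr$resistance$cells),
                          weights = igraph::E(fr$resistance$graph)$weight)
  target <- 40
  d <- dc[, target]
  w <- 1 / d^2
  expect_equal(ip$MEM1[target], sum(w * mem$mem1$MEM1) / sum(w),
               tolerance = 1e-9)
})

test_that("the glacial genomic offset is a metric on transformed space", {
  set.seed(6)
  tv <- list(
    predictors = c("temp", "lon", "lat"),
    knots = list(temp = seq(0, 10, length.out = 21),
                 lon = seq(6, 9, length.out = 21),
                 lat = seq(44, 46, length.out = 21)),
    cumimp = list(temp = cumsum(c(0, runif(20))),
                  lon = cumsum(c(0, runif(20, 0, 0.3))),
                  lat = cumsum(c(0, runif(20, 0, 0.3)))),
    total_importance = NULL, weights = 1, snp_r2 = 1,
    spatial_vars = c("lon", "lat"))
  tv$total_importance <- vapply(tv$cumimp, max, numeric(1))
  class(tv) <- "sieve_turnover"

  ids <- sprintf("P%d", 1:6)
  env_a <- tibble::tibble(id = ids, temp = runif(6, 0, 10),
                          lon = runif(6, 6, 9), lat = runif(6, 44, 46))
  env_b <- dplyr::mutate(env_a, temp = runif(6, 0, 10), lon = runif(6, 6, 9))
  env_c <- dplyr::mutate(env_a, temp = runif(6, 0, 10), lat = runif(6, 44, 46))

  # identity: identical endpoints give zero offset
  off0 <- glacial_genomic_offset(tv, env_a, env_a)
  expect_true(all(off0$offset < 1e-12))

  # symmetry
  oab <- glacial_genomic_offset(tv, env_a, env_b)$offset
  oba <- glacial_genomic_offset(tv, env_b, env_a)$offset
  expect_equal(oab, oba, tolerance = 1e-12)

  # triangle inequality on random triples
  obc <- glacial_genomic_offset(tv, env_b, env_c)$offset
  oac <- glacial_genomic_offset(tv, env_a, env_c)$offset
  expect_true(all(oac <= oab + obc + 1e-12))

  # offset equals the norm of its components
  oo <- glacial_genomic_offset(tv, env_a, env_b)
  comp <- as.matrix(oo[, grep("^comp_", names(oo))])
  expect_equal(oo$offset, sqrt(rowSums(comp^2)), tolerance = 1e-12)

  # one-step curve straddled by the endpoints yields that predictor's
  # total importance
  tv1 <- tv
  tv1$predictors <- "temp"
  tv1$knots <- tv$knots["temp"]
  step <- c(rep(0, 10), rep(4, 11)) # step between knots 10 and 11
  tv1$cumimp <- list(temp = step)
  tv1$total_importance <- c(temp = 4)
  tv1$spatial_vars <- character()
  e1 <- tibble::tibble(id = "P", temp = 1)
  e2 <- tibble::tibble(id = "P", temp = 9)
  expect_equal(glacial_genomic_offset(tv1, e1, e2)$offset, 4)

  # missing endpoint flagged, not dropped
  expect_warning(
    om <- glacial_genomic_offset(tv, env_a, env_b[-2, ]),
    "missing refugial endpoint")
  expect_true(om$flagged[2])
  expect_true(is.na(om$offset[2]))
  expect_equal(nrow(om), 6)

  # excluding spatial co-variates removes their components
  on <- glacial_genomic_offset(tv, env_a, env_b, include_spatial = FALSE)
  expect_false(any(grepl("comp_lon", names(on))))
  expect_true(all(on$offset <= oab + 1e-12))
})
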