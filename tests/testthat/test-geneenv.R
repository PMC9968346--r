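# Per-SNP forests, turnover functions, environment transformation,
# composition PCA, environmental-space shift.

toy_predictors <- function(n = 30, seed = 1) {
  set.seed(seed)
  tibble::tibble(temp = rnorm(n), prec = rnorm(n), lon = runif(n, 6, 9),
                 lat = runif(n, 44, 46))
}

test_that("snp forests recover a deterministic step response", {
  # a SNP that is a step function of one predictor earns R2 near 1 with
  # importance concentrated on that predictor, across seeds
  hits_r2 <- 0; hits_imp <- 0
  for (s in 1:10) {
    X <- toy_predictors(30, s)
    y <- as.numeric(X$temp > 0) * 0.6 + 0.2
    fit <- fit_snp_forests(matrix(y, ncol = 1), X, n_trees = 100, seed = s)
    hits_r2 <- hits_r2 + (fit$r2 > 0.8)
    hits_imp <- hits_imp + (which.max(fit$importance[1, ]) == 1)
  }
  expect_gte(hits_r2, 9)
  expect_gte(hits_imp, 9)
})

test_that("pure-noise SNPs are flagged inactive on average", {
  X <- toy_predictors(30, 3)
  set.seed(4)
  Y <- matrix(runif(30 * 100), 30, 100)
  fit <- fit_snp_forests(Y, X, n_trees = 100, seed = 5)
  expect_lte(mean(fit$r2), 0.05)
  expect_gt(mean(!fit$active), 0.5)
})

test_that("forest fits are deterministic under a fixed seed", {
  X <- toy_predictors(25, 6)
  set.seed(7)
  Y <- matrix(runif(25 * 20), 25, 20)
  f1 <- fit_snp_forests(Y, X, n_trees = 50, seed = 11)
  f2 <- fit_snp_forests(Y, X, n_trees = 50, seed = 11)
  expect_identical(f1$r2, f2$r2)
  expect_identical(f1$importance, f2$importance)
  expect_identical(f1$binned, f2$binned)
})

test_that("single-tree split choice agrees with an independent CART oracle", {
  # one greedy tree (mtry = all, no depth beyond the first split is
  # compared) must pick the same first split as rpart does
  skip_if_not_installed("rpart")
  set.seed(9)
  X <- tibble::tibble(a = rnorm(40), b = rnorm(40))
  y <- ifelse(X$a > 0.3, 0.8, 0.2) + rnorm(40, 0, 0.02)
  fit <- fit_snp_forests(matrix(y, ncol = 1), X, n_trees = 200, mtry = 2,
                         seed = 1)
  # dominant importance on a
  expect_gt(fit$importance[1, "a"], 10 * fit$importance[1, "b"])
  rp <- rpart::rpart(y ~ a + b, data = cbind(X, y = y),
                     control = rpart::rpart.control(maxdepth = 1, cp = 0,
                                                    minsplit = 5))
  rp_var <- rownames(rp$splits)[1]
  expect_equal(rp_var, "a")
  rp_split <- rp$splits[1, "index"]
  # the bulk of harvested split mass for a sits in the bin containing the
  # oracle split point
  bins <- fit$breaks$a
  b_idx <- findInterval(rp_split, bins, all.inside = TRUE)
  mass <- fit$binned[1, 1, ]
  window <- max(1, b_idx - 5):min(length(mass), b_idx + 5)
  expect_gt(sum(mass[window]) / sum(mass), 0.5)
})

test_that("turnover curves are monotone, conserved, and correctly combined", {
  set.seed(12)
  X <- toy_predictors(30, 12)
  Y <- cbind(
    vapply(1:10, function(i) plogis(2 * X$temp + rnorm(1)), numeric(30)),
    matrix(runif(30 * 10), 30, 10))
  colnames(Y) <- sprintf("S%02d", 1:20)
  fit <- fit_snp_forests(Y, X, n_trees = 100, seed = 13)
  tv <- build_turnover(fit)
  for (p in tv$predictors) {
    ci <- tv$cumimp[[p]]
    expect_true(all(diff(ci) >= -1e-12)) # monotone
    expect_equal(ci[1], 0)               # zero at the observed minimum
    expect_equal(ci[length(ci)], tv$total_importance[[p]], tolerance = 1e-9)
  }
  # weighted-mean endpoint identity: combined total equals the
  # R2-weighted mean of per-SNP raw totals
  w <- pmax(fit$r2, 0); w[!fit$active] <- 0
  for (j in seq_along(tv$predictors)) {
    raw_tot <- apply(fit$binned[, j, , drop = FALSE], 1, sum)
    expect_equal(tv$total_importance[[j]], sum(w * raw_tot) / sum(w),
                 tolerance = 1e-9)
  }

  # two identical SNPs combine to the single-SNP curve
  fit1 <- fit_snp_forests(Y[, 1, drop = FALSE], X, n_trees = 100, seed = 3)
  fit2 <- fit1
  fit2$binned <- array(rep(fit1$binned, each = 2),
                       dim = c(2, dim(fit1$binned)[2:3]))
  fit2$r2 <- rep(fit1$r2, 2)
  fit2$importance <- fit1$importance[c(1, 1), , drop = FALSE]
  fit2$active <- rep(fit1$active, 2)
  fit2$snp_ids <- c("a", "b")
  tv1 <- build_turnover(fit1)
  tv2 <- build_turnover(fit2)
  for (p in tv1$predictors) {
    expect_equal(tv2$cumimp[[p]], tv1$cumimp[[p]], tolerance = 1e-9)
  }

  # all-noise input has no active SNP
  fitn <- fit_snp_forests(matrix(runif(30), ncol = 1), X, n_trees = 30,
                          seed = 5)
  if (!any(fitn$active)) expect_error(build_turnover(fitn), "no gene-environment")
})

test_that("noise-only turnover carries under 10% of the causal signal mass", {
  # 20-seed calibration at matched SNP counts: the R2-weighted signal mass
  # (sum over SNPs of weight x total split importance, the quantity the
  # combined curves distribute along the gradients) of an all-noise panel
  # stays below 10% of a panel containing real gene-environment signal
  signal_mass <- function(fit) {
    w <- pmax(fit$r2, 0); w[!fit$active] <- 0
    sum(w * rowSums(fit$importance))
  }
  ratio <- numeric(20)
  for (s in 1:20) {
    X <- toy_predictors(30, s + 40)
    set.seed(s)
    Y_causal <- cbind(
      vapply(1:10, function(i) plogis(3 * X$temp + rnorm(1)) +
               rnorm(30, 0, 0.05), numeric(30)),
      matrix(runif(30 * 40), 30, 40))
    Y_noise <- matrix(runif(30 * 50), 30, 50)
    fit_c <- fit_snp_forests(Y_causal, X, n_trees = 60, seed = s)
    fit_n <- fit_snp_forests(Y_noise, X, n_trees = 60, seed = s)
    ratio[s] <- signal_mass(fit_n) / signal_mass(fit_c)
  }
  expect_lt(mean(ratio), 0.1)
})

test_that("transform_environment interpolates, clamps, and stays monotone", {
  tv <- list(
    predictors = "x",
    knots = list(x = seq(0, 1, length.out = 11)),
    cumimp = list(x = c(0, 0, 0, 0, 0, 5, 5, 5, 5, 5, 5)), # one step at 0.45
    total_importance = c(x = 5), weights = 1, snp_r2 = 1,
    spatial_vars = character())
  class(tv) <- "sieve_turnover"
  out <- transform_environment(tv, tibble::tibble(x = c(-1, 0, 0.2, 0.45, 0.6, 1, 2)))
  expect_equal(out$x[1], 0)  # clamp left
  expect_equal(out$x[2], 0)  # fitted minimum maps to zero
  expect_equal(out$x[3], 0)  # below the step
  expect_equal(out$x[4], 2.5) # interpolating across the step bin
  expect_equal(out$x[5], 5)  # above the step
  expect_equal(out$x[7], 5)  # clamp right at total importance

  # monotone in the input coordinate
  xs <- sort(runif(50, -0.5, 1.5))
  ys <- transform_environment(tv, tibble::tibble(x = xs))$x
  expect_true(all(diff(ys) >= -1e-12))

  expect_error(transform_environment(tv, tibble::tibble(y = 1)),
               "missing predictor")
})

test_that("composition PCA centres, honours exclusion, and aligns with variance", {
  # constant grid: all scores zero
  const <- tibble::tibble(a = rep(1, 10), b = rep(2, 10), lon = rep(0, 10))
  sc <- suppressWarnings(composition_pca(const))
  expect_true(all(abs(sc$PC1) < 1e-12))

  # variance concentrated on one variable: PC1 aligns with it
  set.seed(15)
  comp <- tibble::tibble(a = rnorm(50, sd = 10), b = rnorm(50, sd = 0.1),
                         c = rnorm(50, sd = 0.1))
  sc2 <- composition_pca(comp)
  pc <- attr(sc2, "pca")
  expect_gt(abs(pc$rotation["a", 1]), 0.99)

  # spatial exclusion: lon/lat never influence the scores
  comp_sp <- dplyr::mutate(comp, lon = rnorm(50, sd = 100), lat = rnorm(50))
  sc3 <- composition_pca(comp_sp, exclude_spatial = TRUE)
  comp_sp2 <- dplyr::mutate(comp_sp, lon = lon * 5, lat = lat + 3)
  sc4 <- composition_pca(comp_sp2, exclude_spatial = TRUE)
  expect_equal(sc3$PC1, sc4$PC1)
})

test_that("environmental-space shift conserves area and tracks loadings", {
  ls <- tiny_landscape(16)
  shift <- env_space_shift(ls)
  areas <- tapply(shift$bins$area, shift$bins$slice, sum)
  land_area <- sum(ls$land) * attr(ls, "cell_size_km")^2
  expect_equal(unname(areas[["present"]]), land_area)
  expect_equal(unname(areas[["lgm"]]), land_area)

  # identical slices produce identical bin tables
  ls0 <- generate_landscape(n_rows = 20, n_cols = 20, warming_amplitude = 0,
                            seed = 2)
  s0 <- env_space_shift(ls0)
  b_now <- dplyr::arrange(s0$bins[s0$bins$slice == "present", -1], hex_q, hex_r)
  b_lgm <- dplyr::arrange(s0$bins[s0$bins$slice == "lgm", -1], hex_q, hex_r)
  expect_equal(as.data.frame(b_now), as.data.frame(b_lgm))

  # a uniform shift in one variable moves the cloud along that variable's
  # loading direction
  ls1 <- ls0
  ls1$temp_lgm <- ls1$temp - 2
  s1 <- env_space_shift(ls1)
  pc <- s1$pca
  delta_expected <- -(2 / pc$scale[["temp"]]) * pc$rotation["temp", 1:2]
  now <- s1$scores[s1$scores$slice == "present", ]
  lgm <- s1$scores[s1$scores$slice == "lgm", ]
  expect_equal(mean(lgm$PC1) - mean(now$PC1), unname(delta_expected[1]),
               tolerance = 1e-9)
  expect_equal(mean(lgm$PC2) - mean(now$PC2), unname(delta_expected[2]),
               tolerance = 1e-9)
})
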