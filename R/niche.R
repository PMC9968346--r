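# Niche modelling: environmental variable selection, the four-component
# ensemble distribution model with AUC weighting, DBSCAN refugia
# delineation, climate interpolation between the LGM and the present, and
# the dispersal-limited, competitively exclusive colonisation simulation.

#' Extract one time slice of a landscape's environment
#'
#' @param landscape A `sieve_landscape`.
#' @param slice `"present"` or `"lgm"`.
#' @return Tibble with `cell` plus one column per environmental variable
#'   (LGM columns are renamed to their base names).
#' @export
env_slice <- function(landscape, slice = c("present", "lgm")) {
  slice <- match.arg(slice)
  vars <- env_vars(landscape)
  cols <- if (slice == "present") vars else paste0(vars, "_lgm")
  out <- landscape[, c("cell", cols)]
  names(out) <- c("cell", vars)
  as_tibble(out)
}

rf_importance <- function(data, response) {
  fit <- randomForest::randomForest(
    x = as.data.frame(data), y = factor(response), ntree = 200)
  imp <- randomForest::importance(fit)[, 1]
  imp[names(data)]
}

#' Select important, low-collinearity environmental variables
#'
#' Iteratively removes variables until every pairwise Pearson correlation is
#' below `r_max` and every variance inflation factor (VIF) is below
#' `vif_max`: from each violating pair (or VIF-violating set) the variable
#' with the lower random-forest importance for the presence/background
#' response is dropped. Constant variables are dropped up front with a
#' warning.
#'
#' @param env_table Tibble/data frame of candidate variables (rows =
#'   presence + background points).
#' @param response Binary vector (1 = presence) aligned with `env_table`.
#' @param vif_max,r_max Collinearity thresholds (defaults 10 and 0.7).
#' @param seed Seed for the random-forest importance fit.
#' @return Character vector of retained variable names.
#' @export
select_variables <- function(env_table, response, vif_max = 10, r_max = 0.7,
                             seed = 1) {
  env_table <- as_tibble(env_table)
  if (ncol(env_table) < 3) abort("need at least 3 candidate variables")
  const <- vapply(env_table, function(x) sd(x) == 0 || !is.finite(sd(x)), logical(1))
  if (any(const)) {
    warn(paste("dropping constant variable(s):",
               paste(names(env_table)[const], collapse = ", ")))
    env_table <- env_table[!const]
  }
  set.seed(seed)
  imp <- rf_importance(env_table, response)
  vars <- names(env_table)
  vif_of <- function(v) {
    cm <- cor(env_table[v])
    diag(solve(cm))
  }
  repeat {
    cm <- abs(cor(env_table[vars]))
    diag(cm) <- 0
    if (max(cm) >= r_max) {
      idx <- which(cm == max(cm), arr.ind = TRUE)[1, ]
      pair <- vars[idx]
      drop <- pair[which.min(imp[pair])]
      vars <- setdiff(vars, drop)
      next
    }
    if (length(vars) > 1) {
      v <- tryCatch(vif_of(vars), error = function(e) rep(1, length(vars)))
      if (max(v) >= vif_max) {
        bad <- vars[v >= vif_max]
        drop <- bad[which.min(imp[bad])]
        vars <- setdiff(vars, drop)
        next
      }
    }
    break
  }
  vars
}

#' Thin occurrences to a minimum spacing
#'
#' Greedy geographic disaggregation: records are visited in a seeded random
#' order and kept only if at least `min_spacing_km` from every record already
#' retained, balancing sampling density in space.
#'
#' @param occ Tibble with `lon`, `lat` (extra columns are preserved).
#' @param min_spacing_km Minimum pairwise great-circle distance to keep.
#' @param seed Integer seed for the visiting order.
#' @export
thin_occurrences <- function(occ, min_spacing_km, seed = 1) {
  if (nrow(occ) == 0) abort("no occurrences to thin")
  if (min_spacing_km <= 0) return(as_tibble(occ))
  set.seed(seed)
  ord <- sample(nrow(occ))
  kept <- integer(0)
  for (i in ord) {
    if (length(kept) == 0) { kept <- i; next }
    d <- gc_dist_km(occ[i, ], occ[kept, , drop = FALSE])
    if (min(d) >= min_spacing_km) kept <- c(kept, i)
  }
  as_tibble(occ[sort(kept), , drop = FALSE])
}

# quadratic feature expansion used by the entropy-style component
maxent_features <- function(x) {
  x <- as.matrix(x)
  cbind(x, x^2)
}

auc_of <- function(labels, scores) {
  as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                 direction = "<", levels = c(0, 1))))
}

#' Fit an AUC-weighted four-component distribution model ensemble
#'
#' Components: (1) linear-logistic GLM, (2) additive spline logistic (GAM),
#' (3) entropy-style L1-regularised logistic on linear + quadratic features
#' (a maxent-like estimating structure), (4) random forest. Background
#' points are sampled uniformly from the land mask. Each component's AUC is
#' estimated from out-of-fold predictions under k-fold cross-validation;
#' ensemble weights are the AUCs normalised to sum to one. The binarisation
#' threshold maximises the true skill statistic (TSS) on the out-of-fold
#' ensemble predictions. A component that fails to fit is excluded with a
#' warning and the weights renormalised.
#'
#' @param occ Occurrence tibble (`lon`, `lat`).
#' @param landscape A `sieve_landscape` providing present-day environment and
#'   the land mask.
#' @param vars Environmental variables to use (default: all).
#' @param background_ratio Background points per presence (default 10).
#' @param k_folds Cross-validation folds (default 5).
#' @param seed Integer seed.
#' @return A `sieve_ensemble` object.
#' @export
fit_ensemble <- function(occ, landscape, vars = NULL, background_ratio = 10,
                         k_folds = 5, seed = 1) {
  if (is.null(vars)) vars <- env_vars(landscape)
  set.seed(seed)
  land <- dplyr::filter(landscape, .data$land)
  # snap presences to their nearest land cell
  d <- gc_dist_km(occ, land)
  pres_cells <- land$cell[apply(d, 1, which.min)]
  n_bg <- background_ratio * length(pres_cells)
  # background drawn from unoccupied land cells so no cell carries both labels
  bg_pool <- setdiff(land$cell, pres_cells)
  bg_cells <- sample(bg_pool, min(n_bg, length(bg_pool)),
                     replace = length(bg_pool) < n_bg)
  cells <- c(pres_cells, bg_cells)
  y <- rep(c(1L, 0L), c(length(pres_cells), length(bg_cells)))
  X <- env_slice(landscape, "present")[match(cells, landscape$cell), vars]
  ctr <- vapply(X, mean, numeric(1)); scl <- vapply(X, sd, numeric(1))
  scl[scl == 0] <- 1
  dat <- as.data.frame(X)

  fitters <- list(
    glm = function(d, yy) {
      f <- stats::glm(yy ~ ., data = d, family = stats::binomial())
      function(nd) as.numeric(predict(f, nd, type = "response"))
    },
    gam = function(d, yy) {
      rhs <- paste(sprintf("s(%s, k = 4)", names(d)), collapse = " + ")
      f <- mgcv::gam(stats::as.formula(paste("yy ~", rhs)),
                     data = cbind(yy = yy, d), family = stats::binomial())
      function(nd) as.numeric(predict(f, nd, type = "response"))
    },
    maxent = function(d, yy) {
      Z <- maxent_features(scale(as.matrix(d), ctr, scl))
      f <- glmnet::cv.glmnet(Z, yy, family = "binomial", alpha = 1, nfolds = 5)
      function(nd) {
        Zn <- maxent_features(scale(as.matrix(nd), ctr, scl))
        as.numeric(predict(f, Zn, s = "lambda.min", type = "response"))
      }
    },
    rf = function(d, yy) {
      # nodesize > 1 keeps presence/background probabilities calibrated
      f <- randomForest::randomForest(x = d, y = factor(yy, levels = 0:1),
                                      ntree = 300, nodesize = 5)
      function(nd) as.numeric(predict(f, nd, type = "prob")[, "1"])
    }
  )

  folds <- sample(rep(seq_len(k_folds), length.out = length(y)))
  oof <- matrix(NA_real_, length(y), length(fitters),
                dimnames = list(NULL, names(fitters)))
  ok <- setNames(rep(TRUE, length(fitters)), names(fitters))
  for (m in names(fitters)) {
    res <- try({
      for (kf in seq_len(k_folds)) {
        tr <- folds != kf
        pr <- fitters[[m]](dat[tr, , drop = FALSE], y[tr])
        oof[!tr, m] <- pr(dat[!tr, , drop = FALSE])
      }
    }, silent = TRUE)
    if (inherits(res, "try-error") || anyNA(oof[, m])) {
      warn(paste("component", m, "failed; excluded from the ensemble"))
      ok[m] <- FALSE
    }
  }
  if (!any(ok)) abort("no ensemble component could be fitted")
  auc <- vapply(names(fitters)[ok], function(m) auc_of(y, oof[, m]), numeric(1))
  weights <- auc / sum(auc)
  # final components refitted on all data
  components <- lapply(names(fitters)[ok], function(m) fitters[[m]](dat, y))
  names(components) <- names(fitters)[ok]
  ens_oof <- as.numeric(oof[, ok, drop = FALSE] %*% weights)
  thr <- tss_threshold(y, ens_oof)
  structure(list(components = components, auc = auc, weights = weights,
                 vars = vars, threshold = thr,
                 train = tibble(cell = cells, presence = y)),
            class = "sieve_ensemble")
}

tss_threshold <- function(y, p) {
  cand <- sort(unique(p))
  if (length(cand) > 200) cand <- quantile(p, seq(0.005, 0.995, length.out = 200))
  tss <- vapply(cand, function(t) {
    pred <- p >= t
    sens <- sum(pred & y == 1) / sum(y == 1)
    spec <- sum(!pred & y == 0) / sum(y == 0)
    sens + spec - 1
  }, numeric(1))
  cand[which.max(tss)]
}

#' @export
print.sieve_ensemble <- function(x, ...) {
  cat("<ensemble SDM>", length(x$components), "components; AUC:",
      paste(names(x$auc), signif(x$auc, 3), collapse = ", "),
      "; threshold", signif(x$threshold, 3), "\n")
  invisible(x)
}

#' @export
tidy.sieve_ensemble <- function(x, ...) {
  tibble(component = names(x$auc), auc = unname(x$auc),
         weight = unname(x$weights))
}

#' @export
glance.sieve_ensemble <- function(x, ...) {
  tibble(n_components = length(x$components), threshold = x$threshold,
         mean_auc = mean(x$auc))
}

#' Project an ensemble model onto an environment
#'
#' Weighted average of the component probabilities per cell, binarised at
#' the model's TSS-maximising threshold.
#'
#' @param model A `sieve_ensemble`.
#' @param env Tibble with a `cell` column and the model's variables (e.g.
#'   [env_slice()] or [interpolate_climate()] output), restricted to the
#'   cells to predict.
#' @return A `sieve_suitability` tibble: `cell`, `suitability`, `presence`.
#' @export
project_suitability <- function(model, env) {
  missing <- setdiff(model$vars, names(env))
  if (length(missing) > 0) {
    abort(paste("environment lacks model variable(s):",
                paste(missing, collapse = ", ")))
  }
  nd <- as.data.frame(env[model$vars])
  preds <- vapply(model$components, function(f) f(nd), numeric(nrow(nd)))
  if (nrow(nd) == 1) preds <- matrix(preds, nrow = 1)
  s <- as.numeric(preds %*% model$weights)
  structure(tibble(cell = env$cell, suitability = s,
                   presence = s >= model$threshold),
            threshold = model$threshold,
            class = c("sieve_suitability", class(tibble())))
}

#' Delineate refugia by density-based clustering of presence cells
#'
#' Runs DBSCAN (classic region-growing formulation) on the coordinates of
#' predicted-presence cells, in kilometre space. Clusters are labelled by
#' decreasing size (1 = largest); unclustered cells get cluster 0 (noise).
#'
#' @param suitability A `sieve_suitability` (typically of the LGM slice).
#' @param landscape The landscape the suitability was computed on.
#' @param eps Neighbourhood radius in km (default: two cell diagonals).
#' @param min_pts Minimum neighbourhood size for a core point (default 5).
#' @return A `sieve_refugia` tibble: `cell`, `lon`, `lat`, `cluster`;
#'   attribute `centroids` (per-cluster mean lon/lat and size).
#' @export
cluster_refugia <- function(suitability, landscape, eps = NULL, min_pts = 5) {
  pres <- suitability$cell[suitability$presence]
  if (length(pres) == 0) abort("no refugium predicted: zero presence cells")
  if (is.null(eps)) eps <- 2 * sqrt(2) * attr(landscape, "cell_size_km")
  idx <- match(pres, landscape$cell)
  pts <- tibble(cell = pres, lon = landscape$lon[idx], lat = landscape$lat[idx])
  # planar km coordinates (grids are regional; adequate for clustering)
  xy <- cbind(pts$lon * 111.32 * cos(mean(pts$lat) * pi / 180),
              pts$lat * 111.32)
  n <- nrow(xy)
  dm <- as.matrix(stats::dist(xy))
  labels <- rep(0L, n)
  visited <- rep(FALSE, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (visited[i]) next
    visited[i] <- TRUE
    nb <- which(dm[i, ] <= eps)
    if (length(nb) < min_pts) next # noise unless claimed later
    cl <- cl + 1L
    labels[i] <- cl
    queue <- setdiff(nb, i)
    while (length(queue) > 0) {
      q <- queue[[1]]; queue <- queue[-1]
      if (!visited[q]) {
        visited[q] <- TRUE
        nb_q <- which(dm[q, ] <= eps)
        if (length(nb_q) >= min_pts) queue <- c(queue, setdiff(nb_q, q))
      }
      if (labels[q] == 0L) labels[q] <- cl
    }
  }
  # relabel by size rank
  if (cl > 0) {
    sizes <- table(factor(labels[labels > 0], levels = seq_len(cl)))
    rank_map <- order(order(-as.integer(sizes)))
    labels[labels > 0] <- rank_map[labels[labels > 0]]
  }
  pts$cluster <- labels
  cents <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(pts, .data$cluster > 0), .data$cluster),
    lon = mean(.data$lon), lat = mean(.data$lat), size = dplyr::n(),
    .groups = "drop")
  structure(pts, centroids = cents, eps = eps, min_pts = min_pts,
            class = c("sieve_refugia", class(tibble())))
}

#' Linearly interpolate climate between the LGM and the present
#'
#' Per cell and variable, the blend `(1 - t) * LGM + t * present`; `t = 0`
#' reproduces the LGM slice and `t = 1` the present slice. Used to build the
#' century-scale climate series that drives the colonisation simulation.
#'
#' @param landscape A `sieve_landscape`.
#' @param t Interpolation fraction in `[0, 1]`.
#' @return Tibble with `cell` plus the blended environmental variables.
#' @export
interpolate_climate <- function(landscape, t) {
  if (t < 0 || t > 1) abort("t must lie in [0, 1]")
  pres <- env_slice(landscape, "present")
  lgm <- env_slice(landscape, "lgm")
  out <- pres
  for (v in env_vars(landscape)) out[[v]] <- (1 - t) * lgm[[v]] + t * pres[[v]]
  out
}

#' Simulate dispersal-limited colonisation from glacial refugia
#'
#' Forward simulation from the LGM to the present under linearly
#' interpolated climate: at each step every lineage's suitability is
#' projected, cells that became unsuitable for their occupying lineage are
#' vacated, and every suitable unoccupied cell is assigned the lineage of
#' its nearest occupied cell provided that cell lies within `d_km` --
#' with competitive exclusion, so a cell holds at most one lineage and never
#' switches lineage while continuously occupied. Ties in distance go to the
#' lowest lineage index.
#'
#' @param models Named list of `sieve_ensemble` models, one per lineage.
#' @param seeds Named list (same names) of refugial seed cell vectors.
#' @param landscape A `sieve_landscape`.
#' @param n_steps Number of time steps from LGM (`t = 0`) to present
#'   (`t = 1`); the paper-scale analogue is one step per century.
#' @param d_km Dispersal reach per step in km (field default: 12 km per
#'   century).
#' @return A `sieve_colonisation` object: list with `occupancy` (list of
#'   per-step integer vectors; 0 = empty, k = lineage k), `lineages`,
#'   `d_km`, `n_steps`.
#' @export
simulate_colonisation <- function(models, seeds, landscape, n_steps = 20,
                                  d_km = 12) {
  if (d_km <= 0) abort("dispersal distance d_km must be positive")
  lineages <- names(models)
  if (is.null(lineages) || !identical(sort(lineages), sort(names(seeds)))) {
    abort("models and seeds must be named lists over the same lineages")
  }
  if (any(vapply(seeds, length, integer(1)) == 0)) {
    abort("every lineage needs a non-empty refugial seed set")
  }
  n <- nrow(landscape)
  dmat <- gc_dist_km(landscape)
  occ <- rep(0L, n)
  for (k in seq_along(lineages)) occ[seeds[[lineages[k]]]] <- k
  history <- vector("list", n_steps + 1)
  history[[1]] <- occ
  for (step in seq_len(n_steps)) {
    t_frac <- step / n_steps
    env <- interpolate_climate(landscape, t_frac)
    suit <- vapply(lineages, function(ln) {
      project_suitability(models[[ln]], env)$presence
    }, logical(n))
    if (n == 1) suit <- matrix(suit, nrow = 1)
    # local extinction: vacate cells unsuitable for their occupant
    occupied <- which(occ > 0)
    vacate <- occupied[!suit[cbind(occupied, occ[occupied])]]
    occ[vacate] <- 0L
    # colonisation
    sources <- which(occ > 0)
    if (length(sources) > 0) {
      open <- which(occ == 0L & landscape$land & rowSums(suit) > 0)
      new_occ <- occ
      for (cl in open) {
        cand <- sources[suit[cl, occ[sources]]] # sources whose lineage finds cl suitable
        if (length(cand) == 0) next
        dd <- dmat[cl, cand]
        if (min(dd) > d_km) next
        best <- cand[dd == min(dd)]
        new_occ[cl] <- min(occ[best]) # tie-break: lowest lineage index
      }
      occ <- new_occ
    }
    history[[step + 1]] <- occ
  }
  structure(list(occupancy = history, lineages = lineages, d_km = d_km,
                 n_steps = n_steps),
            class = "sieve_colonisation")
}

#' @export
print.sieve_colonisation <- function(x, ...) {
  final <- x$occupancy[[length(x$occupancy)]]
  cat("<colonisation history>", x$n_steps, "steps; final occupancy:",
      paste(x$lineages, tabulate(final, length(x$lineages)), collapse = ", "),
      "cells\n")
  invisible(x)
}

#' Audit a colonisation history's dispersal and exclusivity invariants
#'
#' Checks, exhaustively over every step, that (i) no cell holds more than
#' one lineage (structural under the integer encoding, asserted anyway) and
#' (ii) every newly occupied cell had a same-lineage occupied cell within
#' `d_km` at the previous step.
#'
#' @param history A `sieve_colonisation`.
#' @param landscape The landscape simulated on.
#' @return Tibble of violations (empty when the history is clean).
#' @export
audit_colonisation <- function(history, landscape) {
  dmat <- gc_dist_km(landscape)
  bad <- list()
  for (s in 2:length(history$occupancy)) {
    prev <- history$occupancy[[s - 1]]
    cur <- history$occupancy[[s]]
    new_cells <- which(cur > 0 & prev == 0)
    for (cl in new_cells) {
      same <- which(prev == cur[cl])
      dmin <- if (length(same)) min(dmat[cl, same]) else Inf
      if (dmin > history$d_km + 1e-9) {
        bad[[length(bad) + 1]] <- tibble(step = s - 1, cell = cl,
                                         lineage = cur[cl], nearest_source_km = dmin)
      }
    }
  }
  if (length(bad) == 0) {
    tibble(step = integer(), cell = integer(), lineage = integer(),
           nearest_source_km = numeric())
  } else {
    bind_rows(bad)
  }
}
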