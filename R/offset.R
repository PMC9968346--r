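# Glacial genomic offset and its spatial machinery: resistance surfaces,
# least-cost paths, refugial source assignment, expansion-path divergence,
# Moran's eigenvector maps, and the offset metric itself.

#' Build a resistance surface from a suitability map
#'
#' Conductance equals ensemble suitability; resistance is its reciprocal
#' (`1 / (suitability + eps)`). Land cells form an 8-neighbour lattice graph
#' whose edge costs are the mean resistance of the two end cells times the
#' step length.
#'
#' @param suitability A `sieve_suitability` covering the landscape's cells.
#' @param landscape The `sieve_landscape`.
#' @param eps Floor added to suitability before inversion (default 1e-3).
#' @return A `sieve_resistance` object: `graph` (igraph), `cells` (cell ids
#'   of the vertices), `resistance` (per vertex), `landscape_ref` grid info.
#' @export
resistance_surface <- function(suitability, landscape, eps = 1e-3) {
  land <- dplyr::filter(landscape, .data$land)
  s <- suitability$suitability[match(land$cell, suitability$cell)]
  if (anyNA(s)) abort("suitability must cover every land cell")
  res <- 1 / (s + eps)
  g <- attr(landscape, "grid")
  csize <- attr(landscape, "cell_size_km")
  vid <- setNames(seq_len(nrow(land)), land$cell)
  edges <- list(); wts <- list(); k <- 0
  offs <- rbind(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  key <- (land$row - 1) * g[["cols"]] + land$col
  lookup <- setNames(seq_len(nrow(land)), key)
  for (o in seq_len(nrow(offs))) {
    nb_key <- (land$row - 1 + offs[o, 1]) * g[["cols"]] + (land$col + offs[o, 2])
    valid <- land$col + offs[o, 2] >= 1 & land$col + offs[o, 2] <= g[["cols"]] &
      land$row + offs[o, 1] <= g[["rows"]] & land$row + offs[o, 1] >= 1
    j <- lookup[as.character(nb_key)]
    ok <- valid & !is.na(j)
    if (!any(ok)) next
    step <- csize * sqrt(sum(offs[o, ]^2))
    k <- k + 1
    edges[[k]] <- cbind(which(ok), j[ok])
    wts[[k]] <- (res[which(ok)] + res[j[ok]]) / 2 * step
  }
  em <- do.call(rbind, edges)
  graph <- igraph::graph_from_edgelist(em, directed = FALSE)
  igraph::E(graph)$weight <- unlist(wts)
  if (igraph::vcount(graph) < nrow(land)) {
    graph <- igraph::add_vertices(graph, nrow(land) - igraph::vcount(graph))
  }
  comp <- igraph::components(graph)
  if (comp$no > 1) {
    warn(paste("resistance graph has", comp$no, "connected components"))
  }
  structure(list(graph = graph, cells = land$cell, resistance = res,
                 grid = g, cell_size_km = csize),
            class = "sieve_resistance")
}

res_vertex <- function(resistance, cells) {
  v <- match(cells, resistance$cells)
  if (anyNA(v)) abort("cell(s) not on the resistance surface (water?)")
  v
}

#' Least-cost paths over a resistance surface
#'
#' Dijkstra shortest paths on the 8-neighbour lattice; edge cost is mean
#' end-cell resistance times step length.
#'
#' @param resistance A `sieve_resistance`.
#' @param source_cell Source cell id.
#' @param targets Vector of target cell ids.
#' @return Tibble: `target`, `cost`, `path` (list column of cell-id
#'   vectors); unreachable targets get `cost = Inf` and an empty path.
#' @export
least_cost_paths <- function(resistance, source_cell, targets) {
  sv <- res_vertex(resistance, source_cell)
  tv <- res_vertex(resistance, targets)
  sp <- igraph::shortest_paths(resistance$graph, from = sv, to = tv,
                               weights = igraph::E(resistance$graph)$weight,
                               output = "vpath")
  cost <- as.numeric(igraph::distances(resistance$graph, v = sv, to = tv,
                                       weights = igraph::E(resistance$graph)$weight))
  tibble(target = targets, cost = cost,
         path = lapply(sp$vpath, function(v) resistance$cells[as.integer(v)]))
}

#' Assign each population to its closest refugial source
#'
#' Geographic mode picks the nearest refugial cell by great-circle
#' distance; path mode by least-cost distance over the resistance surface
#' (falling back to geographic, with a warning, for unreachable
#' populations). Ties go to the larger refugial cluster, then to a seeded
#' random draw.
#'
#' @param pop_table Tibble with `id`, `cell`, `lon`, `lat`.
#' @param refugia A `sieve_refugia` (noise cells are ignored).
#' @param landscape The landscape (for refugial coordinates).
#' @param mode `"geographic"` (default) or `"path"`.
#' @param resistance A `sieve_resistance`, required for path mode.
#' @param seed Seed for tie-breaking.
#' @return A `sieve_assignment` tibble: `id`, `source_cluster`,
#'   `source_cell`, `distance_km` (geographic) or `cost` (path), `mode`.
#' @export
assign_refugial_source <- function(pop_table, refugia, landscape,
                                   mode = c("geographic", "path"),
                                   resistance = NULL, seed = 1) {
  mode <- match.arg(mode)
  ref <- dplyr::filter(as_tibble(refugia), .data$cluster > 0)
  if (nrow(ref) == 0) abort("refugia map contains no clustered cells")
  sizes <- table(ref$cluster)
  set.seed(seed)
  pick <- function(d) {
    # d: distances to each refugial cell; smaller wins, ties to larger cluster
    cand <- which(d <= min(d) + 1e-9)
    if (length(cand) > 1) {
      sz <- as.integer(sizes[as.character(ref$cluster[cand])])
      cand <- cand[sz == max(sz)]
      if (length(cand) > 1) cand <- sample(cand, 1)
    }
    cand[[1]]
  }
  if (mode == "geographic") {
    d <- gc_dist_km(pop_table, ref)
    rows <- apply(d, 1, pick)
    out <- tibble(id = pop_table$id,
                  source_cluster = ref$cluster[rows],
                  source_cell = ref$cell[rows],
                  distance_km = d[cbind(seq_len(nrow(d)), rows)],
                  mode = mode)
  } else {
    if (is.null(resistance)) abort("path mode needs a resistance surface")
    pv <- res_vertex(resistance, pop_table$cell)
    rv <- res_vertex(resistance, ref$cell)
    dc <- igraph::distances(resistance$graph, v = pv, to = rv,
                            weights = igraph::E(resistance$graph)$weight)
    dgeo <- gc_dist_km(pop_table, ref)
    rows <- integer(nrow(pop_table))
    used_geo <- logical(nrow(pop_table))
    for (i in seq_len(nrow(pop_table))) {
      if (all(!is.finite(dc[i, ]))) {
        used_geo[i] <- TRUE
        rows[i] <- pick(dgeo[i, ])
      } else {
        rows[i] <- pick(dc[i, ])
      }
    }
    if (any(used_geo)) {
      warn(paste("population(s) unreachable over the resistance surface,",
                 "assigned geographically:",
                 paste(pop_table$id[used_geo], collapse = ", ")))
    }
    out <- tibble(id = pop_table$id,
                  source_cluster = ref$cluster[rows],
                  source_cell = ref$cell[rows],
                  cost = dc[cbind(seq_len(nrow(dc)), rows)],
                  distance_km = dgeo[cbind(seq_len(nrow(dgeo)), rows)],
                  mode = ifelse(used_geo, "geographic-fallback", mode))
  }
  structure(out, class = c("sieve_assignment", class(tibble())))
}

#' Divergence of two expansion paths
#'
#' `1 - |A intersect B| / min(|A|, |B|)` on the path cell sets: 0 for
#' identical or nested paths, 1 for disjoint paths.
#'
#' @param path_a,path_b Vectors of path cell ids.
#' @export
path_divergence <- function(path_a, path_b) {
  if (length(path_a) == 0 || length(path_b) == 0) abort("empty path")
  a <- unique(path_a); b <- unique(path_b)
  1 - length(intersect(a, b)) / min(length(a), length(b))
}

#' Pairwise expansion-path divergence between populations
#'
#' Least-cost paths from each population's refugial source to the
#' population define its expansion route; entry (i, j) is the
#' [path_divergence()] of the two routes.
#'
#' @param assignment A `sieve_assignment`.
#' @param pop_table Tibble with `id`, `cell` aligned with the assignment.
#' @param resistance A `sieve_resistance`.
#' @return Symmetric matrix of divergences in `[0, 1]`.
#' @export
expansion_path_divergence <- function(assignment, pop_table, resistance) {
  paths <- vector("list", nrow(pop_table))
  for (i in seq_len(nrow(pop_table))) {
    lp <- least_cost_paths(resistance, assignment$source_cell[i],
                           pop_table$cell[i])
    paths[[i]] <- lp$path[[1]]
  }
  k <- nrow(pop_table)
  D <- matrix(0, k, k, dimnames = list(pop_table$id, pop_table$id))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      D[i, j] <- D[j, i] <- path_divergence(paths[[i]], paths[[j]])
    }
  }
  D
}

#' Moran's eigenvector map over an expansion-weighted neighbour graph
#'
#' Populations are neighbours when their great-circle distance does not
#' exceed the longest edge of the minimum spanning tree (which keeps the
#' graph connected). The spatial weighting matrix carries the supplied edge
#' weights (e.g. expansion-path divergence) on neighbour pairs; its doubly
#' centred form is eigen-decomposed and the eigenvectors with positive
#' eigenvalues retained, MEM1 being the leading one.
#'
#' @param pop_table Tibble with `id`, `lon`, `lat`.
#' @param edge_weights Optional symmetric matrix of edge weights (default
#'   all ones).
#' @return A `sieve_mem` object: `values`, `vectors` (populations x
#'   retained), `mem1` tibble (`id`, `MEM1`), `neighbours` adjacency,
#'   `threshold_km`.
#' @export
build_mem <- function(pop_table, edge_weights = NULL) {
  k <- nrow(pop_table)
  if (k < 4) abort("need at least 4 populations")
  d <- gc_dist_km(pop_table)
  g_full <- igraph::graph_from_adjacency_matrix(d, weighted = TRUE,
                                                mode = "undirected")
  mst <- igraph::mst(g_full, weights = igraph::E(g_full)$weight)
  thr <- max(igraph::E(mst)$weight)
  nb <- d <= thr + 1e-9
  diag(nb) <- FALSE
  if (igraph::components(igraph::graph_from_adjacency_matrix(nb, mode = "undirected"))$no != 1) {
    abort("neighbour graph disconnected despite MST rule; should not happen")
  }
  W <- matrix(0, k, k)
  if (is.null(edge_weights)) edge_weights <- matrix(1, k, k)
  W[nb] <- edge_weights[nb]
  W <- (W + t(W)) / 2
  H <- diag(k) - matrix(1 / k, k, k)
  B <- H %*% W %*% H
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  pos <- eig$values > 1e-9
  if (!any(pos)) abort("no positive eigenvalue: degenerate weighting matrix")
  vec <- eig$vectors[, pos, drop = FALSE]
  colnames(vec) <- paste0("MEM", seq_len(ncol(vec)))
  structure(list(values = eig$values[pos], vectors = vec,
                 mem1 = tibble(id = pop_table$id, MEM1 = vec[, 1]),
                 neighbours = nb, threshold_km = thr,
                 pop_table = pop_table),
            class = "sieve_mem")
}

#' @export
print.sieve_mem <- function(x, ...) {
  cat("<MEM basis>", ncol(x$vectors), "positive eigenvectors; MEM1 explains",
      signif(x$values[1] / sum(x$values) * 100, 3), "% of positive variance\n")
  invisible(x)
}

#' Interpolate MEM1 across a landscape by inverse path-distance weighting
#'
#' Each land cell receives the inverse-path-distance-weighted mean of the
#' population MEM1 scores, with path distances measured as least-cost path
#' costs over the resistance surface; a cell coinciding with a population
#' takes that population's score exactly.
#'
#' @param mem A `sieve_mem`.
#' @param resistance A `sieve_resistance`.
#' @param pop_table Tibble with `id`, `cell` for the MEM populations.
#' @param power IDW exponent (default 2).
#' @return Tibble: `cell`, `MEM1` (`NA` for cells unreachable from every
#'   population).
#' @export
interpolate_mem <- function(mem, resistance, pop_table, power = 2) {
  pv <- res_vertex(resistance, pop_table$cell)
  dc <- igraph::distances(resistance$graph, v = pv,
                          weights = igraph::E(resistance$graph)$weight)
  vals <- mem$mem1$MEM1[match(pop_table$id, mem$mem1$id)]
  out <- numeric(ncol(dc))
  for (cc in seq_len(ncol(dc))) {
    d <- dc[, cc]
    if (any(d < 1e-9)) { out[cc] <- vals[which.min(d)]; next }
    fin <- is.finite(d)
    if (!any(fin)) { out[cc] <- NA_real_; next }
    w <- 1 / d[fin]^power
    out[cc] <- sum(w * vals[fin]) / sum(w)
  }
  tibble(cell = resistance$cells, MEM1 = out)
}

#' Glacial genomic offset
#'
#' The Euclidean distance, in gene-environment (turnover-transformed)
#' space, between each present-day population and its refugial source at
#' the LGM. Spatial co-variates (transformed longitude/latitude or MEM1)
#' are retained by default so the metric captures isolation by distance and
#' expansion-associated drift alongside the adaptive response to the
#' environmental shift.
#'
#' @param model A `sieve_turnover`.
#' @param present_env Tibble: `id` plus the model predictors evaluated at
#'   each population's present location and climate.
#' @param lgm_env Tibble: `id` plus the model predictors evaluated at the
#'   assigned refugial source's location under LGM climate. Populations
#'   missing here are flagged, not dropped.
#' @param include_spatial Keep the transformed spatial co-variates in the
#'   distance (default `TRUE`).
#' @return A `sieve_offset` tibble: `id`, `offset`, `flagged`, and one
#'   `comp_<predictor>` column per retained predictor (signed transformed
#'   difference, present minus LGM).
#' @export
glacial_genomic_offset <- function(model, present_env, lgm_env,
                                   include_spatial = TRUE) {
  f_now <- transform_environment(model, present_env)
  vars <- model$predictors
  if (!include_spatial) vars <- setdiff(vars, model$spatial_vars)
  m <- match(present_env$id, lgm_env$id)
  flagged <- is.na(m)
  f_then <- transform_environment(model, lgm_env)
  comp <- matrix(NA_real_, nrow(present_env), length(vars),
                 dimnames = list(NULL, vars))
  okr <- which(!flagged)
  for (v in vars) comp[okr, v] <- f_now[[v]][okr] - f_then[[v]][m[okr]]
  out <- tibble(id = present_env$id,
                offset = sqrt(rowSums(comp^2)),
                flagged = flagged)
  for (v in vars) out[[paste0("comp_", v)]] <- comp[, v]
  if (any(flagged)) {
    warn(paste("missing refugial endpoint for:",
               paste(present_env$id[flagged], collapse = ", ")))
  }
  structure(out, include_spatial = include_spatial,
            class = c("sieve_offset", class(tibble())))
}
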