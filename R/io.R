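# Readers, writers, the VCF-derived frequency table with the per-population
# depth filter and MAF filter, and the one-config end-to-end pipeline.

#' Write / read a landscape variable as an ESRI ASCII grid
#'
#' @param values Per-cell values aligned with `landscape$cell` (NA over
#'   water is written as the nodata value).
#' @param landscape A `sieve_landscape` (defines grid shape and georeference).
#' @param path Output file.
#' @param nodata Nodata sentinel (default -9999).
#' @export
write_esri_ascii <- function(values, landscape, path, nodata = -9999) {
  g <- attr(landscape, "grid")
  m <- matrix(nodata, g[["rows"]], g[["cols"]])
  v <- ifelse(is.na(values), nodata, values)
  m[cbind(landscape$row, landscape$col)] <- v
  cellsize <- attr(landscape, "cell_size_km") / 111.32
  hdr <- c(
    paste("ncols", g[["cols"]]),
    paste("nrows", g[["rows"]]),
    paste("xllcorner", format(min(landscape$lon), digits = 15)),
    paste("yllcorner", format(min(landscape$lat) - cellsize, digits = 15)),
    paste("cellsize", format(cellsize, digits = 15)),
    paste("NODATA_value", nodata))
  body <- apply(m, 1, function(r) paste(format(r, digits = 15, trim = TRUE),
                                        collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_esri_ascii
#' @return `read_esri_ascii` returns a list: `values` (matrix, NA at
#'   nodata), `xllcorner`, `yllcorner`, `cellsize`, `nodata`.
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  keys <- vapply(hdr, `[[`, "", 1)
  vals <- as.numeric(vapply(hdr, `[[`, "", 2))
  names(vals) <- tolower(keys)
  m <- do.call(rbind, lapply(lines[-(1:6)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  m[m == vals[["nodata_value"]]] <- NA
  list(values = m, xllcorner = vals[["xllcorner"]],
       yllcorner = vals[["yllcorner"]], cellsize = vals[["cellsize"]],
       nodata = vals[["nodata_value"]])
}

#' Write / read a populations-by-loci frequency matrix as TSV
#'
#' First column `id` holds population ids; remaining columns are loci.
#' @param freqs Matrix with row and column names.
#' @param path File path.
#' @export
write_freqs_tsv <- function(freqs, path) {
  df <- bind_cols(tibble(id = rownames(freqs)), as_tibble(freqs))
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_freqs_tsv
#' @export
read_freqs_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[-1])
  rownames(m) <- df$id
  m
}

#' Write haplotypes as FASTA-like 0/1 text, one file per population
#'
#' Each haplotype is a `>pop_hap<k>` header followed by a 0/1 string.
#' @param genotypes A `sieve_genotypes`.
#' @param dir Output directory (created if needed).
#' @export
write_haplotypes <- function(genotypes, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (pid in names(genotypes$haplotypes)) {
    h <- genotypes$haplotypes[[pid]]
    lines <- character(2 * nrow(h))
    for (i in seq_len(nrow(h))) {
      lines[2 * i - 1] <- paste0(">", pid, "_hap", i)
      lines[2 * i] <- paste(h[i, ], collapse = "")
    }
    writeLines(lines, file.path(dir, paste0(pid, ".hap.txt")))
  }
  invisible(dir)
}

#' @rdname write_haplotypes
#' @param path A single population's `.hap.txt` file.
#' @export
read_haplotypes <- function(path) {
  lines <- readLines(path)
  seqs <- lines[seq(2, length(lines), by = 2)]
  do.call(rbind, lapply(seqs, function(s)
    as.integer(strsplit(s, "")[[1]])))
}

#' Population allele frequencies from a VCF
#'
#' Builds a populations-by-sites derived-allele frequency table from hard
#' genotypes of a biallelic VCF (the ALT allele is taken as derived; supply
#' a pre-polarised VCF). Sites are dropped when any population's summed
#' sample depth falls below `min_depth`; multi-allelic sites are skipped.
#'
#' @param vcf_path Path to a VCF (plain or gzipped).
#' @param pop_assignments Tibble/data frame with columns `sample`, `pop`.
#' @param min_depth Minimum summed depth per population (default 7).
#' @return List: `freqs` (pops x sites matrix), `meta` (site tibble:
#'   `contig`, `pos`, `ref`, `alt`), `depth` (pops x sites), `dropped`
#'   (counts by reason).
#' @export
read_vcf_frequencies <- function(vcf_path, pop_assignments, min_depth = 7) {
  if (!requireNamespace("vcfR", quietly = TRUE)) abort("vcfR is required")
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  samples <- colnames(v@gt)[-1]
  missing <- setdiff(pop_assignments$sample, samples)
  if (length(missing) > 0) {
    abort(paste("sample(s) in the population map absent from the VCF:",
                paste(missing, collapse = ", ")))
  }
  multi <- grepl(",", fix[, "ALT"]) | is.na(fix[, "ALT"])
  n_multi <- sum(multi)
  if (n_multi > 0) message(n_multi, " multi-allelic site(s) skipped")
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  if (all(is.na(dp))) dp <- matrix(Inf, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  keep_sites <- which(!multi)
  pops <- unique(pop_assignments$pop)
  freqs <- matrix(NA_real_, length(pops), length(keep_sites),
                  dimnames = list(pops, NULL))
  depth <- matrix(0, length(pops), length(keep_sites), dimnames = list(pops, NULL))
  alt_count <- function(g) {
    if (is.na(g)) return(c(0L, 0L))
    al <- strsplit(g, "[/|]")[[1]]
    al <- al[al != "."]
    c(sum(al == "1"), length(al))
  }
  for (p in seq_along(pops)) {
    smp <- pop_assignments$sample[pop_assignments$pop == pops[p]]
    for (k in seq_along(keep_sites)) {
      s <- keep_sites[k]
      counts <- rowSums(vapply(smp, function(sm) alt_count(gt[s, sm]),
                               numeric(2)))
      freqs[p, k] <- if (counts[2] > 0) counts[1] / counts[2] else NA_real_
      depth[p, k] <- sum(dp[s, smp], na.rm = TRUE)
    }
  }
  ok_depth <- apply(depth, 2, function(cc) all(cc >= min_depth))
  n_shallow <- sum(!ok_depth)
  if (n_shallow > 0) {
    message(n_shallow, " site(s) dropped by the depth >= ", min_depth,
            " per-population rule")
  }
  freqs <- freqs[, ok_depth, drop = FALSE]
  depth <- depth[, ok_depth, drop = FALSE]
  meta <- tibble(contig = fix[keep_sites[ok_depth], "CHROM"],
                 pos = as.integer(fix[keep_sites[ok_depth], "POS"]),
                 ref = fix[keep_sites[ok_depth], "REF"],
                 alt = fix[keep_sites[ok_depth], "ALT"])
  colnames(freqs) <- paste0(meta$contig, ":", meta$pos)
  list(freqs = freqs, meta = meta, depth = depth,
       dropped = c(multiallelic = n_multi, shallow = n_shallow))
}

#' Filter loci by pooled minor allele frequency
#'
#' Removes loci whose pooled (across-population mean) minor-allele frequency
#' is below `threshold`.
#'
#' @param freqs Populations x loci frequency matrix.
#' @param threshold MAF threshold in `[0, 0.5)` (field default 0.05).
#' @export
maf_filter <- function(freqs, threshold = 0.05) {
  if (threshold < 0 || threshold >= 0.5) abort("threshold must lie in [0, 0.5)")
  p <- colMeans(freqs)
  maf <- pmin(p, 1 - p)
  freqs[, maf >= threshold, drop = FALSE]
}

#' Default configuration of the synthetic end-to-end pipeline
#'
#' Every parameter of [run_pipeline()], with the generator defaults
#' representing the study conditions the synthetic landscape emulates.
#' @export
default_config <- function() {
  list(
    seed = 1,
    landscape = list(n_rows = 24, n_cols = 32, n_env = 3,
                     warming_amplitude = 3, cell_size_km = 10),
    niche = list(q_low = 0.2, q_high = 1),
    expansion = list(d_per_step_km = 25, n_steps = 1000),
    genotypes = list(n_pops = 30, n_haplotypes = 20, l_neutral = 1800,
                     l_adaptive = 200, beta = 5, drift_scale = 0.005),
    psi = list(n_perm = 999),
    tdoa = list(resolution = 20),
    sdm = list(n_occurrences = 120, background_ratio = 5, k_folds = 5),
    colonise = list(n_steps = 8, d_km = 30),
    gf = list(n_trees = 100, n_bins = 200, mtry = NULL),
    validate = list(low_max = 1000, high_min = 1500)
  )
}

read_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(paste("config file not found:", config))
    config <- yaml::read_yaml(config)
  }
  utils::modifyList(default_config(), config)
}

# the refugial origin of the synthetic expansion: an eastern land cell near
# the grid's vertical midline
auto_origin <- function(landscape) {
  land_cells <- landscape[landscape$land, ]
  east <- land_cells[land_cells$col >= quantile(land_cells$col, 0.8), ]
  g <- attr(landscape, "grid")
  east$cell[which.min(abs(east$row - g[["rows"]] / 2))]
}

#' Run the full synthetic pipeline from one configuration
#'
#' Generates a landscape and expansion with known truth, simulates sieved
#' allele frequencies, infers the expansion signal (psi, Mantel, TDOA,
#' founder strength), fits the ensemble niche model and hindcasts refugia,
#' simulates colonisation, fits the gene-environment turnover model,
#' computes the glacial genomic offset against the assigned refugial
#' sources, and validates it against genome-wide and weighted SFS
#' statistics. All randomness derives from `config$seed`; outputs written
#' under `out_dir` are byte-reproducible.
#'
#' @param config A config list (see [default_config()]) or the path of a
#'   YAML file with the same structure; omitted entries take defaults.
#' @param out_dir Optional output directory for TSV/JSON/ASCII-grid
#'   artefacts and a run log.
#' @return Invisibly, a list with every intermediate object.
#' @examples
#' \donttest{
#' demo <- system.file("extdata", "demo_config.yaml", package = "sievescape")
#' res <- run_pipeline(demo)
#' glance(res$origin_surface)
#' }
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  cfg <- read_config(config)
  seed <- cfg$seed

  landscape <- do.call(generate_landscape, c(cfg$landscape, list(seed = seed)))
  # the species tolerates a temperature band; its glacial refugium is the
  # area that stayed within the band under the colder LGM climate
  tband <- quantile(landscape$temp[landscape$land],
                    c(cfg$niche$q_low, cfg$niche$q_high))
  suitable <- landscape$land & landscape$temp >= tband[1] &
    landscape$temp <= tband[2]
  lgm_ok <- suitable & landscape$temp_lgm >= tband[1] &
    landscape$temp_lgm <= tband[2]
  origin <- cfg$expansion$origin %||% {
    # restrict to the largest habitat patch connected at the dispersal
    # reach, so the refugium is not an isolated pocket
    suit_cells <- which(suitable)
    dsub <- gc_dist_km(landscape[suit_cells, ])
    g <- igraph::graph_from_adjacency_matrix(
      dsub <= cfg$expansion$d_per_step_km, mode = "undirected")
    comp <- igraph::components(g)
    main_patch <- suit_cells[comp$membership == which.max(comp$csize)]
    pool <- intersect(main_patch, which(lgm_ok))
    if (length(pool) == 0) pool <- main_patch
    pool[which.max(landscape$temp_lgm[pool])]
  }
  truth <- simulate_expansion(landscape, origin, suitable = suitable,
                              d_per_step_km = cfg$expansion$d_per_step_km,
                              n_steps = cfg$expansion$n_steps)
  gen <- do.call(simulate_allele_frequencies,
                 c(list(truth = truth, landscape = landscape),
                   cfg$genotypes, list(seed = seed + 1)))

  psi <- pairwise_psi(gen$haplotypes, gen$pop_table)
  mantel <- mantel_psi(psi, n_perm = cfg$psi$n_perm, seed = seed + 2)
  cand <- candidate_grid(landscape, cfg$tdoa$resolution)
  origin_surface <- tdoa_origin(psi, cand)
  best <- glance(origin_surface)
  founder <- founder_strength(psi, c(best$lon, best$lat))

  # occurrences: colonised cells stand in for present-day records
  set.seed(seed + 3)
  founded <- dplyr::filter(landscape, .data$cell %in% truth$cell[truth$founded])
  occ_rows <- founded[sample(nrow(founded),
                             min(cfg$sdm$n_occurrences, nrow(founded))), ]
  occ <- occ_rows[c("lon", "lat")]
  # collinearity screen (VIF < 10, |r| < 0.7) on presence/background points
  land_tbl <- landscape[landscape$land, ]
  bg <- land_tbl[sample(nrow(land_tbl), min(nrow(land_tbl), 5 * nrow(occ))), ]
  sel_cells <- c(occ_rows$cell, bg$cell)
  sel_env <- env_slice(landscape, "present")[
    match(sel_cells, landscape$cell), env_vars(landscape)]
  sel_resp <- rep(c(1L, 0L), c(nrow(occ_rows), nrow(bg)))
  vars_sel <- if (length(env_vars(landscape)) >= 3) {
    select_variables(sel_env, sel_resp, seed = seed + 9)
  } else env_vars(landscape)
  ens <- fit_ensemble(occ, landscape, vars = vars_sel,
                      background_ratio = cfg$sdm$background_ratio,
                      k_folds = cfg$sdm$k_folds, seed = seed + 4)
  land_cells <- dplyr::filter(landscape, .data$land)$cell
  env_now <- dplyr::filter(env_slice(landscape, "present"), .data$cell %in% land_cells)
  env_lgm <- dplyr::filter(env_slice(landscape, "lgm"), .data$cell %in% land_cells)
  suit_now <- project_suitability(ens, env_now)
  suit_lgm <- project_suitability(ens, env_lgm)
  if (!any(suit_lgm$presence)) {
    # binarisation predicts absence everywhere at the LGM: delineate refugia
    # on relative suitability instead (top 5% of cells)
    suit_lgm$presence <- suit_lgm$suitability >=
      quantile(suit_lgm$suitability, 0.95)
  }
  refugia <- cluster_refugia(suit_lgm, landscape)
  if (all(refugia$cluster == 0)) refugia$cluster <- 1L # sparse: one refugium
  resistance <- resistance_surface(suit_now, landscape)
  seed_cells <- refugia$cell[refugia$cluster == 1]
  if (length(seed_cells) == 0) seed_cells <- refugia$cell # all noise: seed all
  colonisation <- simulate_colonisation(
    list(L1 = ens), list(L1 = seed_cells),
    landscape, n_steps = cfg$colonise$n_steps, d_km = cfg$colonise$d_km)
  assignment <- assign_refugial_source(gen$pop_table, refugia, landscape,
                                       seed = seed + 5)

  # gene-environment turnover on the screened variables with lon/lat
  # spatial co-variates
  vars <- vars_sel
  idx <- match(gen$pop_table$cell, landscape$cell)
  predictors <- bind_cols(
    env_slice(landscape, "present")[idx, vars],
    gen$pop_table[c("lon", "lat")])
  gf <- fit_snp_forests(gen$est_freqs, predictors, n_trees = cfg$gf$n_trees,
                        mtry = cfg$gf$mtry, n_bins = cfg$gf$n_bins,
                        seed = seed + 6)
  turnover <- build_turnover(gf)

  src_idx <- match(assignment$source_cell, landscape$cell)
  present_env <- bind_cols(tibble(id = gen$pop_table$id),
                           predictors)
  lgm_env <- bind_cols(tibble(id = gen$pop_table$id),
                       env_slice(landscape, "lgm")[src_idx, vars],
                       tibble(lon = landscape$lon[src_idx],
                              lat = landscape$lat[src_idx]))
  offsets <- glacial_genomic_offset(turnover, present_env, lgm_env)

  w_r2 <- ifelse(is.finite(gf$r2), pmax(gf$r2, 0), 0)
  stats <- population_genetics_stats(gen, weights = w_r2)
  validation <- correlate_offset(offsets, stats)
  elev <- tryCatch(
    elevation_contrast(gen$pop_table, stats, low_max = cfg$validate$low_max,
                       high_min = cfg$validate$high_min),
    error = function(e) NULL)

  result <- list(config = cfg, landscape = landscape, truth = truth,
                 genotypes = gen, psi = psi, mantel = mantel,
                 origin_surface = origin_surface, founder = founder,
                 ensemble = ens, suitability_present = suit_now,
                 suitability_lgm = suit_lgm, refugia = refugia,
                 resistance = resistance, colonisation = colonisation,
                 assignment = assignment, gf = gf, turnover = turnover,
                 offsets = offsets, stats = stats, validation = validation,
                 elevation = elev)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_pipeline_outputs <- function(result, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  readr::write_tsv(result$genotypes$pop_table, p("pop_table.tsv"))
  write_freqs_tsv(result$genotypes$freqs, p("freqs.tsv"))
  readr::write_tsv(tidy(result$psi), p("psi.tsv"))
  readr::write_tsv(result$mantel, p("mantel.tsv"))
  readr::write_tsv(as_tibble(result$origin_surface), p("origin_surface.tsv"))
  jsonlite::write_json(as.list(glance(result$origin_surface)),
                       p("origin_summary.json"), auto_unbox = TRUE, digits = NA)
  readr::write_tsv(result$founder, p("founder.tsv"))
  ls <- result$landscape
  sv <- rep(NA_real_, nrow(ls))
  sv[match(result$suitability_present$cell, ls$cell)] <-
    result$suitability_present$suitability
  write_esri_ascii(sv, ls, p("suitability_present.asc"))
  sv[match(result$suitability_lgm$cell, ls$cell)] <-
    result$suitability_lgm$suitability
  write_esri_ascii(sv, ls, p("suitability_lgm.asc"))
  readr::write_tsv(as_tibble(result$refugia), p("refugia.tsv"))
  readr::write_tsv(as_tibble(result$assignment), p("assignment.tsv"))
  readr::write_tsv(as_tibble(result$offsets), p("offset.tsv"))
  readr::write_tsv(result$stats, p("population_stats.tsv"))
  readr::write_tsv(as_tibble(result$validation), p("validation.tsv"))
  if (!is.null(result$elevation)) {
    readr::write_tsv(result$elevation$tests, p("elevation_tests.tsv"))
  }
  yaml::write_yaml(result$config, p("config_echo.yaml"))
  log_lines <- c(
    paste("sievescape", as.character(utils::packageVersion("sievescape"))),
    paste("R", paste(R.version$major, R.version$minor, sep = ".")),
    paste("seed", result$config$seed),
    paste("populations", nrow(result$genotypes$pop_table)),
    paste("loci", ncol(result$genotypes$freqs)),
    paste("active_snps", sum(result$gf$active)))
  writeLines(log_lines, p("run_log.txt"))
  invisible(out_dir)
}
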