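#' Run manifest for a pipeline invocation
#'
#' Records the configuration snapshot, input file hashes, seeds and
#' thresholds, the package version, and per-stage timings, so a run can be
#' reproduced bit for bit.
#'
#' @param config the (validated) configuration list.
#' @param inputs character vector of input file paths (hashed when present).
#' @return a list of class `run_manifest`; update it with
#'   `manifest_stage()` and write it with [write_manifest()].
#' @export
run_manifest <- function(config, inputs = character(0)) {
  hashes <- vapply(inputs, function(f)
    if (file.exists(f)) unname(tools::md5sum(f)) else NA_character_,
    character(1))
  structure(list(config = config,
                 inputs = as.list(hashes),
                 version = as.character(utils::packageVersion("vasctda")),
                 started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                 stages = list()), class = "run_manifest")
}

manifest_stage <- function(manifest, name, seconds) {
  manifest$stages[[name]] <- round(seconds, 3)
  manifest
}

#' @param manifest a `run_manifest`.
#' @param path output JSON file.
#' @rdname run_manifest
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

.check_config <- function(config, allowed, required) {
  unknown <- setdiff(names(config), allowed)
  if (length(unknown))
    stop_bad("unknown config key(s): ", paste(unknown, collapse = ", "))
  missing <- setdiff(required, names(config))
  if (length(missing))
    stop_bad("missing config key(s): ", paste(missing, collapse = ", "))
  config
}

#' Topological analysis pipeline: clouds to diagrams, distances and MDS
#'
#' For each input point cloud (CSV path or in-memory [point_cloud()]):
#' subsample, compute Vietoris-Rips persistence, then the pairwise Sliced
#' Wasserstein distance matrix over the configured dimensions and a 2D
#' classical MDS embedding.
#'
#' Config keys: `inputs` (named list of CSV paths or point clouds,
#' required), `max_dim` (default 2), `max_radius` (default `NULL` =
#' per-cloud half bounding-box diagonal), `subsample` (default 1500),
#' `seed` (default 0), `n_slices`, `sigma`, `dims_used` (defaults from
#' [sw_config()]), `out_dir` (optional: write diagrams, matrix, coordinates
#' and the manifest as CSV/JSON).
#'
#' @param config a named list; unknown keys are rejected.
#' @return a list with `diagrams`, `distance_matrix`, `mds` and `manifest`.
#' @export
run_tda_pipeline <- function(config) {
  config <- .check_config(config,
                          allowed = c("inputs", "max_dim", "max_radius",
                                      "subsample", "seed", "n_slices",
                                      "sigma", "dims_used", "out_dir"),
                          required = "inputs")
  defaults <- list(max_dim = 2, max_radius = NULL, subsample = 1500,
                   seed = 0L, n_slices = 50L, sigma = 1,
                   dims_used = c(1, 2), out_dir = NULL)
  for (k in names(defaults))
    if (is.null(config[[k]])) config[k] <- list(defaults[[k]])
  paths <- vapply(config$inputs,
                  function(x) if (is.character(x)) x else NA_character_,
                  character(1))
  manifest <- run_manifest(config[setdiff(names(config), "inputs")],
                           inputs = paths[!is.na(paths)])

  load_cloud <- function(x, label) {
    if (inherits(x, "point_cloud")) return(x)
    tryCatch(read_point_cloud(x),
             error = function(e) stop_bad("stage load [", label, "]: ",
                                          conditionMessage(e)))
  }
  labels <- names(config$inputs)
  if (is.null(labels)) labels <- paste0("sample", seq_along(config$inputs))

  t0 <- proc.time()[3]
  diagrams <- lapply(seq_along(config$inputs), function(i) {
    cl <- load_cloud(config$inputs[[i]], labels[i])
    tryCatch(rips_persistence(cl, max_dim = config$max_dim,
                              max_radius = config$max_radius,
                              n_max = config$subsample, seed = config$seed),
             error = function(e) stop_bad("stage persistence [", labels[i],
                                          "]: ", conditionMessage(e)))
  })
  names(diagrams) <- labels
  manifest <- manifest_stage(manifest, "persistence", proc.time()[3] - t0)

  cfg <- sw_config(n_slices = config$n_slices, sigma = config$sigma,
                   dims_used = config$dims_used)
  t0 <- proc.time()[3]
  dm <- pairwise_distance_matrix(diagrams, cfg)
  manifest <- manifest_stage(manifest, "sw_distances", proc.time()[3] - t0)

  t0 <- proc.time()[3]
  emb <- mds_embed(dm, out_dim = min(2L, length(diagrams) - 1L))
  manifest <- manifest_stage(manifest, "mds", proc.time()[3] - t0)
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(diagrams))
      write_diagram(diagrams[[i]],
                    file.path(config$out_dir, paste0("pd_", labels[i], ".csv")))
    utils::write.csv(dm, file.path(config$out_dir, "distance_matrix.csv"))
    utils::write.csv(emb$coords, file.path(config$out_dir, "mds_coords.csv"))
    write_manifest(manifest, file.path(config$out_dir, "manifest.json"))
  }
  list(diagrams = diagrams, distance_matrix = dm, mds = emb,
       manifest = manifest)
}

#' NHPP comparison pipeline: block fits, fold changes, regional Fisher tests
#'
#' Fits the NHPP block-wise for two channels, flags blocks whose strength
#' `a` or directionality `1/b_i` increased by at least the fold threshold in
#' channel A relative to channel B, and tests each region for concentration
#' of changed blocks with Fisher's exact test (two-sided), one row per
#' region per parameter.  P-values are reported raw per area; optional
#' Benjamini-Hochberg adjustment adds a `p_adjusted` column.
#'
#' Config keys: `cloud_a`, `cloud_b` (CSV paths or [point_cloud()]s with
#' region labels attached, required), `box` (optional [domain_box()]),
#' `block_edge` (default 500 um), `min_points` (default 50), `fold`
#' (default 2), `params` (default all four), `two_sided_fold` (default
#' FALSE), `adjust` (default FALSE), `seed` (default 0), `fit_opts`
#' (list passed to [nhpp_fit()]), `out_dir` (optional).
#'
#' @param config a named list; unknown keys are rejected.
#' @return a list with `grid` (the [fit_blocks()] result), `results` (tidy
#'   data frame: region_id, param, A, B, C, D, p_value) and `manifest`.
#' @export
run_nhpp_pipeline <- function(config) {
  config <- .check_config(config,
                          allowed = c("cloud_a", "cloud_b", "box",
                                      "block_edge", "min_points", "fold",
                                      "params", "two_sided_fold", "adjust",
                                      "seed", "fit_opts", "out_dir"),
                          required = c("cloud_a", "cloud_b"))
  defaults <- list(box = NULL, block_edge = 500, min_points = 50L, fold = 2,
                   params = c("a", "inv_b_x", "inv_b_y", "inv_b_z"),
                   two_sided_fold = FALSE, adjust = FALSE, seed = 0L,
                   fit_opts = list(), out_dir = NULL)
  for (k in names(defaults))
    if (is.null(config[[k]])) config[k] <- list(defaults[[k]])

  get_cloud <- function(x) if (inherits(x, "point_cloud")) x
    else read_point_cloud(x)
  ca <- get_cloud(config$cloud_a); cb <- get_cloud(config$cloud_b)

  manifest <- run_manifest(config[setdiff(names(config),
                                          c("cloud_a", "cloud_b", "box"))])
  t0 <- proc.time()[3]
  grid <- do.call(fit_blocks,
                  c(list(cloud_a = ca, cloud_b = cb, box = config$box,
                         block_edge = config$block_edge,
                         min_points = config$min_points,
                         seed = config$seed), config$fit_opts))
  manifest <- manifest_stage(manifest, "block_fits", proc.time()[3] - t0)

  eval_blocks <- grid$blocks[grid$blocks$evaluable, , drop = FALSE]
  regions <- sort(unique(eval_blocks$region_id))
  rows <- list()
  for (param in config$params) {
    changed <- extract_changed_blocks(grid, param = param,
                                      fold = config$fold,
                                      two_sided = config$two_sided_fold)
    for (r in regions) {
      ft <- fisher_region_test(changed, eval_blocks$region_id == r)
      rows[[length(rows) + 1L]] <-
        data.frame(region_id = r, param = param,
                   A = ft$table[1, 1], B = ft$table[1, 2],
                   C = ft$table[2, 1], D = ft$table[2, 2],
                   p_value = ft$p_value)
    }
  }
  results <- do.call(rbind, rows)
  if (isTRUE(config$adjust))
    results$p_adjusted <- stats::p.adjust(results$p_value, method = "BH")
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(grid$blocks,
                     file.path(config$out_dir, "block_fits.csv"),
                     row.names = FALSE)
    utils::write.csv(results, file.path(config$out_dir, "fisher_results.csv"),
                     row.names = FALSE)
    write_manifest(manifest, file.path(config$out_dir, "manifest.json"))
  }
  list(grid = grid, results = results, manifest = manifest)
}
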