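#' Pipeline configuration
#'
#' Collects the inputs and stage parameters for [run_pipeline()]. Inputs may
#' be given as paths (CSV / Matrix Market directory, as written by the io
#' functions) or as in-memory objects; paths are checked up front.
#'
#' @param cells Raw imaging cell table (path to CSV or `cell_table`).
#' @param spots Spot matrix (path to a directory or `spot_matrix`).
#' @param reference Reference expression (path to CSV with an `id` column,
#'   or a profiles-by-genes matrix). Optional if the cell table already
#'   carries `type` labels and the `annotate` stage is disabled.
#' @param reference_labels Reference labels (path to CSV `id,label` or named
#'   vector).
#' @param out_dir Output directory.
#' @param alias_map Named protein -> gene alias map (or JSON path).
#' @param stages Character subset of
#'   `c("normalize", "annotate", "register", "deconvolve", "qc")`, run in
#'   that order.
#' @param dapi_channel,size_quantile_range,dapi_quantile,area_normalize,quantiles
#'   Imaging QC and normalization parameters (see [filter_cells()] and
#'   [normalize_features()]).
#' @param smoothing_weight,pivot_fraction Annotation parameters (see
#'   [match_pivots()]).
#' @param gaussian_sigma Mask-detection smoothing sigma in mask pixels;
#'   default (NULL) uses the channel pitch at the raster resolution.
#' @param raster_resolution Original pixels per mask pixel for registration
#'   rasters; default scales the longer field side to ~256 mask pixels.
#' @param zero_denominator_policy Splitting policy (see [split_spots()]).
#' @param seed Integer seed recorded in all outputs and used by the
#'   stochastic stages.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cells, spots, reference = NULL,
                            reference_labels = NULL, out_dir,
                            alias_map = NULL,
                            stages = c("normalize", "annotate", "register",
                                       "deconvolve", "qc"),
                            dapi_channel = "DAPI",
                            size_quantile_range = c(0.05, 0.95),
                            dapi_quantile = 0.1,
                            area_normalize = TRUE,
                            quantiles = c(0.05, 0.95),
                            smoothing_weight = 0.3,
                            pivot_fraction = 0.10,
                            gaussian_sigma = NULL,
                            raster_resolution = NULL,
                            zero_denominator_policy = "beta",
                            seed = 1) {
  stages <- match.arg(stages, several.ok = TRUE)
  for (p in list(cells, spots, reference, reference_labels)) {
    if (is.character(p) && length(p) == 1L && is.null(names(p)) && !file.exists(p))
      stop("input path does not exist: ", p)
  }
  if (is.character(alias_map)) alias_map <- jsonlite::read_json(alias_map,
                                                                simplifyVector = TRUE)
  structure(list(cells = cells, spots = spots, reference = reference,
                 reference_labels = reference_labels, out_dir = out_dir,
                 alias_map = alias_map, stages = stages,
                 dapi_channel = dapi_channel,
                 size_quantile_range = size_quantile_range,
                 dapi_quantile = dapi_quantile,
                 area_normalize = area_normalize, quantiles = quantiles,
                 smoothing_weight = smoothing_weight,
                 pivot_fraction = pivot_fraction,
                 gaussian_sigma = gaussian_sigma,
                 raster_resolution = raster_resolution,
                 zero_denominator_policy = zero_denominator_policy,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

## Paint occupied spot footprints (pitch-sized, so adjacent channels merge
## into a closed tissue silhouette) into a raster of the sequencing frame.
spot_density_image <- function(spot_matrix, resolution = 1) {
  tot <- Matrix::rowSums(spot_matrix$counts)
  sp <- spot_matrix$spots
  half <- spot_matrix$pitch / 2
  w <- max(sp$x) + half; h <- max(sp$y) + half
  nc <- ceiling(w / resolution); nr <- ceiling(h / resolution)
  img <- matrix(0, nr, nc)
  occ <- which(tot > 0)
  for (i in occ) {
    c1 <- max(1, floor((sp$x[i] - half) / resolution) + 1)
    c2 <- min(nc, ceiling((sp$x[i] + half) / resolution))
    r1 <- max(1, floor((sp$y[i] - half) / resolution) + 1)
    r2 <- min(nr, ceiling((sp$y[i] + half) / resolution))
    img[r1:r2, c1:c2] <- img[r1:r2, c1:c2] + tot[i]
  }
  attr(img, "resolution") <- resolution
  img
}

#' Run the full integration pipeline
#'
#' Executes, in order, the enabled stages: `normalize` (imaging QC filters
#' and quantile scaling), `annotate` (linked-feature pivot matching, label
#' transfer, SVM propagation), `register` (tissue-mask similarity transform
#' from the imaging frame to the sequencing frame), `deconvolve` (cell-to-
#' spot assignment, per-spot type proportions, sub-spot splitting, protein
#' sub-spot aggregation) and `qc` (sub-spot embedding ASW/ARI and
#' conservation residual). Every stage logs its outputs into the run report;
#' outputs are hashed so reruns can be checked for bit-identity. Any stage
#' error aborts the run with the failing stage named; outputs of completed
#' stages are kept and the report flags the failure.
#'
#' @param config A [pipeline_config()].
#' @return The run report (list), invisibly also written to
#'   `out_dir/report.json`. Fields: per-stage `status`, `outputs` (with md5
#'   hashes), `warnings`, plus seed and parameters.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(seed = config$seed, stages = list(),
                 provenance = provenance_block(config$seed))
  state <- new.env(parent = emptyenv())

  finish <- function(report) {
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    report
  }
  run_stage <- function(name, fun) {
    warns <- character()
    res <- withCallingHandlers(
      tryCatch(fun(), error = function(e) e),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    if (inherits(res, "error")) {
      report$stages[[name]] <<- list(status = "error",
                                     message = conditionMessage(res),
                                     warnings = warns)
      finish(report)
      stop(sprintf("pipeline aborted at stage '%s': %s", name,
                   conditionMessage(res)), call. = FALSE)
    }
    hashes <- if (length(res$outputs))
      as.list(tools::md5sum(unlist(res$outputs))) else list()
    report$stages[[name]] <<- list(status = "ok", outputs = hashes,
                                   warnings = warns,
                                   info = res$info %||% list())
    invisible(NULL)
  }

  load_cells <- function() {
    if (is_path(config$cells)) read_cell_table(config$cells)
    else as_cell_table(config$cells)
  }
  load_spots <- function() {
    if (is_path(config$spots)) read_spot_matrix(config$spots)
    else config$spots
  }
  load_reference <- function() {
    if (is.null(config$reference)) stop("annotation requires a reference")
    counts <- if (is_path(config$reference)) {
      df <- utils::read.csv(config$reference, check.names = FALSE)
      m <- as.matrix(df[, -1, drop = FALSE]); rownames(m) <- df[[1]]; m
    } else as.matrix(config$reference)
    labels <- if (is_path(config$reference_labels)) {
      df <- utils::read.csv(config$reference_labels, stringsAsFactors = FALSE)
      stats::setNames(df[[2]], df[[1]])
    } else config$reference_labels
    if (is.null(labels)) stop("annotation requires reference labels")
    list(counts = counts, labels = labels)
  }

  if ("normalize" %in% config$stages) run_stage("normalize", function() {
    cells <- load_cells()
    filtered <- filter_cells(cells,
                             size_quantile_range = config$size_quantile_range,
                             dapi_channel = config$dapi_channel,
                             dapi_quantile = config$dapi_quantile)
    norm <- normalize_features(filtered, area_normalize = config$area_normalize,
                               q = config$quantiles)
    state$cells <- norm$cells
    f <- file.path(config$out_dir, "cells_normalized.csv")
    write_cell_table(norm$cells, f)
    rec <- file.path(config$out_dir, "normalization.json")
    jsonlite::write_json(c(unclass(norm$record),
                           list(provenance = provenance_block(config$seed))),
                         rec, auto_unbox = TRUE, digits = NA, force = TRUE)
    list(outputs = list(f, rec),
         info = list(n_cells_in = nrow(cells), n_cells_kept = nrow(filtered)))
  })

  if ("annotate" %in% config$stages) run_stage("annotate", function() {
    if (is.null(state$cells)) state$cells <- load_cells()
    ref <- load_reference()
    state$reference <- ref
    ref_norm <- lognormalize_counts(ref$counts)
    linked <- link_features(ref_norm, state$cells, alias_map = config$alias_map)
    pivots <- match_pivots(ref_norm, state$cells, linked,
                           smoothing_weight = config$smoothing_weight,
                           pivot_fraction = config$pivot_fraction,
                           seed = config$seed)
    pivots <- transfer_labels(pivots, ref$labels)
    prop <- propagate_labels(pivots, state$cells, seed = config$seed)
    state$labels <- stats::setNames(prop$labels$label, prop$labels$cell_id)
    f <- file.path(config$out_dir, "labels.csv")
    utils::write.csv(prop$labels, f, row.names = FALSE)
    mj <- file.path(config$out_dir, "annotation_metrics.json")
    jsonlite::write_json(list(f1 = as.list(prop$f1), macro_f1 = prop$macro_f1,
                              n_pivots = nrow(pivots),
                              n_linked_features = sum(linked$retained),
                              provenance = provenance_block(config$seed)),
                         mj, auto_unbox = TRUE, digits = NA)
    list(outputs = list(f, mj),
         info = list(macro_f1 = prop$macro_f1, n_pivots = nrow(pivots)))
  })

  if ("register" %in% config$stages) run_stage("register", function() {
    if (is.null(state$cells)) state$cells <- load_cells()
    sm <- load_spots(); state$spots <- sm
    half <- sm$pitch / 2
    extent <- max(max(sm$spots$x) + half, max(sm$spots$y) + half,
                  max(state$cells$x), max(state$cells$y))
    res <- config$raster_resolution %||% max(1, round(extent / 256))
    mov_img <- rasterize_points(state$cells,
                                field_size = c(max(state$cells$x) + res,
                                               max(state$cells$y) + res),
                                resolution = res)
    fix_img <- spot_density_image(sm, resolution = res)
    ## mask smoothing at the pitch scale merges the channel pattern (fixed
    ## side) and bridges sparse niches (moving side) into one tissue blob
    sigma <- config$gaussian_sigma %||% (sm$pitch / res)
    mov_mask <- detect_tissue_mask(mov_img, gaussian_sigma = sigma)
    fix_mask <- detect_tissue_mask(fix_img, gaussian_sigma = sigma)
    fit <- estimate_similarity_transform(mov_mask, fix_mask)
    ## polish 1: density images matched at the pitch scale (masks carry only
    ## the outline)
    rfi <- refine_similarity_intensity(mov_img, fix_img, fit$transform,
                                       smooth_sigma = sm$pitch / res)
    ## polish 2: observed spot totals vs soft-binned cell counts on the
    ## grid's own geometry; raster- and lattice-artifact free
    rfs <- refine_similarity_spot_counts(state$cells, sm,
                                         rescale_transform(rfi$transform, res))
    state$transform <- rfs$transform
    f <- file.path(config$out_dir, "transform.json")
    write_transform(state$transform, f, loss = rfs$loss,
                    converged = fit$converged && rfs$converged,
                    seed = config$seed)
    list(outputs = list(f),
         info = list(scale = state$transform$scale,
                     rotation_deg = state$transform$rotation,
                     mask_loss = fit$loss, intensity_loss = rfi$loss,
                     spot_count_loss = rfs$loss, resolution = res))
  })

  if ("deconvolve" %in% config$stages) run_stage("deconvolve", function() {
    if (is.null(state$cells)) state$cells <- load_cells()
    if (is.null(state$spots)) state$spots <- load_spots()
    cells <- state$cells
    if (!is.null(state$transform)) cells <- apply_transform(state$transform, cells)
    labels <- state$labels %||% (
      if ("type" %in% names(cells)) stats::setNames(cells$type, cells$cell_id)
      else stop("no cell labels: run the annotate stage or supply a 'type' column"))
    assignment <- assign_cells_to_spots(cells, state$spots)
    prop <- compute_proportions(assignment, labels,
                                type_universe = sort(unique(unname(labels))),
                                spot_ids = state$spots$spots$spot_id)
    if (is.null(state$reference) && !is.null(config$reference))
      state$reference <- load_reference()
    mu <- if (!is.null(state$reference))
      aggregate_signatures(lognormalize_counts(state$reference$counts, log1p = FALSE),
                           state$reference$labels)
    else stop("deconvolution requires a reference for the signature matrix")
    mu <- mu[rownames(prop$beta)[rownames(prop$beta) %in% rownames(mu)], ,
             drop = FALSE]
    if (!setequal(rownames(mu), rownames(prop$beta)))
      stop("cell labels include types absent from the reference")
    subs <- split_spots(state$spots, prop, mu,
                        zero_denominator_policy = config$zero_denominator_policy)
    state$subspots <- subs
    state$assignment <- assignment
    state$cells_registered <- cells

    bfile <- file.path(config$out_dir, "beta.csv")
    utils::write.csv(data.frame(type = rownames(prop$beta),
                                as.data.frame(prop$beta, check.names = FALSE),
                                check.names = FALSE),
                     bfile, row.names = FALSE)
    sdir <- file.path(config$out_dir, "subspots")
    write_subspots(subs, sdir)
    pr <- aggregate_codex_subspots(cells, assignment, labels = labels)
    pfile <- file.path(config$out_dir, "protein_subspots.csv")
    utils::write.csv(data.frame(key = rownames(pr$protein),
                                as.data.frame(pr$protein, check.names = FALSE),
                                check.names = FALSE),
                     pfile, row.names = FALSE)
    state$protein_subspots <- pr
    list(outputs = list(bfile, pfile,
                        file.path(sdir, "subspots.mtx"),
                        file.path(sdir, "subspots.tsv"),
                        file.path(sdir, "genes.tsv")),
         info = list(n_assigned = sum(!is.na(assignment$spot_id)),
                     n_subspots = nrow(subs$counts)))
  })

  if ("qc" %in% config$stages) run_stage("qc", function() {
    if (is.null(state$subspots)) stop("qc stage needs deconvolution results")
    subs <- state$subspots
    expr <- log1p(lognormalize_counts(subs$counts, log1p = FALSE))
    keep <- apply(expr, 2, stats::sd) > 0
    pc <- stats::prcomp(expr[, keep, drop = FALSE], rank. = min(10, sum(keep)))
    asw <- average_silhouette_width(pc$x, subs$keys$type)
    km <- withr::with_seed(config$seed,
                           stats::kmeans(pc$x, centers = length(unique(subs$keys$type)),
                                         nstart = 10))
    ari <- adjusted_rand_index(km$cluster, subs$keys$type)
    x <- as.matrix(state$spots$counts[unique(subs$keys$spot_id), subs$genes,
                                      drop = FALSE])
    recon <- rowsum(subs$counts, subs$keys$spot_id)[rownames(x), , drop = FALSE]
    if (!is.null(subs$unassigned))
      recon <- recon + subs$unassigned[rownames(x), , drop = FALSE]
    cons <- max(abs(recon - x) / pmax(x, 1))
    f <- file.path(config$out_dir, "qc.json")
    jsonlite::write_json(list(asw = asw, ari = ari,
                              conservation_max_rel_error = cons,
                              provenance = provenance_block(config$seed)),
                         f, auto_unbox = TRUE, digits = NA)
    list(outputs = list(f), info = list(asw = asw, ari = ari))
  })

  report$parameters <- config[setdiff(names(config),
                                      c("cells", "spots", "reference",
                                        "reference_labels"))]
  finish(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_path <- function(x) is.character(x) && length(x) == 1L && is.null(names(x))
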