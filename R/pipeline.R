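# Config-driven pipeline stages. Each run_* function reads its inputs,
# executes one stage, writes machine-readable outputs plus a provenance
# block (config hash, seed, package version) into the output directory,
# and returns its main result invisibly. The numbered scripts under
# analysis/ are thin drivers over these functions.

#' Read a pipeline configuration
#'
#' YAML with any of: `paths` (annotations, taxonomy, catches, out_dir),
#' `rank`, `seed`, `design` (kind, intervals, sizes, n_reps),
#' `sufficiency` (span, slope_tol, cv_threshold), `cluster` (rank, k,
#' effort_correct), `sim` (n_frames, organisms_total, occupancy,
#' persistence, fps). Missing entries take package defaults.
#'
#' @param path YAML file path, or `NULL` for an all-defaults config.
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path = NULL) {
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  cfg <- utils::modifyList(default_pipeline_config(), user)
  class(cfg) <- "pipeline_config"
  cfg
}

default_pipeline_config <- function() {
  list(
    paths = list(annotations = NULL, taxonomy = NULL, catches = NULL,
                 out_dir = "towcam-out"),
    rank = "taxon",
    seed = 1L,
    design = list(kind = "random", n_reps = 10L,
                  intervals = NULL, sizes = NULL),
    sufficiency = list(span = 2/3, slope_tol = 0.05, cv_threshold = 0.25),
    cluster = list(rank = "class", k = 3L, effort_correct = FALSE),
    sim = list(n_frames = 4393L, organisms_total = 3035,
               occupancy = 1463/4393, persistence = c(1L, 1L), fps = 5)
  )
}

provenance <- function(cfg, stage) {
  list(stage = stage,
       config_hash = rlang::hash(unclass(cfg)),
       seed = cfg$seed,
       package = "towcam",
       version = as.character(utils::packageVersion("towcam")))
}

write_provenance <- function(cfg, stage, out_dir) {
  jsonlite::write_json(provenance(cfg, stage),
                       file.path(out_dir, paste0(stage, "_provenance.json")),
                       auto_unbox = TRUE)
}

ensure_out_dir <- function(cfg) {
  dir.create(cfg$paths$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg$paths$out_dir
}

#' Pipeline stage: simulate a calibrated frame stream
#'
#' Calibrates the generator to the configured organism total and
#' occupancy, generates the stream, and writes `annotations.csv` (the
#' same schema as real data), `truth.json`, and a provenance block.
#'
#' @param cfg A `pipeline_config`.
#' @return The generated stream (list of records and truth), invisibly.
#' @export
run_simulate <- function(cfg) {
  out_dir <- ensure_out_dir(cfg)
  sim <- cfg$sim
  config <- calibrate(organisms_total = sim$organisms_total,
                      n_frames = sim$n_frames,
                      occupancy = sim$occupancy,
                      persistence_range = sim$persistence,
                      fps = sim$fps, seed = cfg$seed)
  stream <- generate_frame_stream(config)
  write_frame_annotations(stream$records,
                          file.path(out_dir, "annotations.csv"))
  truth <- stream$truth
  truth$organisms <- NULL
  truth$theta <- config$theta
  truth$organism_rate <- config$organism_rate
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  write_provenance(cfg, "simulate", out_dir)
  message("simulate: ", nrow(stream$records), " frames, theta = ",
          signif(config$theta, 4), ", seed = ", cfg$seed)
  invisible(stream)
}

load_annotations <- function(cfg) {
  p <- cfg$paths$annotations
  if (is.null(p)) p <- file.path(cfg$paths$out_dir, "annotations.csv")
  if (!file.exists(p)) {
    stop("annotations not found at '", p,
         "'; set paths$annotations or run run_simulate() first",
         call. = FALSE)
  }
  read_frame_annotations(p)
}

load_taxonomy <- function(cfg) {
  if (is.null(cfg$paths$taxonomy)) read_taxonomy()
  else read_taxonomy(cfg$paths$taxonomy)
}

#' Pipeline stage: subsampling sufficiency
#'
#' Runs the configured subsampling design over the annotations, fits the
#' LOWESS plateau and the CV model, and writes `curve.csv`,
#' `sufficiency.json` and provenance.
#'
#' @param cfg A `pipeline_config`.
#' @return The `sufficiency_report`, invisibly.
#' @export
run_sufficiency <- function(cfg) {
  out_dir <- ensure_out_dir(cfg)
  records <- load_annotations(cfg)
  taxonomy <- load_taxonomy(cfg)
  N <- sum(records$usable)
  des <- cfg$design
  sizes <- des$sizes
  if (identical(des$kind, "random") && is.null(sizes)) {
    sizes <- log_spaced_sizes(31, min(1778, N), 36)
  }
  design <- subsample_design(kind = des$kind, intervals = des$intervals,
                             sizes = sizes, n_reps = des$n_reps)
  withr::with_seed(cfg$seed, {
    curve <- run_design(records, design, taxonomy, rank = cfg$rank)
  })
  readr::write_csv(curve, file.path(out_dir, "curve.csv"), progress = FALSE)
  rep <- sufficiency_report(curve, n_total = N,
                            span = cfg$sufficiency$span,
                            slope_tol = cfg$sufficiency$slope_tol,
                            cv_threshold = cfg$sufficiency$cv_threshold)
  write_sufficiency_report(rep, file.path(out_dir, "sufficiency.json"))
  write_provenance(cfg, "sufficiency", out_dir)
  message("sufficiency: n* = ", rep$n_star, ", n_cv = ", rep$n_cv,
          ", recommended interval = ", rep$recommended_interval)
  invisible(rep)
}

#' Pipeline stage: full run report
#'
#' Diversity tables per group and pooled, community clustering with
#' Newick export, and sediment composition (when sediment columns are
#' present). Writes `diversity.csv`, `clusters.csv`, `dendrogram.nwk`,
#' optionally `sediment.csv`, and provenance.
#'
#' @param cfg A `pipeline_config`.
#' @return List of the report tables, invisibly.
#' @export
run_report <- function(cfg) {
  out_dir <- ensure_out_dir(cfg)
  records <- load_annotations(cfg)
  taxonomy <- load_taxonomy(cfg)
  div <- diversity_by_group(records, taxonomy, rank = cfg$rank)
  readr::write_csv(div, file.path(out_dir, "diversity.csv"),
                   progress = FALSE)
  out <- list(diversity = div)
  n_groups <- length(unique(records$transect_id))
  if (n_groups >= 2) {
    m <- community_matrix(records, taxonomy, rank = cfg$cluster$rank,
                          effort_correct = isTRUE(cfg$cluster$effort_correct))
    sm <- standardize(m)
    tree <- ward_cluster(sm)
    k <- min(cfg$cluster$k, nrow(sm))
    groups <- cut_tree(tree, k)
    write_dendrogram_newick(tree, file.path(out_dir, "dendrogram.nwk"))
    readr::write_csv(tibble::tibble(group = names(groups),
                                    cluster = unname(groups)),
                     file.path(out_dir, "clusters.csv"), progress = FALSE)
    out$tree <- tree
    out$clusters <- groups
  } else {
    warning("fewer than 2 transects: clustering skipped", call. = FALSE)
  }
  if (length(sediment_columns(records)) > 0) {
    sed <- sediment_composition(records)
    readr::write_csv(sed, file.path(out_dir, "sediment.csv"),
                     progress = FALSE)
    out$sediment <- sed
  }
  write_provenance(cfg, "report", out_dir)
  invisible(out)
}
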