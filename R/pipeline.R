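#' Build a pipeline run configuration
#'
#' Defaults follow the reference analysis settings: routes of up to 4 steps,
#' edge FDR at alpha 0.05, route-consistency threshold 0.5 (strict), IQR
#' fence multiplier 1.5, top-10 pathway ranking, per-matrix max
#' normalisation before cross-type metric comparisons.
#'
#' @param atlas path to the atlas CSV
#' @param sc_dir directory of per-subject SC TSV matrices (`<subject>.tsv`)
#' @param fc_dir directory of per-subject FC TSV matrices (`<subject>.tsv`)
#' @param out_dir output directory
#' @param max_steps hop limit for routing (default 4)
#' @param fc_policy `"auto"`, `"masked"` or `"all_nonzero"`
#' @param mode USFC accumulation `"absolute"` or `"signed"`
#' @param alpha FDR level (default 0.05)
#' @param consistency_threshold modal-route support threshold (default 0.5)
#' @param fence_k IQR fence multiplier (default 1.5)
#' @param top_k number of top pathways to report (default 10)
#' @param normalize matrix normalisation for metric comparisons
#' @param seed integer seed recorded in the report
#' @return a `run_config` list
#' @export
run_config <- function(atlas, sc_dir, fc_dir, out_dir,
                       max_steps = 4L, fc_policy = "auto",
                       mode = "absolute", alpha = 0.05,
                       consistency_threshold = 0.5, fence_k = 1.5,
                       top_k = 10L, normalize = "max", seed = 1L) {
  structure(
    list(atlas = atlas, sc_dir = sc_dir, fc_dir = fc_dir, out_dir = out_dir,
         max_steps = as.integer(max_steps), fc_policy = fc_policy,
         mode = mode, alpha = alpha,
         consistency_threshold = consistency_threshold,
         fence_k = fence_k, top_k = as.integer(top_k),
         normalize = normalize, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' Flat keys mirroring [run_config()] arguments; explicit arguments passed
#' via `...` override file values.
#'
#' @param path YAML file path
#' @param ... overrides for individual keys
#' @return a `run_config`
#' @export
read_run_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(run_config, vals)
}

load_cohort_dir <- function(config) {
  atlas <- read_atlas(config$atlas)
  fc_files <- sort(list.files(config$fc_dir, pattern = "\\.tsv$"))
  ids <- sub("\\.tsv$", "", fc_files)
  if (!length(ids)) stop("no FC matrices found in ", config$fc_dir,
                         call. = FALSE)
  subjects <- lapply(ids, function(id) {
    sc_path <- file.path(config$sc_dir, paste0(id, ".tsv"))
    if (!file.exists(sc_path)) {
      stop("missing SC matrix for subject ", id, call. = FALSE)
    }
    sc <- read_conn_matrix(sc_path, atlas, "SC")
    fc <- read_conn_matrix(file.path(config$fc_dir, paste0(id, ".tsv")),
                           atlas, "FC")
    subject_connectome(id, sc, fc)
  })
  list(atlas = atlas, subjects = subjects)
}

#' Run the full traffic-map pipeline
#'
#' Stages: route every subject's functional connections over the structural
#' graph, accumulate per-subject USFC, group statistics (mean, t, FDR),
#' regional loads with IQR outliers, network summary, top-k pathway ranking,
#' step-stratified SC-FC coupling, and cross-type graph-metric comparisons.
#' Every intermediate artifact is written under `config$out_dir` together
#' with a JSON report embedding the resolved configuration.
#'
#' @param config a [run_config()]
#' @return the report list, invisibly
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  inp <- load_cohort_dir(config)
  atlas <- inp$atlas
  subjects <- inp$subjects
  message("stage load: ", length(subjects), " subjects, ",
          nrow(atlas), " regions")

  D <- euclidean_distances(atlas)
  write_conn_matrix(D, file.path(config$out_dir, "distances.tsv"))

  dir.create(file.path(config$out_dir, "routes"), showWarnings = FALSE)
  dir.create(file.path(config$out_dir, "usfc"), showWarnings = FALSE)
  route_tables <- vector("list", length(subjects))
  usfc_list <- vector("list", length(subjects))
  n_unroutable <- 0L
  for (si in seq_along(subjects)) {
    subj <- subjects[[si]]
    rt <- route_all_pairs(subj, D, max_steps = config$max_steps,
                          fc_policy = config$fc_policy)
    n_unroutable <- n_unroutable + nrow(rt$unroutable)
    write_route_table(rt, atlas, subj$fc,
                      file.path(config$out_dir, "routes",
                                paste0(subj$subject_id, ".csv")))
    u <- accumulate_usfc(rt, subj$fc, mode = config$mode)
    write_conn_matrix(u, file.path(config$out_dir, "usfc",
                                   paste0(subj$subject_id, ".tsv")))
    route_tables[[si]] <- rt
    usfc_list[[si]] <- u
  }
  message("stage route/build: ",
          sum(vapply(route_tables, function(r) length(r$routes), integer(1))),
          " routes, ", n_unroutable, " unroutable pairs")

  group <- group_usfc(usfc_list, alpha = config$alpha)
  write_conn_matrix(group$mean, file.path(config$out_dir,
                                          "group_usfc_mean.tsv"))
  write_conn_matrix(group$mean_sig, file.path(config$out_dir,
                                              "group_usfc_mean_sig.tsv"))
  message("stage group: ", sum(group$sig_mask[upper.tri(group$sig_mask)]),
          " significant edges")

  loads <- regional_load(group$mean)
  outliers <- iqr_outliers(loads, k = config$fence_k)
  netsum <- network_summary(usfc_list, atlas, alpha = config$alpha)
  top <- top_k_edges(group, k = config$top_k)
  write.csv(top, file.path(config$out_dir, "top_edges.csv"),
            row.names = FALSE)
  write.csv(data.frame(region = names(loads), load = unname(loads)),
            file.path(config$out_dir, "regional_load.csv"),
            row.names = FALSE)
  message("stage summaries: ", length(outliers$outlier_regions),
          " outlier regions; top network ", netsum$ranking[1L])

  consistent <- modal_routes(route_tables, subjects,
                             threshold = config$consistency_threshold)
  coupling <- coupling_by_step(consistent, max_steps = config$max_steps)
  write.csv(consistent, file.path(config$out_dir, "consistent_routes.csv"),
            row.names = FALSE)
  write.csv(coupling$table, file.path(config$out_dir, "coupling.csv"),
            row.names = FALSE)
  message("stage coupling: ", nrow(consistent), " consistent routes")

  metrics <- compare_metrics(subjects, usfc_list,
                             normalize = config$normalize,
                             alpha = config$alpha)
  write.csv(metrics$global, file.path(config$out_dir, "metrics_global.csv"),
            row.names = FALSE)
  write.csv(metrics$global_tests,
            file.path(config$out_dir, "metrics_global_tests.csv"),
            row.names = FALSE)
  message("stage metrics: done")

  report <- list(
    config = unclass(config),
    seed = config$seed,
    n_subjects = length(subjects),
    n_regions = nrow(atlas),
    n_routes = sum(vapply(route_tables, function(r) length(r$routes),
                          integer(1))),
    n_unroutable_pairs = n_unroutable,
    n_significant_edges = sum(group$sig_mask[upper.tri(group$sig_mask)]),
    outlier_regions = outliers$outlier_regions,
    upper_fence = outliers$upper_fence,
    network_ranking = netsum$ranking,
    top_edges = top,
    n_consistent_routes = nrow(consistent),
    coupling = coupling$table,
    metrics_global_tests = metrics$global_tests
  )
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}
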