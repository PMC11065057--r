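# Cached analyses of the default synthetic cohort, shared by the recovery
# tests so each seed's pipeline runs once per session.
.cohort_cache <- new.env(parent = emptyenv())

default_cohort_analysis <- function(seed) {
  key <- paste0("seed", seed)
  if (!is.null(.cohort_cache[[key]])) return(.cohort_cache[[key]])
  cfg <- synth_config(seed = seed)
  atlas <- generate_atlas(cfg)
  cohort <- generate_cohort(cfg, atlas)
  D <- euclidean_distances(atlas)
  route_tables <- lapply(cohort$subjects, route_all_pairs, D = D)
  usfc_list <- mapply(function(rt, s) accumulate_usfc(rt, s$fc),
                      route_tables, cohort$subjects, SIMPLIFY = FALSE)
  group <- group_usfc(usfc_list)
  res <- list(cfg = cfg, atlas = atlas, cohort = cohort, D = D,
              route_tables = route_tables, usfc_list = usfc_list,
              group = group)
  .cohort_cache[[key]] <- res
  res
}

top_edge_keys <- function(top, atlas) {
  labs <- atlas_labels(atlas)
  ia <- match(top$region_a, labs)
  ib <- match(top$region_b, labs)
  paste(pmin(ia, ib), pmax(ia, ib), sep = ":")
}
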