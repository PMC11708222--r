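usage_error <- function(...) {
  stop(structure(class = c("allelegeo_usage_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

#' Read a pipeline run configuration
#'
#' A YAML or JSON document whose keys mirror the arguments of the `run_*`
#' functions: `fasta`, `metadata`, `panel`, `out_dir`, `origin`,
#' `exclude_deleted`, `region` (`[start, end]` or `"start:end"`),
#' `numbering_offset`, `seed`, and a `simulate` block passed to
#' [sim_spec()].  Relative input paths are resolved against the config
#' file's directory.
#'
#' @param path config file.
#' @return a named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) usage_error("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  for (key in c("fasta", "metadata", "panel")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]])) {
      rel <- file.path(dirname(path), cfg[[key]])
      if (file.exists(rel)) cfg[[key]] <- rel
    }
  }
  cfg
}

resolve_config <- function(config) {
  defaults <- list(out_dir = ".", exclude_deleted = FALSE, seed = 1L,
                   match = 1L, mismatch = -1L, gap = -2L,
                   numbering_offset = 0L)
  config <- utils::modifyList(defaults, config)
  if (!is.null(config$region) && is.character(config$region)) {
    parts <- as.integer(strsplit(config$region, ":", fixed = TRUE)[[1L]])
    config$region <- parts
  }
  config
}

config_inputs <- function(config) {
  if (is.null(config$fasta)) usage_error("config must name a 'fasta' input")
  if (is.null(config$panel)) usage_error("config must name a 'panel' config")
  if (!file.exists(config$fasta)) usage_error("FASTA not found: ", config$fasta)
  if (!file.exists(config$panel)) usage_error("panel config not found: ", config$panel)
  seqs <- read_fasta(config$fasta)
  panel <- tryCatch(read_panel(config$panel),
                    error = function(e) usage_error("invalid panel config: ",
                                                    conditionMessage(e)))
  list(seqs = seqs, panel = panel)
}

#' Type every isolate and write the per-isolate call table
#'
#' @param config named list (or path via [read_run_config()]): `fasta`,
#'   `panel`, `out_dir`.
#' @return path of the written call table, invisibly.
#' @export
run_type <- function(config) {
  config <- resolve_config(config)
  inp <- config_inputs(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- file.path(config$out_dir, "calls.tsv")
  if (!nrow(inp$seqs)) {
    warning("empty FASTA: writing an empty call table", call. = FALSE)
    write.table(call_table(list()), out, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  genotypes <- type_panel(inp$seqs, inp$panel)
  tab <- call_table(genotypes)
  write.table(tab, out, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  message(sprintf("typed %d isolates: %d typable, %d untypable",
                  nrow(tab), sum(tab$typable), sum(!tab$typable)))
  invisible(out)
}

#' Group typed isolates and write the group table and GeoJSON map
#'
#' @param config named list: `fasta`, `panel`, `metadata` (optional),
#'   `origin` (optional origin-class filter), `exclude_deleted`, `out_dir`.
#' @return list of written paths, invisibly.
#' @export
run_group <- function(config) {
  config <- resolve_config(config)
  inp <- config_inputs(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- if (!is.null(config$metadata)) {
    if (!file.exists(config$metadata)) usage_error("metadata not found: ", config$metadata)
    read_metadata(config$metadata)
  }
  genotypes <- type_panel(inp$seqs, inp$panel)
  include <- NULL
  if (!is.null(meta) && (!is.null(config$origin) || isTRUE(config$exclude_deleted))) {
    include <- filter_isolates(meta, origin = config$origin,
                               exclude_deleted = isTRUE(config$exclude_deleted))
  }
  groups <- build_groups(genotypes, include = include)
  n_iso <- sum(vapply(groups, function(g) length(g$member_ids), integer(1)))
  message(sprintf("%d groups among %d isolates", length(groups), n_iso))
  paths <- list(groups = file.path(config$out_dir, "groups.tsv"))
  if (!is.null(meta)) {
    has_coords <- any(!is.na(meta$lat))
    if (has_coords) {
      groups <- lapply(groups, group_dispersal, meta = meta)
    } else {
      warning("metadata has no coordinates; GeoJSON will be empty", call. = FALSE)
    }
    paths$geojson <- file.path(config$out_dir, "groups.geojson")
    export_geojson(groups, meta, paths$geojson)
  }
  write.table(group_table(groups), paths$groups, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  invisible(paths)
}

#' Build the neighbor-joining tree and the clade-concordance report
#'
#' @param config named list: `fasta`, `panel` (optional; only used for
#'   input validation), `metadata` (optional; supplies clade labels),
#'   `region` (optional `c(start, end)` with `numbering_offset`),
#'   `match`/`mismatch`/`gap` alignment scores, `out_dir`.
#' @return list of written paths, invisibly.
#' @export
run_tree <- function(config) {
  config <- resolve_config(config)
  if (is.null(config$fasta)) usage_error("config must name a 'fasta' input")
  if (!file.exists(config$fasta)) usage_error("FASTA not found: ", config$fasta)
  seqs <- read_fasta(config$fasta)
  if (nrow(seqs) < 3L) usage_error("need at least 3 sequences for a tree, got ",
                                   nrow(seqs))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  region <- NULL
  if (!is.null(config$region)) {
    region <- region_spec(config$region[1L], config$region[2L],
                          config$numbering_offset)
    message(sprintf("region [%d, %d]: %d-column extraction",
                    region$start_nt, region$end_nt,
                    region$end_nt - region$start_nt + 1L))
  }
  d <- build_distance_matrix(seqs, region = region, match = config$match,
                             mismatch = config$mismatch, gap = config$gap)
  tree <- neighbor_joining(d)
  paths <- list(newick = file.path(config$out_dir, "tree.nwk"))
  write_newick(tree, paths$newick)
  write_phylip_dist(d, file.path(config$out_dir, "distances.phylip"))
  if (!is.null(config$metadata) && file.exists(config$metadata)) {
    meta <- read_metadata(config$metadata)
    clades <- setNames(meta$clade, meta$id)
    clades <- clades[!is.na(clades) & nzchar(clades)]
    if (length(clades)) {
      conc <- clade_concordance(tree, clades)
      paths$concordance <- file.path(config$out_dir, "concordance.tsv")
      write.table(attr(conc, "report"), paths$concordance, sep = "\t",
                  quote = FALSE, row.names = FALSE)
      message(sprintf("clade concordance: %.3f", as.numeric(conc)))
    }
  }
  invisible(paths)
}

#' Simulate a synthetic panel to disk
#'
#' @param config named list: `out_dir`, `seed`, and an optional `simulate`
#'   block of [sim_spec()] arguments.
#' @return list of written paths, invisibly.
#' @export
run_simulate <- function(config) {
  config <- resolve_config(config)
  args <- if (is.null(config$simulate)) list() else config$simulate
  if (!is.null(config$seed)) args$seed <- config$seed
  spec <- tryCatch(do.call(sim_spec, args),
                   error = function(e) usage_error("invalid simulation spec: ",
                                                   conditionMessage(e)))
  sim <- simulate_panel(spec, out_dir = config$out_dir)
  message(sprintf("simulated %d isolates in %d groups (seed %d)",
                  nrow(sim$sequences), length(spec$groups), spec$seed))
  invisible(list(fasta = file.path(config$out_dir, "sequences.fasta"),
                 metadata = file.path(config$out_dir, "metadata.tsv"),
                 truth = file.path(config$out_dir, "ground_truth.tsv"),
                 panel = file.path(config$out_dir, "panel.yaml")))
}
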