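# IUGG mean Earth radius, km
EARTH_RADIUS_KM <- 6371.0088

#' Great-circle distance between two points
#'
#' Haversine distance on a sphere of radius 6371.0088 km (IUGG mean).
#'
#' @param a,b numeric `c(lat, lon)` in decimal degrees.
#' @return distance in km.
#' @export
haversine_km <- function(a, b) {
  geosphere::distHaversine(c(a[2L], a[1L]), c(b[2L], b[1L]), r = EARTH_RADIUS_KM)
}

#' Filter isolates by origin annotation
#'
#' Selects isolate ids whose `origin_class` is in `origin` (when given) and,
#' when `exclude_deleted` is set, whose marker gene was not deliberately
#' deleted during strain construction.
#'
#' @param meta `isolate_meta` data frame.
#' @param origin optional character set of origin classes (e.g. `"Nature"`).
#' @param exclude_deleted drop isolates flagged `ho_deleted`.
#' @return character vector of ids.
#' @export
filter_isolates <- function(meta, origin = NULL, exclude_deleted = FALSE) {
  keep <- rep(TRUE, nrow(meta))
  if (!is.null(origin)) keep <- keep & meta$origin_class %in% origin
  if (exclude_deleted) keep <- keep & !meta$ho_deleted
  meta$id[keep]
}

#' Partition typed isolates into allele groups
#'
#' Isolates share a group exactly when their composite genotype keys are
#' identical.  Only typable isolates are grouped; untypable ones are
#' reported separately in the `untypable` attribute.  Groups are ordered by
#' size (descending), then key (lexicographic), for reproducible output.
#'
#' @param genotypes named list of `composite_genotype` (see [type_panel()]).
#' @param include optional character vector restricting the isolate ids
#'   considered (e.g. from [filter_isolates()]).
#' @return list of class `allele_groups`; each element has `key` and
#'   `member_ids`, plus dispersal fields filled by [group_dispersal()].
#'   Attribute `untypable` lists excluded untypable ids.
#' @export
build_groups <- function(genotypes, include = NULL) {
  ids <- names(genotypes)
  if (!is.null(include)) ids <- intersect(ids, include)
  typable <- vapply(genotypes[ids], `[[`, logical(1), "typable")
  untypable <- ids[!typable]
  ids <- ids[typable]
  keys <- vapply(genotypes[ids], `[[`, character(1), "key")
  by_key <- split(ids, keys)
  groups <- lapply(names(by_key), function(k) {
    structure(list(key = k, member_ids = by_key[[k]],
                   location_counts = NULL, n_locations = NA_integer_,
                   max_pairwise_km = NA_real_, mean_pairwise_km = NA_real_),
              class = "allele_group")
  })
  sizes <- vapply(groups, function(g) length(g$member_ids), integer(1))
  ord <- order(-sizes, names(by_key))
  structure(groups[ord], class = "allele_groups", untypable = untypable)
}

#' Fill geographic dispersal statistics for one allele group
#'
#' Computes all pairwise haversine distances between members with
#' coordinates, the per-location member counts (locations identified by
#' `location_name`, mirroring per-location map pins), and the number of
#' distinct locations.  Members without coordinates are counted in
#' `n_unlocated` and excluded from the distances.
#'
#' @param group an `allele_group` from [build_groups()].
#' @param meta `isolate_meta` data frame.
#' @return the group with `location_counts`, `n_locations`,
#'   `max_pairwise_km`, `mean_pairwise_km` and `n_unlocated` filled.
#' @export
group_dispersal <- function(group, meta) {
  m <- meta[match(group$member_ids, meta$id), , drop = FALSE]
  located <- which(!is.na(m$lat) & !is.na(m$lon))
  group$n_unlocated <- length(group$member_ids) - length(located)
  if (!length(located)) {
    warning("group '", group$key, "' has no members with coordinates", call. = FALSE)
    return(group)
  }
  loc <- m[located, , drop = FALSE]
  group$location_counts <- table(loc$location_name)
  group$n_locations <- length(group$location_counts)
  if (length(located) == 1L) {
    group$max_pairwise_km <- 0
    group$mean_pairwise_km <- 0
  } else {
    pairs <- combn(length(located), 2L)
    dists <- apply(pairs, 2L, function(p) {
      haversine_km(c(loc$lat[p[1L]], loc$lon[p[1L]]),
                   c(loc$lat[p[2L]], loc$lon[p[2L]]))
    })
    group$max_pairwise_km <- max(dists)
    group$mean_pairwise_km <- mean(dists)
  }
  group
}

#' Export allele groups as GeoJSON
#'
#' One Point feature per (group, location), with properties `group`
#' (composite key), `location` and `count` (members of that group at that
#' location).  Feature coordinates are the mean of the member coordinates
#' sharing the location name; true coordinates are used, never repositioned
#' for legibility.
#'
#' @param groups `allele_groups` (after [group_dispersal()] or not).
#' @param meta `isolate_meta`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_geojson <- function(groups, meta, path) {
  features <- list()
  for (g in groups) {
    m <- meta[match(g$member_ids, meta$id), , drop = FALSE]
    m <- m[!is.na(m$lat) & !is.na(m$lon), , drop = FALSE]
    if (!nrow(m)) next
    for (loc in sort(unique(m$location_name))) {
      sub <- m[m$location_name == loc, , drop = FALSE]
      features[[length(features) + 1L]] <- list(
        type = "Feature",
        geometry = list(type = "Point",
                        coordinates = c(mean(sub$lon), mean(sub$lat))),
        properties = list(group = g$key, location = loc, count = nrow(sub)))
    }
  }
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Tabulate allele groups
#'
#' @param groups `allele_groups` with dispersal statistics filled.
#' @return data frame: `key`, `n_members`, `n_locations`,
#'   `max_pairwise_km`, `mean_pairwise_km`, `member_ids` (comma-joined).
#' @export
group_table <- function(groups) {
  if (!length(groups)) {
    return(data.frame(key = character(0), n_members = integer(0),
                      n_locations = integer(0), max_pairwise_km = numeric(0),
                      mean_pairwise_km = numeric(0), member_ids = character(0)))
  }
  data.frame(
    key = vapply(groups, `[[`, character(1), "key"),
    n_members = vapply(groups, function(g) length(g$member_ids), integer(1)),
    n_locations = vapply(groups, `[[`, integer(1), "n_locations"),
    max_pairwise_km = vapply(groups, `[[`, numeric(1), "max_pairwise_km"),
    mean_pairwise_km = vapply(groups, `[[`, numeric(1), "mean_pairwise_km"),
    member_ids = vapply(groups, function(g) paste(g$member_ids, collapse = ","),
                        character(1)),
    stringsAsFactors = FALSE)
}
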