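#' Build a parcel table
#'
#' The parcel table is the package's central container: one row per parcel,
#' with the polygon carried in a `geometry` list-column so the table pipes
#' through `dplyr` like any other tibble.
#'
#' @param geometry List of [pitt_polygon] objects.
#' @param parcel_id Character ids; generated (`p0001`, ...) when missing.
#' @param label Optional character vector of truth labels.
#' @return A tibble with columns `parcel_id`, `geometry`, `label`.
#' @export
parcel_table <- function(geometry, parcel_id = NULL, label = NA_character_) {
  n <- length(geometry)
  if (is.null(parcel_id)) parcel_id <- sprintf("p%04d", seq_len(n))
  if (anyDuplicated(parcel_id)) stop("parcel ids must be unique", call. = FALSE)
  tibble(parcel_id = as.character(parcel_id),
         geometry = geometry,
         label = rep_len(as.character(label), n))
}

geojson_ring <- function(m) {
  m <- rbind(m, m[1, , drop = FALSE])  # close the ring
  lapply(seq_len(nrow(m)), function(i) c(m[i, 1], m[i, 2]))
}

polygon_to_geojson <- function(poly) {
  list(type = "Polygon",
       coordinates = c(list(geojson_ring(poly$outer)),
                       lapply(poly$holes, geojson_ring)))
}

geojson_to_polygon <- function(geom) {
  if (!identical(geom$type, "Polygon"))
    stop("only Polygon geometries are supported, got: ", geom$type, call. = FALSE)
  rings <- lapply(geom$coordinates, function(ring)
    do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]]))))
  pitt_polygon(rings[[1]], rings[-1])
}

#' Read parcels from a GeoJSON FeatureCollection
#'
#' Recognised feature properties: `id`/`parcel_id`, `label`, `scale_level`,
#' `branch`; unknown properties are ignored. Coordinates are taken as planar
#' map units in a single CRS (no reprojection).
#'
#' @param path Path to a GeoJSON file.
#' @return A parcel tibble (see [parcel_table()]).
#' @export
read_parcels_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  if (!identical(fc$type, "FeatureCollection"))
    stop("expected a GeoJSON FeatureCollection", call. = FALSE)
  feats <- fc$features
  geoms <- lapply(feats, function(f) geojson_to_polygon(f$geometry))
  prop <- function(name, default) {
    vapply(feats, function(f) {
      v <- f$properties[[name]]
      if (is.null(v)) default else as.character(v)
    }, character(1))
  }
  ids <- prop("parcel_id", NA_character_)
  alt <- prop("id", NA_character_)
  ids <- ifelse(is.na(ids), alt, ids)
  if (anyNA(ids)) ids[is.na(ids)] <- sprintf("p%04d", which(is.na(ids)))
  out <- parcel_table(geoms, ids, prop("label", NA_character_))
  sl <- suppressWarnings(as.numeric(prop("scale_level", NA_character_)))
  if (!all(is.na(sl))) out$scale_level <- sl
  br <- prop("branch", NA_character_)
  if (!all(is.na(br))) out$branch <- br
  out
}

#' Write a parcel table to GeoJSON
#'
#' Emits `parcel_id`, `label`, and any of `scale_level` and `branch` that the
#' table carries, as feature properties.
#'
#' @param parcels A parcel tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_parcels_geojson <- function(parcels, path) {
  extra <- intersect(c("label", "scale_level", "branch"), names(parcels))
  feats <- lapply(seq_len(nrow(parcels)), function(i) {
    props <- c(list(parcel_id = parcels$parcel_id[i]),
               lapply(setNames(extra, extra), function(cn) parcels[[cn]][i]))
    props <- props[!vapply(props, function(v) is.na(v), TRUE)]
    list(type = "Feature",
         properties = props,
         geometry = polygon_to_geojson(parcels$geometry[[i]]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
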