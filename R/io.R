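# Readers and writers for the pipeline's interchange formats: polygon
# neighborhoods as GeoJSON feature collections, tabular inputs/outputs as
# CSV with schema validation, and YAML run configurations. Coordinates are
# planar meters throughout; float columns are written at full precision.

#' Write neighborhoods to GeoJSON
#'
#' One Polygon feature per neighborhood with id, population and
#' deprivation properties.
#'
#' @param neighborhoods data.table with neighborhood_id, population,
#'   deprivation
#' @param polygons list of closed rings in the same order
#' @param path output file
#' @export
write_neighborhoods_geojson <- function(neighborhoods, polygons, path) {
  nb <- data.table::as.data.table(neighborhoods)
  feats <- lapply(seq_len(nrow(nb)), function(i) {
    ring <- polygons[[i]]
    list(
      type = "Feature",
      properties = list(neighborhood_id = nb$neighborhood_id[i],
                        population = nb$population[i],
                        deprivation = nb$deprivation[i]),
      geometry = list(type = "Polygon",
                      coordinates = list(lapply(seq_len(nrow(ring)),
                                                function(r) ring[r, ]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read neighborhoods from GeoJSON
#'
#' @param path GeoJSON file of Polygon features with neighborhood_id,
#'   population and deprivation properties
#' @return list: `neighborhoods` (data.table with centroid x, y) and
#'   `polygons`
#' @export
read_neighborhoods_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  assert_that(identical(gj$type, "FeatureCollection"),
              "schema error: not a GeoJSON FeatureCollection")
  polys <- vector("list", length(gj$features))
  rows <- vector("list", length(gj$features))
  for (i in seq_along(gj$features)) {
    f <- gj$features[[i]]
    if (!identical(f$geometry$type, "Polygon"))
      stopf("geometry error: feature %d is not a Polygon", i)
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(p) as.numeric(unlist(p))))
    if (nrow(ring) < 4L || any(!is.finite(ring)))
      stopf("geometry error: invalid polygon in feature %d", i)
    if (any(ring[1, ] != ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
    polys[[i]] <- ring
    cen <- polygon_centroid(ring)
    rows[[i]] <- data.table::data.table(
      neighborhood_id = as.integer(f$properties$neighborhood_id),
      x = cen[1], y = cen[2],
      population = as.numeric(f$properties$population %||% NA_real_),
      deprivation = as.numeric(f$properties$deprivation %||% NA_real_))
  }
  list(neighborhoods = data.table::rbindlist(rows), polygons = polys)
}

#' Read an invitation CSV with schema validation
#'
#' Required columns: woman_id, invitation_year, participated (0/1);
#' either x/y coordinates or an address column must be present.
#' @param path CSV file
#' @export
read_invitations_csv <- function(path) {
  inv <- data.table::fread(path)
  need <- c("woman_id", "invitation_year", "participated")
  miss <- setdiff(need, names(inv))
  assert_that(length(miss) == 0L, "schema error: missing columns: %s",
              paste(miss, collapse = ", "))
  bad <- which(!inv$participated %in% c(0L, 1L))
  assert_that(length(bad) == 0L,
              "schema error: participated not in {0,1} at rows: %s",
              paste(utils::head(bad, 5L), collapse = ", "))
  assert_that(all(c("x", "y") %in% names(inv)) || "address" %in% names(inv),
              "schema error: need x/y coordinates or an address column")
  inv
}

#' Write a data.frame to CSV with stable column order
#' @param x table
#' @param path output file
#' @export
write_table_csv <- function(x, path) {
  data.table::fwrite(data.table::as.data.table(x), path)
  invisible(path)
}

#' Read / write a run configuration (YAML)
#'
#' @param path YAML file
#' @return named list of configuration values
#' @export
read_config <- function(path) {
  assert_that(file.exists(path), "missing input path: %s", path)
  yaml::read_yaml(path)
}

#' @rdname read_config
#' @param config named list
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config, tmp)
  unname(tools::md5sum(tmp))
}
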