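HABITAT_LEVELS <- c("nearshore", "offshore")
LAYER_LEVELS <- c("surface", "DCM", "bottom")

#' Validate a sample metadata table
#'
#' Checks the minimal schema used throughout the pipeline: unique sample
#' ids, habitat class and depth layer from their fixed vocabularies, and
#' numeric coordinates.
#'
#' @param metadata data.frame with at least `sample_id`, `station`,
#'   `habitat_class`, `layer`, `latitude`, `longitude`.
#' @return the metadata, invisibly, with ids as character.
#' @export
validate_metadata <- function(metadata) {
  need <- c("sample_id", "station", "habitat_class", "layer",
            "latitude", "longitude")
  miss <- setdiff(need, names(metadata))
  if (length(miss)) stop_invalid("metadata missing column(s): ",
                                 paste(miss, collapse = ", "))
  metadata$sample_id <- as.character(metadata$sample_id)
  if (anyDuplicated(metadata$sample_id)) stop_invalid("duplicate sample ids")
  if (!all(metadata$habitat_class %in% HABITAT_LEVELS))
    stop_invalid("habitat_class must be one of: ",
                 paste(HABITAT_LEVELS, collapse = ", "))
  if (!all(metadata$layer %in% LAYER_LEVELS))
    stop_invalid("layer must be one of: ", paste(LAYER_LEVELS, collapse = ", "))
  invisible(metadata)
}

#' Read / write sample metadata as TSV
#' @param path file path.
#' @return data.frame of metadata.
#' @export
read_metadata <- function(path) {
  md <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  validate_metadata(md)
  md
}

#' @rdname read_metadata
#' @param metadata metadata data.frame.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Great-circle distances between samples
#'
#' Haversine formula on a sphere of radius 6371 km, applied to the
#' latitude/longitude columns of the metadata.
#'
#' @param metadata metadata data.frame with `latitude` and `longitude` in
#'   decimal degrees.
#' @return symmetric sample x sample matrix of distances in km.
#' @export
geographic_distance <- function(metadata) {
  lat <- metadata$latitude
  lon <- metadata$longitude
  if (is.null(lat) || is.null(lon) || any(!is.finite(lat)) ||
      any(!is.finite(lon)))
    stop_invalid("metadata must have finite latitude/longitude")
  R <- 6371
  phi <- lat * pi / 180
  lam <- lon * pi / 180
  n <- length(lat)
  dphi <- outer(phi, phi, "-")
  dlam <- outer(lam, lam, "-")
  a <- sin(dphi / 2)^2 + outer(cos(phi), cos(phi)) * sin(dlam / 2)^2
  a <- pmin(pmax(a, 0), 1)
  d <- 2 * R * asin(sqrt(a))
  diag(d) <- 0
  ids <- if (!is.null(metadata$sample_id)) metadata$sample_id
         else as.character(seq_len(n))
  dimnames(d) <- list(ids, ids)
  d
}

#' Pairwise absolute-difference distance of a numeric variable
#'
#' One-dimensional Euclidean distance, used for temperature and depth
#' dissimilarity matrices.
#'
#' @param values numeric vector (one value per sample).
#' @param ids optional names.
#' @return symmetric matrix of `|x_i - x_j|`.
#' @export
euclidean_distance_1d <- function(values, ids = names(values)) {
  if (!is.numeric(values)) stop_invalid("values must be numeric")
  d <- abs(outer(values, values, "-"))
  if (!is.null(ids)) dimnames(d) <- list(ids, ids)
  d
}
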