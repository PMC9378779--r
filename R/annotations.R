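# Compartment annotations: labelled polygons partitioning a section.

#' Construct a compartment annotation
#'
#' Wraps manually delineated (or synthetic) region polygons with their
#' compartment labels. Region order is meaningful: it is the file order used
#' to break containment ties for points on shared boundaries.
#'
#' @param label character vector of compartment labels, drawn from the closed
#'   vocabulary `airway_epithelium`, `airway_subepithelium`,
#'   `pulmonary_vessel`, `alveolar_parenchyma`, `excluded`.
#' @param polygon list of polygon matrices (x, y in micrometres), same length
#'   as `label`. Polygons must be simple and have positive area.
#' @param section_id identifier of the annotated section.
#' @return A tibble of class `compartment_annotation` with columns `label`
#'   and `polygon` (list-column), and attribute `section_id`.
#' @export
compartment_annotation <- function(label, polygon, section_id = "section") {
  if (length(label) != length(polygon)) {
    abort("label and polygon must have the same length")
  }
  bad <- setdiff(unique(label), compartment_vocab())
  if (length(bad)) {
    abort(sprintf("unknown compartment label(s): %s (allowed: %s)",
                  paste(bad, collapse = ", "),
                  paste(compartment_vocab(), collapse = ", ")),
          class = "mastmap_vocab_error")
  }
  polygon <- lapply(polygon, as_polygon)
  for (i in seq_along(polygon)) {
    if (!polygon_is_simple(polygon[[i]])) {
      abort(sprintf("region %d ('%s') is self-intersecting", i, label[i]),
            class = "mastmap_validation_error")
    }
    if (polygon_area(polygon[[i]]) <= 0) {
      abort(sprintf("region %d ('%s') has zero area", i, label[i]),
            class = "mastmap_validation_error")
    }
  }
  out <- tibble::tibble(label = as.character(label), polygon = polygon)
  class(out) <- c("compartment_annotation", class(out))
  attr(out, "section_id") <- as.character(section_id)
  out
}

#' Read compartment annotations from GeoJSON
#'
#' Expects a `FeatureCollection` of `Polygon` features, each carrying a
#' `compartment` property from the closed label vocabulary. Coordinates are
#' interpreted as micrometres in image coordinates (x rightward, y downward).
#' Only the outer ring of each polygon is used.
#'
#' @param path path to a GeoJSON file.
#' @return A [compartment_annotation()].
#' @export
load_annotations <- function(path) {
  if (!file.exists(path)) abort(sprintf("annotation file not found: %s", path))
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection")) {
    abort("expected a GeoJSON FeatureCollection", class = "mastmap_format_error")
  }
  labels <- character(0)
  polys <- list()
  for (feat in gj$features) {
    if (!identical(feat$geometry$type, "Polygon")) {
      abort("all features must have Polygon geometry", class = "mastmap_format_error")
    }
    lab <- feat$properties$compartment
    if (is.null(lab)) {
      abort("every feature needs a 'compartment' property",
            class = "mastmap_vocab_error")
    }
    ring <- feat$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
    labels <- c(labels, lab)
    polys <- c(polys, list(m))
  }
  section_id <- gj$properties$section_id %||% basename(path)
  compartment_annotation(labels, polys, section_id = section_id)
}

#' Write compartment annotations to GeoJSON
#'
#' @param annotation a [compartment_annotation()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_annotations <- function(annotation, path) {
  stopifnot(inherits(annotation, "compartment_annotation"))
  features <- purrr::map2(annotation$label, annotation$polygon, function(lab, poly) {
    ring <- lapply(seq_len(nrow(poly)), function(i) c(poly[i, 1], poly[i, 2]))
    ring <- c(ring, ring[1]) # close the ring, per GeoJSON
    list(type = "Feature",
         properties = list(compartment = lab),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  gj <- list(type = "FeatureCollection",
             properties = list(section_id = attr(annotation, "section_id")),
             features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Region areas of an annotation
#'
#' @param annotation a [compartment_annotation()].
#' @param effective if `TRUE` (default), carve nested regions out of their
#'   parents so the areas sum to the territory each region actually owns;
#'   if `FALSE`, return raw polygon areas.
#' @return Tibble with columns `label` and `area_um2` (one row per region).
#' @export
annotation_areas <- function(annotation, effective = TRUE) {
  a <- if (effective) region_effective_areas(annotation)
       else vapply(annotation$polygon, polygon_area, numeric(1))
  tibble::tibble(label = annotation$label, area_um2 = a)
}

#' @export
print.compartment_annotation <- function(x, ...) {
  cat(sprintf("<compartment_annotation> '%s': %d regions (%s)\n",
              attr(x, "section_id"), nrow(x),
              paste(unique(x$label), collapse = ", ")))
  invisible(x)
}
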