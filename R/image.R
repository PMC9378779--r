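# Multichannel fluorescence images.

IMAGE_CHANNELS <- c("nuclei", "mrna", "protein", "tryptase")

#' Construct a multiplex fluorescence image
#'
#' Bundles the four acquisition channels of the staining panel — DAPI nuclei,
#' Cy3-type CPA3 mRNA (RNAscope), Cy5-type CPA3 protein, and the combined
#' tryptase lineage channel — with the physical pixel size.
#'
#' @param channels named list of numeric matrices; names must include
#'   `nuclei`, `mrna`, `protein`, `tryptase`; all matrices share dimensions,
#'   with finite non-negative intensities (arbitrary fluorescence units).
#' @param pixel_size_um micrometres per pixel edge (> 0).
#' @param source_id free-text identifier of the source slide/section.
#' @return An object of class `multiplex_image`.
#' @export
multiplex_image <- function(channels, pixel_size_um, source_id = "image") {
  missing <- setdiff(IMAGE_CHANNELS, names(channels))
  if (length(missing)) {
    abort(sprintf("missing channel(s): %s", paste(missing, collapse = ", ")),
          class = "mastmap_config_error")
  }
  channels <- channels[IMAGE_CHANNELS]
  dims <- unique(lapply(channels, dim))
  if (length(dims) != 1) {
    abort("all channel grids must share identical dimensions",
          class = "mastmap_format_error")
  }
  for (nm in IMAGE_CHANNELS) {
    ch <- channels[[nm]]
    if (!is.matrix(ch) || !is.numeric(ch)) {
      abort(sprintf("channel '%s' must be a numeric matrix", nm))
    }
    if (anyNA(ch) || any(!is.finite(ch)) || any(ch < 0)) {
      abort(sprintf("channel '%s' must be finite and >= 0", nm))
    }
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0) {
    abort("pixel_size_um must be a single number > 0")
  }
  structure(
    list(channels = channels, pixel_size_um = pixel_size_um,
         source_id = as.character(source_id)),
    class = "multiplex_image"
  )
}

#' @export
print.multiplex_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<multiplex_image> '%s': %d x %d px, %.3g um/px, channels: %s\n",
              x$source_id, d[1], d[2], x$pixel_size_um,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Load a multichannel grayscale TIFF
#'
#' Reads a single- or multi-page grayscale TIFF and maps pages to the named
#' channels. Pixel size comes from the caller (config), not from TIFF
#' metadata, so OME-XML dialect differences cannot silently change physical
#' units. Integer pages are preserved bit-exactly.
#'
#' @param path path to the TIFF file.
#' @param channel_map named integer vector mapping each required channel name
#'   to a 1-based page index, e.g. `c(nuclei = 1, mrna = 2, protein = 3,
#'   tryptase = 4)` (the default).
#' @param pixel_size_um micrometres per pixel edge.
#' @param source_id identifier stored on the image; defaults to the file name.
#' @return A [multiplex_image()].
#' @export
load_image <- function(path,
                       channel_map = c(nuclei = 1, mrna = 2, protein = 3, tryptase = 4),
                       pixel_size_um,
                       source_id = basename(path)) {
  if (!file.exists(path)) abort(sprintf("image file not found: %s", path))
  missing <- setdiff(IMAGE_CHANNELS, names(channel_map))
  if (length(missing)) {
    abort(sprintf("channel_map is missing: %s", paste(missing, collapse = ", ")),
          class = "mastmap_config_error")
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(channel_map < 1 | channel_map > length(pages))) {
    abort(sprintf("channel_map indexes pages outside 1..%d", length(pages)),
          class = "mastmap_config_error")
  }
  chans <- lapply(channel_map[IMAGE_CHANNELS], function(i) {
    pg <- pages[[i]]
    if (length(dim(pg)) == 3) {
      abort("expected grayscale pages, found a multi-sample (colour) page",
            class = "mastmap_format_error")
    }
    m <- as.matrix(pg)
    storage.mode(m) <- "double"
    m
  })
  dims <- unique(lapply(chans, dim))
  if (length(dims) != 1) {
    abort("mapped planes have mismatched dimensions", class = "mastmap_format_error")
  }
  multiplex_image(chans, pixel_size_um = pixel_size_um, source_id = source_id)
}

#' Save a multiplex image as a multi-page 16-bit grayscale TIFF
#'
#' Channels are written in the fixed order nuclei, mrna, protein, tryptase as
#' unsigned 16-bit pages — the native representation of fluorescence slide
#' scanners. Intensities must therefore be integer-valued in `[0, 65535]`
#' (the synthetic generator emits integer AU); they round-trip bit-exactly
#' through [load_image()].
#'
#' @param image a [multiplex_image()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_image <- function(image, path) {
  stopifnot(inherits(image, "multiplex_image"))
  for (nm in IMAGE_CHANNELS) {
    ch <- image$channels[[nm]]
    if (any(ch != round(ch)) || any(ch > 65535)) {
      abort(sprintf(
        "channel '%s' must hold integers in [0, 65535] for 16-bit storage", nm),
        class = "mastmap_format_error")
    }
  }
  tiff::writeTIFF(lapply(image$channels[IMAGE_CHANNELS], function(ch) ch / 65535),
                  path, bits.per.sample = 16, reduce = FALSE)
  invisible(path)
}
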