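#' Read a single- or multi-page TIFF as an image stack
#'
#' Each TIFF page becomes one z-slice. Voxel spacing is taken from the TIFF
#' resolution tags (`dx = 1/XResolution`, `dy = 1/YResolution`) and, for the
#' z-step, from an ImageJ-style `spacing=` entry in the ImageDescription tag,
#' when present. If no spacing metadata is found the stack defaults to
#' isotropic `(1, 1, 1)` with a warning, so purely synthetic images work.
#'
#' @param path path to a readable single- or multi-page grayscale TIFF.
#' @param spacing optional numeric length-3 override `(dx, dy, dz)`; when
#'   given, metadata is ignored.
#' @param name component identifier; defaults to the file name without
#'   extension.
#' @return An [image_stack()] with z-extent equal to the page count.
#' @seealso [write_stack()]
#' @export
read_stack <- function(path, spacing = NULL, name = NULL) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop_io(sprintf("cannot read TIFF: '%s' does not exist", path))
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE),
                    error = function(e) stop_io(sprintf("unreadable TIFF '%s': %s",
                                                        path, conditionMessage(e))))
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) > 2L, logical(1))))
    stop_input(paste0("'", path, "' contains multi-channel (RGB) pages; ",
                      "split channels into one binary mask per component first"))
  info <- attributes(pages[[1]])
  bits <- if (!is.null(info$bits.per.sample)) info$bits.per.sample else 8L
  scale <- if (bits > 8L) 2^bits - 1 else 255
  vox <- vapply(pages, function(p) t(round(p * scale)), matrix(0, ncol(pages[[1]]), nrow(pages[[1]])))
  dim(vox) <- c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages))
  if (max(vox) > 255)
    stop_input(sprintf("'%s' holds %d-bit values above 255; only 8-bit value range is supported", path, bits))
  if (is.null(spacing)) {
    spacing <- .spacing_from_tags(info)
    if (is.null(spacing)) {
      warning("no voxel-spacing metadata in '", path,
              "'; assuming isotropic spacing (1, 1, 1)", call. = FALSE)
      spacing <- c(1, 1, 1)
    }
  }
  if (is.null(name))
    name <- tools::file_path_sans_ext(basename(path))
  image_stack(vox, spacing = spacing, name = name)
}

.spacing_from_tags <- function(info) {
  xres <- info$x.resolution
  if (is.null(xres) || !is.finite(xres) || xres <= 0) return(NULL)
  dx <- 1 / xres
  yres <- info$y.resolution
  dy <- if (!is.null(yres) && is.finite(yres) && yres > 0) 1 / yres else dx
  dz <- dx
  desc <- info$description
  if (!is.null(desc)) {
    m <- regmatches(desc, regexec("spacing=([0-9.eE+-]+)", desc))[[1]]
    if (length(m) == 2) {
      z <- suppressWarnings(as.numeric(m[2]))
      if (is.finite(z) && z > 0) dz <- z
    }
  }
  c(dx, dy, dz)
}

#' Write an image stack as a multi-page 8-bit TIFF
#'
#' Writes one uncompressed grayscale page per z-slice;
#' `read_stack(write_stack(s, f))` reproduces the voxel grid bit-exactly.
#' Voxel spacing is not embedded in the file; pass it explicitly when
#' re-reading.
#'
#' @param stack an [image_stack()] (values 0..255).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  assert_stack(stack)
  d <- dim(stack$voxels)
  pages <- lapply(seq_len(d[3]), function(z) t(stack$voxels[, , z]) / 255)
  ok <- tryCatch(tiff::writeTIFF(pages, path, bits.per.sample = 8L,
                                 compression = "none", reduce = FALSE),
                 error = function(e) stop_io(sprintf("cannot write TIFF '%s': %s",
                                                     path, conditionMessage(e))))
  invisible(path)
}
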