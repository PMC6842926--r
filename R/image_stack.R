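#' Voxel image stack with physical spacing
#'
#' The unit of input for the whole pipeline: a 3D integer voxel grid indexed
#' `(x, y, z)` plus the physical edge lengths of one voxel. A 2D image is the
#' degenerate case with z-extent 1. Binary masks use the 8-bit convention
#' foreground = 255, background = 0.
#'
#' @param voxels integer array; a matrix is promoted to a single-slice stack.
#'   Values must lie in 0..255 (8-bit).
#' @param spacing numeric length-3, physical size `(dx, dy, dz)` of one voxel
#'   in consistent (arbitrary) units; all components must be positive.
#' @param name identifier for the cellular component the stack represents.
#' @return An object of class `ImageStack`: a list with elements `voxels`
#'   (3D integer array), `spacing` and `name`.
#' @examples
#' s <- image_stack(array(c(0L, 255L), c(2, 1, 1)), name = "Cyt")
#' dim(s$voxels)
#' @export
image_stack <- function(voxels, spacing = c(1, 1, 1), name = "mask") {
  if (is.matrix(voxels)) dim(voxels) <- c(dim(voxels), 1L)
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop_input("'voxels' must be a 3D array (or a matrix for a 2D image)")
  if (any(dim(voxels) < 1L)) stop_input("all extents must be >= 1")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop_input("'spacing' must be 3 positive numbers (dx, dy, dz)")
  storage.mode(voxels) <- "integer"
  if (anyNA(voxels) || min(voxels) < 0L || max(voxels) > 255L)
    stop_input("voxel values must be integers in 0..255 (8-bit)")
  structure(list(voxels = voxels, spacing = spacing, name = as.character(name)),
            class = "ImageStack")
}

#' @export
print.ImageStack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("ImageStack '%s': %d x %d x %d voxels, spacing (%g, %g, %g)\n",
              x$name, d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  vals <- sort(unique(as.vector(x$voxels)))
  if (length(vals) > 8) vals <- c(utils::head(vals, 8), "...")
  cat("  values:", paste(vals, collapse = " "), "\n")
  invisible(x)
}

#' Test or assert that a stack is a binary mask
#'
#' A binary mask contains only the values 0 (background) and 255 (foreground).
#'
#' @param stack an [image_stack()].
#' @return `is_binary` returns a logical scalar.
#' @export
is_binary <- function(stack) {
  all(stack$voxels == 0L | stack$voxels == 255L)
}

assert_stack <- function(stack, arg = "stack") {
  if (!inherits(stack, "ImageStack"))
    stop_input(sprintf("'%s' must be an ImageStack (see image_stack())", arg))
  invisible(stack)
}

assert_binary <- function(stack, arg = "stack") {
  assert_stack(stack, arg)
  if (!is_binary(stack))
    stop_input(sprintf("'%s' must be a binary mask (values 0/255); run ensure_binary() first", arg))
  invisible(stack)
}

#' Normalize a stack to a strict 0/255 binary mask
#'
#' Any nonzero voxel becomes foreground (255); zero voxels stay background.
#' Idempotent, and the zero set is preserved exactly.
#'
#' @param stack an [image_stack()].
#' @return A binary `ImageStack`.
#' @examples
#' s <- image_stack(array(c(0L, 1L, 17L, 255L), c(4, 1, 1)))
#' as.vector(ensure_binary(s)$voxels)
#' @export
ensure_binary <- function(stack) {
  assert_stack(stack)
  v <- stack$voxels
  v[v != 0L] <- 255L
  stack$voxels <- v
  stack
}

# logical foreground mask
fg <- function(stack) stack$voxels != 0L

same_extents <- function(a, b) identical(dim(a$voxels), dim(b$voxels))
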