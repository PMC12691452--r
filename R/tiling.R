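# Tile-grid computation, tile extraction, brightness filtering and Lanczos
# downscaling: the downscaled-patch-sampling stage between a raw WSI and
# the MIL bags.

#' Compute a tile grid over an image
#'
#' Non-overlapping mode (`overlap = 0`) covers the image with
#' `floor(W / tile_w) x floor(H / tile_h)` full tiles; partial edge tiles
#' are discarded, so a 16,000 x 16,000 image yields 31 x 31 = 961 tiles of
#' 512 x 512. Overlapping mode steps by `tile - overlap` pixels on each
#' axis and clamps the last origin so the final tile still fits inside the
#' image. Coordinates are 0-based, half-open, enumerated row-major by
#' (y, x).
#'
#' @param width,height image dimensions in pixels.
#' @param tile_w,tile_h tile dimensions (default 512 square).
#' @param overlap overlap between consecutive tiles in pixels (0 =
#'   non-overlapping; must be < tile size otherwise).
#' @return a `tile_grid` list: `width`, `height`, `tile_w`, `tile_h`,
#'   `stride_x`, `stride_y`, `nh`, `nv`, `n_tiles`, and `origins` (a data
#'   frame of top-left x, y). An image smaller than one tile gives an
#'   empty grid, not an error.
#' @export
tile_grid <- function(width, height, tile_w = 512, tile_h = tile_w, overlap = 0) {
  stopifnot_scalar_number(width, "width", positive = TRUE)
  stopifnot_scalar_number(height, "height", positive = TRUE)
  stopifnot_scalar_number(tile_w, "tile_w", positive = TRUE)
  stopifnot_scalar_number(tile_h, "tile_h", positive = TRUE)
  if (overlap < 0 || overlap >= min(tile_w, tile_h)) {
    if (overlap != 0) stop("`overlap` must be in [0, tile size)", call. = FALSE)
  }
  axis_origins <- function(extent, tile, step, clamp_last) {
    if (extent < tile) return(integer(0))
    xs <- seq.int(0L, extent - tile, by = step)
    # overlapping mode clamps a final origin so the last tile reaches the
    # image edge; non-overlapping mode discards the partial edge strip
    if (clamp_last && xs[length(xs)] != extent - tile) xs <- c(xs, extent - tile)
    xs
  }
  step_x <- if (overlap > 0) tile_w - overlap else tile_w
  step_y <- if (overlap > 0) tile_h - overlap else tile_h
  xs <- axis_origins(width, tile_w, step_x, clamp_last = overlap > 0)
  ys <- axis_origins(height, tile_h, step_y, clamp_last = overlap > 0)
  origins <- if (length(xs) && length(ys)) {
    data.frame(x = rep(xs, times = length(ys)), y = rep(ys, each = length(xs)))
  } else {
    data.frame(x = integer(0), y = integer(0))
  }
  structure(list(width = width, height = height, tile_w = tile_w, tile_h = tile_h,
                 stride_x = step_x, stride_y = step_y,
                 nh = length(xs), nv = length(ys),
                 n_tiles = nrow(origins), origins = origins),
            class = "tile_grid")
}

#' @export
print.tile_grid <- function(x, ...) {
  cat(sprintf("tile_grid: %dx%d image, %dx%d tiles, stride (%d, %d): %d x %d = %d tiles\n",
              x$width, x$height, x$tile_w, x$tile_h, x$stride_x, x$stride_y,
              x$nh, x$nv, x$n_tiles))
  invisible(x)
}

#' Extract the tiles of a grid from an image
#'
#' One tile per grid origin, in the grid's row-major (y, x) order, with the
#' grayscale mean intensity precomputed for the brightness filter.
#'
#' @param img H x W x 3 array in \[0, 255\].
#' @param grid a [tile_grid()] whose dimensions match `img`.
#' @param image_id optional source identifier carried on each tile.
#' @return list of `wsi_tile` objects: `image_id`, `x`, `y`, `pixels`
#'   (tile_h x tile_w x 3), `mean_intensity`, `kept` (NA until filtered).
#' @export
extract_tiles <- function(img, grid, image_id = NA_character_) {
  d <- dim(img)
  if (d[1] != grid$height || d[2] != grid$width) {
    stop(sprintf("image is %dx%d but grid expects %dx%d (width x height)",
                 d[2], d[1], grid$width, grid$height), call. = FALSE)
  }
  lapply(seq_len(grid$n_tiles), function(i) {
    x <- grid$origins$x[i]; y <- grid$origins$y[i]
    px <- img[(y + 1):(y + grid$tile_h), (x + 1):(x + grid$tile_w), , drop = FALSE]
    # unweighted channel mean of the grayscale conversion == overall pixel
    # mean; computed directly so threshold boundaries are exact
    structure(list(image_id = image_id, x = x, y = y, pixels = px,
                   mean_intensity = mean(px), kept = NA),
              class = "wsi_tile")
  })
}

#' Brightness filter for black/empty tiles
#'
#' Keeps exactly the tiles whose grayscale mean intensity is at or above
#' the threshold; tiles with mean strictly below it (near-black artifacts,
#' empty slide regions after inversion, pen marks) are dropped. Input order
#' is preserved and every input tile's `kept` flag is recorded in the
#' `"kept"` attribute of the result.
#'
#' @param tiles list of tiles from [extract_tiles()].
#' @param threshold intensity threshold in \[0, 255\] (default 25; a tile
#'   with mean exactly 25 is kept).
#' @return the kept tiles (each with `kept = TRUE`), with attribute
#'   `"kept"`: the logical flag vector over the input tiles.
#' @export
brightness_filter <- function(tiles, threshold = 25) {
  if (threshold < 0 || threshold > 255) stop("`threshold` must be in [0, 255]", call. = FALSE)
  means <- vapply(tiles, function(t) t$mean_intensity, numeric(1))
  flags <- means >= threshold
  kept <- lapply(which(flags), function(i) {
    t <- tiles[[i]]
    t$kept <- TRUE
    t
  })
  structure(kept, kept = flags)
}

#' Downscale a tile with Lanczos resampling
#'
#' The controlled-resolution-reduction step: a kept tile (512 x 512 by
#' default upstream) is reduced to `target x target` pixels, a
#' `(tile_w * tile_h) / target^2`-fold pixel and memory reduction (4x for
#' 512 to 256).
#'
#' @param tile a `wsi_tile` or a plain H x W x 3 array.
#' @param target output side length in pixels (must be positive and at
#'   most the tile side).
#' @return the same kind of object with `target x target x 3` pixels;
#'   `mean_intensity` is recomputed for tile objects.
#' @export
downscale_tile <- function(tile, target = 256) {
  stopifnot_scalar_number(target, "target", positive = TRUE)
  px <- if (inherits(tile, "wsi_tile")) tile$pixels else tile
  d <- dim(px)
  if (target > d[1] || target > d[2]) {
    stop(sprintf("target %d exceeds tile dimensions %dx%d", target, d[2], d[1]), call. = FALSE)
  }
  out <- resize_lanczos(px, target, target)
  if (inherits(tile, "wsi_tile")) {
    tile$pixels <- out
    tile$mean_intensity <- mean(out)
    tile
  } else {
    out
  }
}

#' Per-class tile accounting
#'
#' With a fixed bag size, each slide contributes exactly `bag_size`
#' instances, so the tile count per class is `WSI count x bag size`.
#'
#' @param class_wsi_counts named non-negative integer vector (class ->
#'   number of WSIs).
#' @param bag_size instances per bag (default 50).
#' @return list with `per_class` (data frame: class, wsi_count,
#'   tile_count) and `total` (total tile count).
#' @export
tile_accounting <- function(class_wsi_counts, bag_size = 50) {
  if (any(class_wsi_counts < 0)) stop("counts must be non-negative", call. = FALSE)
  df <- data.frame(class = names(class_wsi_counts) %||% character(0),
                   wsi_count = as.integer(class_wsi_counts),
                   tile_count = as.integer(class_wsi_counts) * as.integer(bag_size),
                   row.names = NULL)
  list(per_class = df, total = sum(df$tile_count))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tile one WSI end to end
#'
#' Composes the tiling stage: grid computation, extraction, brightness
#' filtering, Lanczos downscaling. Returns the kept, downscaled tiles plus
#' a per-tile manifest.
#'
#' @param img H x W x 3 array in \[0, 255\].
#' @param image_id source identifier.
#' @param tile_size tile side in pixels (default 512).
#' @param downscale target side after Lanczos reduction (default 256);
#'   `NULL` skips downscaling.
#' @param threshold brightness threshold (default 25).
#' @param overlap tile overlap in pixels (default 0 = non-overlapping).
#' @return list with `tiles` (kept, downscaled), `manifest` (data frame:
#'   image_id, x, y, mean_intensity, kept over all grid tiles), and the
#'   `grid`.
#' @export
tile_wsi <- function(img, image_id = "wsi", tile_size = 512, downscale = 256,
                     threshold = 25, overlap = 0) {
  grid <- tile_grid(dim(img)[2], dim(img)[1], tile_size, tile_size, overlap)
  tiles <- extract_tiles(img, grid, image_id)
  kept <- brightness_filter(tiles, threshold)
  flags <- attr(kept, "kept")
  manifest <- data.frame(image_id = image_id,
                         x = grid$origins$x, y = grid$origins$y,
                         mean_intensity = vapply(tiles, `[[`, numeric(1), "mean_intensity"),
                         kept = flags, row.names = NULL)
  if (!is.null(downscale)) kept <- lapply(kept, downscale_tile, target = downscale)
  list(tiles = kept, manifest = manifest, grid = grid)
}
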