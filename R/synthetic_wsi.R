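# Deterministic synthetic multi-center WSI generator. Each image has a
# near-white background, planted class-specific texture regions, optional
# near-black artifact regions, and a per-domain stain perturbation, so the
# tiling, bagging, training and domain-evaluation stages can all be
# exercised without any real slide.

# Per-class procedural texture family: each histotype gets a distinct base
# chromatin-like color plus a sinusoidal stripe pattern whose frequency and
# orientation are indexed by the class, and a dot lattice of class-specific
# spacing. Only statistical separability of the five families matters; no
# attempt at nucleus-level realism is made.
class_texture_params <- function(label) {
  idx <- match(label, histotype_classes())
  if (is.na(idx)) stop(sprintf("unknown class label '%s'", label), call. = FALSE)
  base_cols <- rbind(
    CC   = c(208, 152, 188),
    MC   = c(182, 138, 204),
    LGSC = c(216, 132, 158),
    HGSC = c(162, 118, 176),
    EC   = c(196, 168, 146))
  list(idx = idx,
       base = base_cols[idx, ],
       freq = 3 + 2.5 * idx,          # stripe cycles per 256 px
       theta = (idx - 1) * pi / 5,    # stripe orientation
       dot_period = 12 + 6 * idx)     # dot lattice spacing, px
}

#' Specification of one synthetic WSI
#'
#' @param width,height image dimensions in pixels (positive integers).
#' @param label histotype class, one of [histotype_classes()].
#' @param domain_id integer institutional domain the slide belongs to.
#' @param informative_fraction fraction of the image area carrying the
#'   class texture (the "tissue" signal), in \[0, 1\].
#' @param artifact_fraction fraction of the image area covered by
#'   near-black artifact regions, in \[0, 1\];
#'   `informative_fraction + artifact_fraction` must not exceed 1.
#' @param hue_delta stain hue rotation in degrees applied to tissue pixels
#'   (emulates inter-center staining differences).
#' @param sat_scale stain saturation scaling factor (positive).
#' @param seed integer seed; the generated image is a pure function of the
#'   spec.
#' @param cell alignment cell size in pixels for planted artifact regions
#'   (default 512, clipped to the image).
#' @param informative_cell alignment cell size for planted informative
#'   texture regions (default `cell / 4`, giving fine fraction
#'   granularity; setting it equal to the downstream tile size makes
#'   informative tiles wholly informative, the sparse-instance MIL
#'   regime).
#' @return a `wsi_spec` list.
#' @export
wsi_spec <- function(width, height, label, domain_id = 1L,
                     informative_fraction = 0.3, artifact_fraction = 0.05,
                     hue_delta = 0, sat_scale = 1, seed = 1, cell = 512,
                     informative_cell = NULL) {
  stopifnot_scalar_number(width, "width", positive = TRUE)
  stopifnot_scalar_number(height, "height", positive = TRUE)
  if (width != round(width) || height != round(height)) {
    stop("width and height must be whole pixel counts", call. = FALSE)
  }
  if (informative_fraction < 0 || informative_fraction > 1) {
    stop("`informative_fraction` must be in [0, 1]", call. = FALSE)
  }
  if (artifact_fraction < 0 || artifact_fraction > 1) {
    stop("`artifact_fraction` must be in [0, 1]", call. = FALSE)
  }
  if (informative_fraction + artifact_fraction > 1) {
    stop("informative_fraction + artifact_fraction must not exceed 1", call. = FALSE)
  }
  stopifnot_scalar_number(sat_scale, "sat_scale", positive = TRUE)
  if (!is.null(informative_cell) && informative_cell > cell) {
    stop("`informative_cell` must not exceed `cell`", call. = FALSE)
  }
  class_texture_params(label)  # validates the label
  structure(list(width = as.integer(width), height = as.integer(height),
                 label = label, domain_id = as.integer(domain_id),
                 informative_fraction = informative_fraction,
                 artifact_fraction = artifact_fraction,
                 hue_delta = hue_delta, sat_scale = sat_scale,
                 seed = as.integer(seed),
                 cell = as.integer(min(cell, width, height)),
                 informative_cell = if (is.null(informative_cell)) NULL else
                   as.integer(min(informative_cell, width, height))),
            class = "wsi_spec")
}

# choose n cells from a cell grid, returning a logical matrix over cells
pick_cells <- function(n_cells_x, n_cells_y, n_pick, exclude = NULL) {
  total <- n_cells_x * n_cells_y
  free <- seq_len(total)
  if (!is.null(exclude)) free <- setdiff(free, exclude)
  n_pick <- min(n_pick, length(free))
  if (n_pick <= 0) return(integer(0))
  sample(free, n_pick)
}

cell_pixels <- function(cell_idx, n_cells_x, cell, width, height) {
  # returns (row, col) pixel index ranges for a linear cell index
  cx <- (cell_idx - 1L) %% n_cells_x
  cy <- (cell_idx - 1L) %/% n_cells_x
  list(rows = (cy * cell + 1L):min((cy + 1L) * cell, height),
       cols = (cx * cell + 1L):min((cx + 1L) * cell, width))
}

#' Generate one synthetic WSI
#'
#' Produces an RGB image (H x W x 3 in \[0, 255\]) and the binary mask of
#' informative (class-texture) pixels. The background is near-white (mean
#' channel intensity > 200), artifact regions are near-black (mean < 25,
#' so they fail the brightness filter), the class texture covers the
#' requested fraction of the image within the granularity of the planting
#' grid (well inside +/-5 percent absolute), and the stain shift is applied
#' to tissue pixels only. Output is bitwise identical for identical specs.
#'
#' @param spec a [wsi_spec()].
#' @return list with `image` (H x W x 3 array), `mask` (H x W logical
#'   matrix of informative pixels) and `spec`.
#' @export
generate_wsi <- function(spec) {
  stopifnot(inherits(spec, "wsi_spec"))
  w <- spec$width; h <- spec$height
  with_seed(spec$seed, {
    # near-white background with slight pinkish tint and mild noise
    bg <- stats::runif(1, 240, 248)
    img <- array(0, c(h, w, 3))
    tint <- c(stats::runif(1, 2, 6), stats::runif(1, -4, 0), stats::runif(1, -1, 3))
    for (ch in 1:3) {
      img[, , ch] <- pmin(pmax(bg + tint[ch] + matrix(stats::rnorm(h * w, sd = 2), h, w), 210), 255)
    }

    # artifact cells on the coarse alignment grid
    cellA <- spec$cell
    nax <- max(1L, w %/% cellA); nay <- max(1L, h %/% cellA)
    n_art <- round(spec$artifact_fraction * (w * h) / (cellA^2))
    art_cells <- pick_cells(nax, nay, n_art)
    for (ci in art_cells) {
      px <- cell_pixels(ci, nax, cellA, w, h)
      vals <- pmin(pmax(8 + matrix(stats::rnorm(length(px$rows) * length(px$cols), sd = 3),
                                   length(px$rows)), 0), 20)
      for (ch in 1:3) img[px$rows, px$cols, ch] <- vals
    }

    # informative cells on a 4x finer grid, avoiding artifact cells
    cellI <- spec$informative_cell %||% max(16L, cellA %/% 4L)
    nix <- max(1L, w %/% cellI); niy <- max(1L, h %/% cellI)
    ratio <- cellA %/% cellI
    art_fine <- unlist(lapply(art_cells, function(ci) {
      cx <- (ci - 1L) %% nax; cy <- (ci - 1L) %/% nax
      fx <- cx * ratio + seq_len(ratio) - 1L
      fy <- cy * ratio + seq_len(ratio) - 1L
      fx <- fx[fx < nix]; fy <- fy[fy < niy]
      as.vector(outer(fx, fy * nix, `+`)) + 1L
    }))
    n_inf <- round(spec$informative_fraction * (w * h) / (cellI^2))
    inf_cells <- pick_cells(nix, niy, n_inf, exclude = art_fine)

    mask <- matrix(FALSE, h, w)
    if (length(inf_cells)) {
      tp <- class_texture_params(spec$label)
      xx <- matrix(seq_len(w), h, w, byrow = TRUE)
      yy <- matrix(seq_len(h), h, w)
      u <- cos(tp$theta) * xx + sin(tp$theta) * yy
      stripes <- 0.5 + 0.5 * sin(2 * pi * tp$freq * u / 256)
      dots <- as.numeric((xx %% tp$dot_period) < 3 & (yy %% tp$dot_period) < 3)
      tex <- 0.65 + 0.35 * (0.7 * stripes + 0.3 * dots)
      for (ci in inf_cells) {
        px <- cell_pixels(ci, nix, cellI, w, h)
        mask[px$rows, px$cols] <- TRUE
      }
      idx <- which(mask)
      noise <- stats::rnorm(length(idx), sd = 4)
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[idx] <- pmin(pmax(tp$base[ch] * tex[idx] + noise, 0), 255)
        img[, , ch] <- plane
      }
      if (spec$hue_delta != 0 || spec$sat_scale != 1) {
        img <- shift_stain(img, mask, spec$hue_delta, spec$sat_scale)
      }
    }
    list(image = img, mask = mask, spec = spec)
  })
}

# deterministic per-domain stain perturbation
domain_stain <- function(domain_id, n_domains) {
  centered <- domain_id - (n_domains + 1) / 2
  list(hue_delta = 10 * centered, sat_scale = 1 + 0.10 * centered)
}

#' Generate a synthetic multi-center cohort
#'
#' `5 * n_per_class` slides with exactly `n_per_class` per histotype;
#' domains are assigned round-robin within each class so every domain sees
#' a balanced class mix, and each domain carries its own fixed stain
#' perturbation (hue rotation + saturation scaling). Reproducible under
#' `seed`.
#'
#' @param n_per_class slides per histotype (>= 1).
#' @param n_domains number of institutional domains (>= 1).
#' @param size_range length-2 integer range from which slide side lengths
#'   are drawn (a single value fixes the size).
#' @param seed cohort seed.
#' @param out_dir directory for PNG images and `manifest.csv`; `NULL`
#'   (default) keeps the images in memory (`$images`) and leaves `path`
#'   empty in the manifest.
#' @param informative_fraction,artifact_fraction,cell,informative_cell
#'   forwarded to [wsi_spec()].
#' @param process optional `function(result, manifest_row)` applied to
#'   each generated slide in turn; when given, images are neither stored
#'   nor written (streaming mode for large cohorts), and the per-slide
#'   return values are collected in `$processed`.
#' @return list with `manifest` (data frame: image_id, label, image_width,
#'   image_height, is_tma, domain_id, path) and `images` (named list of
#'   `generate_wsi()` results; NULL when written to disk or streamed) and
#'   `processed` (in streaming mode).
#' @export
generate_cohort <- function(n_per_class, n_domains, size_range = c(1024, 2048),
                            seed = 1, out_dir = NULL,
                            informative_fraction = 0.3, artifact_fraction = 0.05,
                            cell = 512, informative_cell = NULL, process = NULL) {
  if (n_per_class < 1 || n_domains < 1) {
    stop("`n_per_class` and `n_domains` must be >= 1", call. = FALSE)
  }
  if (length(size_range) == 1L) size_range <- rep(size_range, 2)
  classes <- histotype_classes()
  n_total <- 5L * as.integer(n_per_class)
  draw_sizes <- function(n) {
    if (size_range[1] == size_range[2]) rep(as.integer(size_range[1]), n)
    else sample(size_range[1]:size_range[2], n, replace = TRUE)
  }
  rows <- with_seed(seed, {
    sizes_w <- draw_sizes(n_total)
    sizes_h <- draw_sizes(n_total)
    data.frame(
      image_id = sprintf("wsi_%04d", seq_len(n_total)),
      label = rep(classes, each = n_per_class),
      image_width = sizes_w, image_height = sizes_h,
      is_tma = FALSE,
      domain_id = rep((seq_len(n_per_class) - 1L) %% n_domains + 1L, times = 5L),
      path = "", stringsAsFactors = FALSE)
  })
  seeds <- derive_seeds(seed, n_total)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create output directory '%s'", out_dir), call. = FALSE)
  }
  streaming <- !is.null(process)
  images <- if (is.null(out_dir) && !streaming) vector("list", n_total) else NULL
  processed <- if (streaming) vector("list", n_total) else NULL
  for (i in seq_len(n_total)) {
    st <- domain_stain(rows$domain_id[i], n_domains)
    sp <- wsi_spec(rows$image_width[i], rows$image_height[i], rows$label[i],
                   domain_id = rows$domain_id[i],
                   informative_fraction = informative_fraction,
                   artifact_fraction = artifact_fraction,
                   hue_delta = st$hue_delta, sat_scale = st$sat_scale,
                   seed = seeds[i], cell = cell,
                   informative_cell = informative_cell)
    res <- generate_wsi(sp)
    if (streaming) {
      processed[[i]] <- process(res, rows[i, , drop = FALSE])
    } else if (is.null(out_dir)) {
      images[[i]] <- res
    } else {
      rows$path[i] <- file.path(out_dir, paste0(rows$image_id[i], ".png"))
      write_image(res$image, rows$path[i])
    }
  }
  if (!is.null(images)) {
    names(images) <- rows$image_id
  } else if (!is.null(out_dir) && !streaming) {
    utils::write.csv(rows, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  }
  if (streaming) names(processed) <- rows$image_id
  list(manifest = rows, images = images, processed = processed)
}

#' Add size z-scores to a cohort manifest
#'
#' Standardizes slide widths and heights over the cohort (mean 0, sample
#' standard deviation 1), the convention used for flagging size outliers.
#'
#' @param manifest a cohort manifest data frame with `image_width` and
#'   `image_height` columns.
#' @return the manifest with `width_zscore` and `height_zscore` columns
#'   appended.
#' @export
manifest_zscores <- function(manifest) {
  z <- function(x) if (stats::sd(x) == 0) rep(0, length(x)) else (x - mean(x)) / stats::sd(x)
  manifest$width_zscore <- z(manifest$image_width)
  manifest$height_zscore <- z(manifest$image_height)
  manifest
}
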