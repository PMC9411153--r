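#' Construct or read a core image
#'
#' `as_core_image()` wraps a pixel array; `read_core_image()` loads a
#' PNG/TIFF file. Pixels are stored as a `height x width x 3` array (or a
#' greyscale matrix) with values in [0, 1], row = image y.
#'
#' @param pixels Numeric array (`h x w x 3`) or matrix (`h x w`).
#' @param resolution Micrometres per pixel (> 0).
#' @param core_id Core identifier.
#' @param path Image file path (PNG or TIFF).
#' @return A `core_image` object.
#' @export
as_core_image <- function(pixels, resolution, core_id = "core") {
  stopifnot(resolution > 0, length(dim(pixels)) %in% c(2, 3))
  structure(list(pixels = pixels, truth_mask = NULL,
                 resolution = resolution, core_id = core_id),
            class = "core_image")
}

#' @rdname as_core_image
#' @export
read_core_image <- function(path, resolution, core_id = basename(path)) {
  img <- EBImage::readImage(path)
  arr <- as.array(img)
  arr <- if (length(dim(arr)) == 2) {
    t(arr)
  } else {
    aperm(arr[, , 1:3, drop = FALSE], c(2, 1, 3))
  }
  as_core_image(arr, resolution = resolution, core_id = core_id)
}

#' Write a core image or a binary mask to file
#'
#' Masks are written as single-channel PNG with tissue = 255.
#'
#' @param x A `core_image` or `tissue_mask`.
#' @param path Output path (extension selects the format).
#' @return `path`, invisibly.
#' @export
write_image <- function(x, path) {
  arr <- if (inherits(x, "tissue_mask")) {
    t(x$mask * 1)
  } else if (length(dim(x$pixels)) == 2) {
    t(x$pixels)
  } else {
    aperm(x$pixels, c(2, 1, 3))
  }
  img <- EBImage::Image(arr,
                        colormode = if (length(dim(arr)) == 3) "Color"
                        else "Grayscale")
  EBImage::writeImage(img, path)
  invisible(path)
}

core_grey <- function(pixels) {
  if (length(dim(pixels)) == 2) return(pixels)
  0.2126 * pixels[, , 1] + 0.7152 * pixels[, , 2] + 0.0722 * pixels[, , 3]
}

#' Compute the tissue mask of a core image
#'
#' Fixed pipeline: greyscale conversion, Otsu thresholding (tissue is the
#' darker side, as stained tissue is darker than the glass background),
#' morphological closing with a disc kernel, then retention of the tissue
#' contour with selective hole handling: interior background holes of
#' area at most `hole_um2` (converted to pixels via the image resolution)
#' are filled, larger holes are suppressed, i.e. kept as background. At
#' 0.25 um/px the default 1470 um^2 threshold is 23,520 px^2.
#'
#' @param image A `core_image` (RGB or greyscale).
#' @param hole_um2 Hole-area threshold in square micrometres.
#' @param closing_radius_px Radius of the closing disc at 0.25 um/px;
#'   scaled inversely with the actual resolution.
#' @param keep_largest Keep only the largest connected tissue component
#'   (the main tissue contour). Set `FALSE` for fragmented toy images.
#' @return A `tissue_mask`: logical `mask` congruent with the image,
#'   plus `resolution`, `hole_um2`, `hole_px2` and `core_id`. A
#'   constant-intensity image yields an empty mask with a warning.
#' @export
compute_tissue_mask <- function(image, hole_um2 = 1470,
                                closing_radius_px = 5,
                                keep_largest = TRUE) {
  grey <- core_grey(image$pixels)
  res <- image$resolution
  hole_px2 <- hole_um2 / res^2
  empty <- function() {
    structure(list(mask = matrix(FALSE, nrow(grey), ncol(grey)),
                   resolution = res, hole_um2 = hole_um2,
                   hole_px2 = hole_px2, core_id = image$core_id),
              class = "tissue_mask")
  }
  if (diff(range(grey)) < 1e-8) {
    warn("Constant-intensity image: Otsu threshold is degenerate; returning an empty mask.")
    return(empty())
  }
  thr <- EBImage::otsu(EBImage::Image(t(grey)))
  mask <- grey < thr
  if (!any(mask)) return(empty())

  radius <- max(1L, round(closing_radius_px * 0.25 / res))
  brush <- EBImage::makeBrush(2L * radius + 1L, shape = "disc")
  mask <- EBImage::closing(mask * 1, brush) > 0.5

  # selective hole handling: label background components; interior ones
  # (not touching the border) are holes, filled only when small enough
  bg_lab <- EBImage::bwlabel((!mask) * 1)
  if (max(bg_lab) > 0) {
    border_labels <- unique(c(bg_lab[1, ], bg_lab[nrow(bg_lab), ],
                              bg_lab[, 1], bg_lab[, ncol(bg_lab)]))
    areas <- tabulate(bg_lab[bg_lab > 0])
    fill <- setdiff(which(areas <= hole_px2), border_labels)
    if (length(fill) > 0) mask[bg_lab %in% fill] <- TRUE
  }

  if (keep_largest) {
    fg_lab <- EBImage::bwlabel(mask * 1)
    if (max(fg_lab) > 1) {
      areas <- tabulate(fg_lab[fg_lab > 0])
      mask <- fg_lab == which.max(areas)
    }
  }
  structure(list(mask = mask, resolution = res, hole_um2 = hole_um2,
                 hole_px2 = hole_px2, core_id = image$core_id),
            class = "tissue_mask")
}

#' @export
print.tissue_mask <- function(x, ...) {
  cat("<tissue_mask> ", x$core_id, ": ", sum(x$mask), "/",
      length(x$mask), " tissue pixels, hole threshold ", x$hole_um2,
      " um^2 (", round(x$hole_px2), " px^2)\n", sep = "")
  invisible(x)
}

#' Extract the non-overlapping patch grid of a masked core
#'
#' Tiles the image with non-overlapping `patch_size_px` squares anchored
#' at (0, 0); partial boundary patches are discarded. Each patch's tissue
#' fraction is the share of mask-positive pixels it covers; only patches
#' meeting `min_tissue_fraction` are retained.
#'
#' @param image A `core_image` (only its dimensions and id are used when
#'   `mask` is supplied).
#' @param mask A `tissue_mask` congruent with the image.
#' @param patch_size_px Patch side length in pixels.
#' @param min_tissue_fraction Minimum tissue share for a patch to be
#'   kept, in [0, 1].
#' @return Tibble `core_id, row, col, patch_size_px, tissue_fraction`
#'   with 0-based top-left pixel origins on multiples of
#'   `patch_size_px` (half-open patches `[row, row + size)`).
#' @export
extract_patch_grid <- function(image, mask, patch_size_px = 256L,
                               min_tissue_fraction = 0.5) {
  m <- mask$mask
  if (!identical(dim(m), dim(core_grey(image$pixels)))) {
    abort("Mask shape does not match the image.")
  }
  size <- as.integer(patch_size_px)
  n_r <- nrow(m) %/% size
  n_c <- ncol(m) %/% size
  if (n_r == 0 || n_c == 0) {
    return(tibble::tibble(core_id = character(), row = integer(),
                          col = integer(), patch_size_px = integer(),
                          tissue_fraction = numeric()))
  }
  cells <- tidyr::expand_grid(row = (seq_len(n_r) - 1L) * size,
                              col = (seq_len(n_c) - 1L) * size)
  cells$tissue_fraction <- purrr::map2_dbl(cells$row, cells$col, function(r, c) {
    mean(m[(r + 1):(r + size), (c + 1):(c + size)])
  })
  out <- cells |>
    dplyr::filter(.data$tissue_fraction >= min_tissue_fraction) |>
    dplyr::mutate(core_id = image$core_id, patch_size_px = size,
                  .before = 1)
  out
}

# ---- geometric / colour transforms --------------------------------------

flip_h <- function(a) {
  if (length(dim(a)) == 2) a[, ncol(a):1]
  else a[, dim(a)[2]:1, , drop = FALSE]
}

flip_v <- function(a) {
  if (length(dim(a)) == 2) a[nrow(a):1, ]
  else a[dim(a)[1]:1, , , drop = FALSE]
}

rot90cw <- function(a) {
  if (length(dim(a)) == 2) t(a[nrow(a):1, ])
  else {
    out <- array(0, dim = c(dim(a)[2], dim(a)[1], dim(a)[3]))
    for (ch in seq_len(dim(a)[3])) out[, , ch] <- t(a[dim(a)[1]:1, , ch])
    out
  }
}

colour_jitter <- function(a, brightness = 1.08, saturation = 1.15) {
  if (length(dim(a)) == 2) return(pmin(pmax(a * brightness, 0), 1))
  grey <- core_grey(a)
  out <- a
  for (ch in 1:3) {
    out[, , ch] <- grey + (a[, , ch] - grey) * saturation
  }
  pmin(pmax(out * brightness, 0), 1)
}

geo_transform_image <- function(pixels, transform) {
  switch(transform,
         identity = pixels,
         hflip = flip_h(pixels),
         vflip = flip_v(pixels),
         rot90 = rot90cw(pixels),
         rot180 = rot90cw(rot90cw(pixels)),
         rot270 = rot90cw(rot90cw(rot90cw(pixels))),
         hflip_rot90 = flip_h(rot90cw(pixels)),
         abort(paste0("Unknown transform: ", transform)))
}

# Permutation of the 2x2 super-patch blocks (TL, TR, BL, BR order)
# induced by each geometric transform, derived by acting on an index
# matrix so image- and feature-space augmentation stay consistent.
superpatch_block_perm <- function(transform, g = 2L) {
  idx <- matrix(seq_len(g * g), g, g, byrow = TRUE)
  as.integer(t(geo_transform_image(idx, transform)))
}

geo_transform_bag <- function(bag, transform) {
  if (transform == "identity" || bag$grid == 1L) return(bag)
  g <- bag$grid
  perm <- superpatch_block_perm(transform, g)
  d <- bag$d
  block_cols <- lapply(seq_len(g * g), function(b) ((b - 1) * d + 1):(b * d))
  new_cols <- unlist(block_cols[perm])
  bag$instances <- bag$instances[, new_cols, drop = FALSE]
  bag
}

#' Augment a cohort of images or feature bags
#'
#' `geo4` emits the original plus three geometric transforms per item
#' (horizontal flip, vertical flip, 90-degree rotation; 4x total).
#' `geocolour13` emits the original plus twelve variants: six geometric
#' transforms, each with and without a fixed-strength colour jitter
#' (13x total). Augmented copies keep the original's survival label and
#' record their provenance. On feature bags, geometric transforms act by
#' permuting super-patch sub-vectors (features of 1x1 patches carry no
#' spatial layout, so their vectors are unchanged); colour variants of
#' already-encoded features are provenance-only.
#'
#' @param items List of `core_image` or [patient_bag()] objects.
#' @param mode `"geo4"` or `"geocolour13"`.
#' @return Tibble with one row per augmented item: `origin` (source
#'   item's id), `transform`, `colour` (logical) and `item` (list
#'   column).
#' @export
augment_cohort <- function(items, mode = c("geo4", "geocolour13")) {
  mode <- match.arg(mode)
  plan <- if (mode == "geo4") {
    tibble::tibble(transform = c("identity", "hflip", "vflip", "rot90"),
                   colour = FALSE)
  } else {
    geo <- c("rot90", "rot180", "rot270", "hflip", "vflip", "hflip_rot90")
    dplyr::bind_rows(
      tibble::tibble(transform = "identity", colour = FALSE),
      tidyr::expand_grid(transform = geo, colour = c(FALSE, TRUE))
    )
  }
  rows <- purrr::map(items, function(it) {
    id <- if (inherits(it, "core_image")) it$core_id else it$patient_id
    aug <- purrr::map2(plan$transform, plan$colour, function(tr, col) {
      out <- if (inherits(it, "core_image")) {
        it$pixels <- geo_transform_image(it$pixels, tr)
        if (col) it$pixels <- colour_jitter(it$pixels)
        if (!is.null(it$truth_mask) && tr != "identity") {
          it$truth_mask <- geo_transform_image(it$truth_mask, tr) > 0.5
        }
        it
      } else {
        geo_transform_bag(it, tr)
      }
      out
    })
    dplyr::mutate(plan, origin = id, item = aug, .before = 1)
  })
  dplyr::bind_rows(rows)
}
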