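#' Rescale attention weights to [0, 1] with dataset-wide bounds
#'
#' Affine rescale `(a - min) / (max - min)` clipped to [0, 1], using the
#' global minimum and maximum attention weight over the whole dataset so
#' heatmaps of different cores are comparable. In the degenerate case
#' `global_max == global_min` every weight maps to 0.5.
#'
#' @param weights Numeric attention weights.
#' @param global_min,global_max Dataset-wide bounds
#'   (`global_max >= global_min`).
#' @return Numeric vector in [0, 1]; rescaling preserves the ranking of
#'   the raw weights.
#' @export
scale_attention <- function(weights, global_min, global_max) {
  stopifnot(global_max >= global_min)
  if (global_max == global_min) {
    return(rep(0.5, length(weights)))
  }
  pmin(pmax((weights - global_min) / (global_max - global_min), 0), 1)
}

#' Attention map of one core
#'
#' Binds per-patch attention weights to their patch-grid geometry,
#' rescaled with dataset-wide bounds (see [scale_attention()]).
#'
#' @param grid Patch-grid tibble for the core
#'   ([extract_patch_grid()]-shaped: `core_id, row, col,
#'   patch_size_px`).
#' @param weights Raw attention weights, one per grid row.
#' @param global_min,global_max Dataset-wide attention bounds; default
#'   to this core's own range.
#' @return Tibble `core_id, row, col, patch_size_px, weight,
#'   scaled_weight` of class `attention_map`.
#' @export
attention_map <- function(grid, weights, global_min = min(weights),
                          global_max = max(weights)) {
  if (nrow(grid) != length(weights)) {
    abort("One weight per grid patch is required.")
  }
  out <- dplyr::mutate(
    dplyr::select(tibble::as_tibble(grid),
                  "core_id", "row", "col", "patch_size_px"),
    weight = weights,
    scaled_weight = scale_attention(weights, global_min, global_max)
  )
  class(out) <- c("attention_map", class(out))
  out
}

# Bilinear interpolation of per-patch values (placed at patch centres)
# to the full pixel raster.
interpolate_weights <- function(map, height, width) {
  size <- map$patch_size_px[1]
  ctr_r <- sort(unique(map$row)) + size / 2
  ctr_c <- sort(unique(map$col)) + size / 2
  grid_vals <- matrix(NA_real_, length(ctr_r), length(ctr_c))
  ri <- match(map$row + size / 2, ctr_r)
  ci <- match(map$col + size / 2, ctr_c)
  grid_vals[cbind(ri, ci)] <- map$scaled_weight
  # patches dropped by tissue filtering get weight 0 in the field
  grid_vals[is.na(grid_vals)] <- 0

  interp_axis <- function(x, centers) {
    # clamp outside the convex hull of centres
    j <- findInterval(x, centers, all.inside = TRUE)
    x0 <- centers[j]
    x1 <- centers[j + 1]
    tfrac <- ifelse(x1 > x0, (x - x0) / (x1 - x0), 0)
    tfrac <- pmin(pmax(tfrac, 0), 1)
    list(lo = j, frac = tfrac)
  }
  if (length(ctr_r) == 1 && length(ctr_c) == 1) {
    return(matrix(grid_vals[1, 1], height, width))
  }
  ay <- interp_axis(seq_len(height) - 0.5,
                    if (length(ctr_r) > 1) ctr_r else c(ctr_r, ctr_r + 1))
  ax <- interp_axis(seq_len(width) - 0.5,
                    if (length(ctr_c) > 1) ctr_c else c(ctr_c, ctr_c + 1))
  gv <- grid_vals
  if (length(ctr_r) == 1) gv <- rbind(gv, gv)
  if (length(ctr_c) == 1) gv <- cbind(gv, gv)
  v00 <- gv[cbind(rep(ay$lo, width), rep(ax$lo, each = height))]
  v10 <- gv[cbind(rep(ay$lo + 1, width), rep(ax$lo, each = height))]
  v01 <- gv[cbind(rep(ay$lo, width), rep(ax$lo + 1, each = height))]
  v11 <- gv[cbind(rep(ay$lo + 1, width), rep(ax$lo + 1, each = height))]
  fy <- rep(ay$frac, width)
  fx <- rep(ax$frac, each = height)
  field <- (1 - fy) * (1 - fx) * v00 + fy * (1 - fx) * v10 +
    (1 - fy) * fx * v01 + fy * fx * v11
  matrix(field, height, width)
}

# simple blue -> red diverging-ish heat colouring of values in [0, 1]
heat_colour <- function(v) {
  r <- pmin(pmax(1.5 * v, 0), 1)
  g <- pmin(pmax(1 - abs(2 * v - 1), 0), 1) * 0.6
  b <- pmin(pmax(1.5 * (1 - v), 0), 1)
  list(r = r, g = g, b = b)
}

#' Render an attention heatmap over a core image
#'
#' Per-patch scaled attention weights are placed on the patch grid,
#' bilinearly interpolated to pixel resolution, colour-mapped, and
#' alpha-blended over the H&E image; non-tissue pixels stay untinted.
#'
#' @param image The `core_image` to overlay.
#' @param map An [attention_map()] for the same core.
#' @param mask Optional `tissue_mask`; tinting is restricted to its
#'   tissue pixels.
#' @param alpha Overlay opacity in [0, 1].
#' @return A `core_image` whose pixels carry the blended overlay (same
#'   dimensions as the input), with the interpolated weight field in
#'   attribute `weight_field`.
#' @export
render_heatmap <- function(image, map, mask = NULL, alpha = 0.4) {
  px <- image$pixels
  if (length(dim(px)) == 2) {
    px <- array(rep(px, 3), dim = c(dim(px), 3))
  }
  h <- dim(px)[1]
  w <- dim(px)[2]
  size <- map$patch_size_px[1]
  if (any(map$row + size > h) || any(map$col + size > w)) {
    abort("Attention map geometry exceeds the core raster.")
  }
  field <- interpolate_weights(map, h, w)
  tint <- heat_colour(as.vector(field))
  blend <- array(c(tint$r, tint$g, tint$b), dim = c(h, w, 3))
  out <- (1 - alpha) * px + alpha * blend
  if (!is.null(mask)) {
    keep <- !mask$mask
    for (ch in 1:3) {
      layer <- out[, , ch]
      orig <- px[, , ch]
      layer[keep] <- orig[keep]
      out[, , ch] <- layer
    }
  }
  res <- as_core_image(out, resolution = image$resolution,
                       core_id = paste0(image$core_id, "_heatmap"))
  attr(res, "weight_field") <- field
  res
}

#' Write a heatmap overlay and its side-car weight table
#'
#' @param image A `core_image`, typically from [render_heatmap()].
#' @param map The [attention_map()] used for the overlay.
#' @param dir Output directory.
#' @return Paths of the written files, invisibly.
#' @export
write_heatmap <- function(image, map, dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  png_path <- file.path(dir, paste0(image$core_id, ".png"))
  csv_path <- file.path(dir, paste0(image$core_id, "_weights.csv"))
  write_image(image, png_path)
  utils::write.csv(as.data.frame(map), csv_path, row.names = FALSE)
  invisible(c(png_path, csv_path))
}
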