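#' Deterministic synthetic patch encoder
#'
#' The real pipeline uses a pretrained neural image-compression encoder
#' mapping a 128 x 128 px tile at 0.5 um/px to a 1 x 1 x d encoding; its
#' weights are an external artifact, so the framework treats the encoder
#' as a pluggable contract. This synthetic stand-in is a seeded
#' pseudo-random linear projection of the tile's pixel content (per-row
#' and per-column channel means plus global moments), squashed through
#' tanh. It is deterministic, emits fixed-length d-vectors, and changing
#' any single pixel changes the output.
#'
#' @param d Output feature dimension.
#' @param tile_px Expected tile side length in pixels.
#' @param seed Seed of the projection.
#' @return An encoder object (list with `d`, `tile_px` and `encode`,
#'   a function from a tile array to a d-vector), class
#'   `synthetic_encoder`.
#' @export
synthetic_encoder <- function(d = 128L, tile_px = 128L, seed = 42L) {
  s_len <- tile_px * 3L * 2L + 6L
  P <- local_seeded(seed,
                    matrix(rnorm(d * s_len, sd = 1 / sqrt(s_len)), d, s_len))
  enc <- function(tile) {
    if (length(dim(tile)) == 2) {
      tile <- array(rep(tile, 3), dim = c(dim(tile), 3))
    }
    if (dim(tile)[1] != tile_px || dim(tile)[2] != tile_px) {
      abort(paste0("Encoder expects a ", tile_px, " x ", tile_px,
                   " tile."))
    }
    row_means <- apply(tile, c(1, 3), mean)   # tile_px x 3
    col_means <- apply(tile, c(2, 3), mean)
    moments <- c(mean(tile), sd(as.vector(tile)),
                 apply(tile, 3, mean), 0)[1:6]
    s <- c(as.vector(row_means), as.vector(col_means), moments)
    drop(tanh(P %*% (s * tile_px / 4)))
  }
  structure(list(d = as.integer(d), tile_px = as.integer(tile_px),
                 encode = enc, seed = as.integer(seed)),
            class = "synthetic_encoder")
}

# Average 2x2 pixel blocks (bilinear downsampling by a factor of 2).
downsample_by2 <- function(pixels) {
  ds_mat <- function(m) {
    r <- nrow(m) %/% 2L
    c <- ncol(m) %/% 2L
    m <- m[seq_len(2L * r), seq_len(2L * c)]
    0.25 * (m[seq(1, 2 * r, 2), seq(1, 2 * c, 2)] +
              m[seq(2, 2 * r, 2), seq(1, 2 * c, 2)] +
              m[seq(1, 2 * r, 2), seq(2, 2 * c, 2)] +
              m[seq(2, 2 * r, 2), seq(2, 2 * c, 2)])
  }
  if (length(dim(pixels)) == 2) return(ds_mat(pixels))
  out <- array(0, dim = c(dim(pixels)[1] %/% 2L, dim(pixels)[2] %/% 2L, dim(pixels)[3]))
  for (ch in seq_len(dim(pixels)[3])) out[, , ch] <- ds_mat(pixels[, , ch])
  out
}

#' Encode one 256-px patch into a feature vector
#'
#' The 256 x 256 px patch (at 0.25 um/px) is first downsampled by a
#' factor of 2 by bilinear averaging to the 128 x 128 px, 0.5 um/px tile
#' the encoder contract expects, then encoded to a d-vector.
#'
#' @param patch Pixel array of the patch (`256 x 256 x 3` or matrix).
#' @param encoder An encoder object (e.g. [synthetic_encoder()]).
#' @param patch_px Expected patch side length.
#' @return Numeric d-vector.
#' @export
encode_patch <- function(patch, encoder, patch_px = 256L) {
  dm <- dim(patch)
  if (dm[1] != patch_px || dm[2] != patch_px) {
    abort(paste0("Patch must be ", patch_px, " x ", patch_px, " px."))
  }
  encoder$encode(downsample_by2(patch))
}

#' Encode every retained patch of a core
#'
#' @param image A `core_image`.
#' @param grid Patch grid tibble from [extract_patch_grid()].
#' @param encoder Encoder object.
#' @return Feature tibble `core_id, row, col, feature` (list column of
#'   d-vectors).
#' @export
encode_core <- function(image, grid, encoder) {
  feats <- purrr::map2(grid$row, grid$col, function(r, c) {
    size <- grid$patch_size_px[1]
    patch <- if (length(dim(image$pixels)) == 2) {
      image$pixels[(r + 1):(r + size), (c + 1):(c + size)]
    } else {
      image$pixels[(r + 1):(r + size), (c + 1):(c + size), , drop = FALSE]
    }
    encode_patch(patch, encoder, patch_px = size)
  })
  tibble::tibble(core_id = grid$core_id, row = grid$row, col = grid$col,
                 feature = feats)
}

#' Assemble 2 x 2 super-patch instances from per-patch features
#'
#' Groups the 256-px patch features into 512-px super-patches: each
#' 2x2 block of adjacent patches whose four children all survived tissue
#' filtering becomes a single instance holding the four d-vectors
#' (flattened TL, TR, BL, BR); blocks with any child missing are
#' dropped.
#'
#' @param features Feature tibble (`core_id, row, col, feature`) at the
#'   base patch size.
#' @param patch_size_px Base patch size in pixels.
#' @return Feature tibble of super-patch instances with `grid = 2`
#'   recorded in attribute `grid`; `row`/`col` are the block origins.
#' @export
assemble_superpatches <- function(features, patch_size_px = 256L) {
  s <- as.integer(patch_size_px)
  key <- function(core, r, c) paste(core, r, c, sep = "|")
  have <- setNames(seq_len(nrow(features)),
                   key(features$core_id, features$row, features$col))
  blocks <- features |>
    dplyr::mutate(block_row = (.data$row %/% (2L * s)) * 2L * s,
                  block_col = (.data$col %/% (2L * s)) * 2L * s) |>
    dplyr::distinct(.data$core_id, .data$block_row, .data$block_col)
  rows <- purrr::pmap(blocks, function(core_id, block_row, block_col) {
    children <- c(
      key(core_id, block_row, block_col),
      key(core_id, block_row, block_col + s),
      key(core_id, block_row + s, block_col),
      key(core_id, block_row + s, block_col + s)
    )
    idx <- have[children]
    if (anyNA(idx)) return(NULL)
    tibble::tibble(core_id = core_id, row = block_row, col = block_col,
                   feature = list(unlist(features$feature[idx],
                                         use.names = FALSE)))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(core_id = character(), row = integer(),
                          col = integer(), feature = list())
  }
  attr(out, "grid") <- 2L
  out
}

#' Pool per-core features into per-patient bags
#'
#' Joins a feature table to the cohort through each patient's core ids
#' and pools all instances of a patient's cores into one bag carrying
#' the patient's survival label.
#'
#' @param cohort Cohort tibble ([read_manifest()] / [as_cohort()]).
#' @param features Feature tibble (`core_id, row, col, feature`), plain
#'   patch vectors or super-patch instances.
#' @param grid Super-patch grid size of the features (1 or 2; defaults
#'   to the table's `grid` attribute).
#' @return Named list of [patient_bag()] objects, one per patient, in
#'   cohort order.
#' @export
build_bags <- function(cohort, features, grid = NULL) {
  grid <- as.integer(grid %||% attr(features, "grid") %||% 1L)
  core_to_patient <- cohort |>
    dplyr::select("patient_id", "core_ids") |>
    tidyr::unnest("core_ids") |>
    dplyr::rename(core_id = "core_ids")
  orphans <- setdiff(unique(features$core_id), core_to_patient$core_id)
  if (length(orphans) > 0) {
    abort(paste0("Features reference core id(s) absent from the cohort: ",
                 paste(orphans, collapse = ", ")))
  }
  joined <- dplyr::inner_join(features, core_to_patient, by = "core_id")
  bags <- purrr::map(seq_len(nrow(cohort)), function(i) {
    pid <- cohort$patient_id[i]
    rows <- joined[joined$patient_id == pid, ]
    if (nrow(rows) == 0) {
      abort(paste0("Patient ", pid,
                   " has no surviving instances; cannot build a bag."),
            class = "milsurv_validation_error")
    }
    X <- do.call(rbind, rows$feature)
    patient_bag(pid, X, time = cohort$time_years[i],
                event = cohort$event[i], d = ncol(X) %/% grid^2,
                grid = grid)
  })
  names(bags) <- cohort$patient_id
  bags
}

#' Write / read a plain-text feature store
#'
#' One CSV per core (`row,col` plus the feature entries) and an
#' `index.csv` listing the cores.
#'
#' @param features Feature tibble (`core_id, row, col, feature`).
#' @param dir Directory for the store (created if needed).
#' @return `write_feature_store()` returns `dir` invisibly;
#'   `read_feature_store()` returns the feature tibble.
#' @export
write_feature_store <- function(features, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cores <- unique(features$core_id)
  for (core in cores) {
    rows <- features[features$core_id == core, ]
    mat <- do.call(rbind, rows$feature)
    df <- data.frame(row = rows$row, col = rows$col, mat)
    utils::write.csv(df, file.path(dir, paste0(core, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(data.frame(core_id = cores,
                              grid = attr(features, "grid") %||% 1L),
                   file.path(dir, "index.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_feature_store
#' @export
read_feature_store <- function(dir) {
  index <- utils::read.csv(file.path(dir, "index.csv"),
                           stringsAsFactors = FALSE)
  out <- purrr::map_dfr(index$core_id, function(core) {
    df <- utils::read.csv(file.path(dir, paste0(core, ".csv")))
    tibble::tibble(
      core_id = core, row = as.integer(df$row), col = as.integer(df$col),
      feature = lapply(seq_len(nrow(df)),
                       function(i) as.numeric(df[i, -(1:2)]))
    )
  })
  attr(out, "grid") <- as.integer(index$grid[1])
  out
}
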