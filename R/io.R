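# TIFF + YAML-sidecar serialization.  Pixel data are written as 32-bit
# float TIFF pages scaled to [0, 1] by the bit-depth ceiling; the sidecar
# records channel roles, window edges, lasers, bit depth and scale so a
# read round-trips exactly.

#' Write / read a three-cube set as multi-page TIFF + YAML sidecar
#'
#' Pages are ordered donor, raw-FRET, acceptor, validity mask.
#'
#' @param cube a [three_cube()].
#' @param path output TIFF path; the sidecar is written next to it with a
#'   `.yaml` extension.
#' @return `write_three_cube`: the TIFF path, invisibly.
#' @export
write_three_cube <- function(cube, path) {
  stopifnot(inherits(cube, "three_cube"))
  sat <- saturation_value(cube$bit_depth)
  pages <- list(cube$I_DD / sat, cube$I_DA / sat, cube$I_AA / sat,
                cube$valid_mask * 1)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(kind = "three_cube",
               channels = c("I_DD", "I_DA", "I_AA", "valid_mask"),
               bit_depth = cube$bit_depth, scale = sat)
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}

#' @rdname write_three_cube
#' @export
read_three_cube <- function(path) {
  meta <- yaml::read_yaml(sidecar_path(path))
  if (!identical(meta$kind, "three_cube"))
    stopf("'%s' is not a three-cube sidecar", sidecar_path(path))
  pages <- tiff::readTIFF(path, all = TRUE)
  sat <- meta$scale
  three_cube(pages[[1]] * sat, pages[[2]] * sat, pages[[3]] * sat,
             valid_mask = pages[[4]] > 0.5, bit_depth = meta$bit_depth)
}

#' Write / read a lambda stack as multi-page TIFF + YAML sidecar
#'
#' Channel pages are laser-major, window-minor, followed by the validity
#' mask; the sidecar stores the laser lines and window edges.
#'
#' @param stack a [lambda_stack()].
#' @param path output TIFF path.
#' @export
write_lambda_stack <- function(stack, path) {
  stopifnot(inherits(stack, "lambda_stack"))
  sat <- saturation_value(stack$bit_depth)
  pages <- c(lapply(unlist(stack$blocks, recursive = FALSE),
                    function(im) im / sat),
             list(stack$valid_mask * 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(kind = "lambda_stack",
               lasers = as.numeric(names(stack$blocks)),
               window_edges = apply(stack$window_edges, 1, as.list),
               bit_depth = stack$bit_depth, scale = sat)
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}

#' @rdname write_lambda_stack
#' @export
read_lambda_stack <- function(path) {
  meta <- yaml::read_yaml(sidecar_path(path))
  if (!identical(meta$kind, "lambda_stack"))
    stopf("'%s' is not a lambda-stack sidecar", sidecar_path(path))
  pages <- tiff::readTIFF(path, all = TRUE)
  sat <- meta$scale
  windows <- do.call(rbind, lapply(meta$window_edges, unlist))
  nw <- nrow(windows)
  lasers <- meta$lasers
  blocks <- stats::setNames(vector("list", length(lasers)),
                            as.character(lasers))
  for (li in seq_along(lasers)) {
    blocks[[li]] <- lapply(pages[(li - 1L) * nw + seq_len(nw)],
                           function(p) p * sat)
  }
  mask_page <- pages[[length(lasers) * nw + 1L]]
  lambda_stack(blocks, windows, valid_mask = mask_page > 0.5,
               bit_depth = meta$bit_depth)
}

#' Write the ground truth of a synthetic scene
#'
#' Writes the integer label map and nuclear mask as TIFF pages and the
#' per-cell table (cell id, centroid, area, abundance, nuclear retention)
#' as CSV.
#'
#' @param scene a [simulate_scene()] result.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return named paths, invisibly.
#' @export
write_scene_truth <- function(scene, dir, prefix = "scene") {
  stopifnot(inherits(scene, "ground_truth_scene"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tif <- file.path(dir, paste0(prefix, "_labels.tif"))
  csv <- file.path(dir, paste0(prefix, "_cells.csv"))
  tiff::writeTIFF(list(scene$label_map / 65535,
                       scene$nuclear_mask * 1), tif, bits.per.sample = 32L)
  utils::write.csv(scene$cells, csv, row.names = FALSE)
  invisible(c(labels = tif, cells = csv))
}

#' Read back a scene's label map and nuclear mask
#' @param path TIFF written by [write_scene_truth()].
#' @return list: `label_map` (integer matrix), `nuclear_mask` (logical).
#' @export
read_scene_labels <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  list(label_map = matrix(as.integer(round(pages[[1]] * 65535)),
                          nrow(pages[[1]]), ncol(pages[[1]])),
       nuclear_mask = pages[[2]] > 0.5)
}

#' Write bleed-through constants to CSV
#' @param constants list of [estimate_bleedthrough()] results.
#' @param path CSV path.
#' @export
write_bleedthrough_csv <- function(constants, path) {
  rows <- lapply(constants, function(x) {
    stopifnot(inherits(x, "bleedthrough_constant"))
    data.frame(which = x$which, value = x$value,
               n_pixels_used = x$n_pixels_used,
               fit_residual = x$fit_residual, method = x$method)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

sidecar_path <- function(path) paste0(sub("\\.tiff?$", "", path), ".yaml")
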