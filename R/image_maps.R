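#' Cell distance map (CDP)
#'
#' Per object, the Euclidean distance of each object pixel to the nearest
#' pixel not belonging to that object, normalized to `[0, 1]` by the
#' object's maximum, then composited. Single-pixel objects map to 1
#' (the degenerate 0/0 normalization resolves to the maximum). Background
#' is 0 everywhere.
#'
#' @param labels Integer label matrix (0 = background).
#' @return Numeric matrix in `[0, 1]`.
#' @export
make_cell_distance_map <- function(labels) {
  ids <- setdiff(sort(unique(as.vector(labels))), 0)
  cdp <- matrix(0, nrow(labels), ncol(labels))
  if (!length(ids)) {
    warning("empty label image: all-zero cell distance map")
    return(cdp)
  }
  for (k in ids) {
    mask <- labels == k
    dt <- EBImage::distmap(EBImage::Image(mask * 1), metric = "euclidean")
    dt <- dt@.Data
    mx <- max(dt[mask])
    cdp[mask] <- if (mx > 0) dt[mask] / mx else 1
  }
  cdp
}

#' Neighbor distance map (NDP)
#'
#' For each object: remove it from the label image, invert, distance
#' transform (distance to the nearest remaining object), mask to the
#' removed object's pixels, normalize to `[0, 1]`, and invert again.
#' All per-object results are composited, grayscale-closed with a flat 3x3
#' kernel, and raised to the 10th power for a steep within-object gradient.
#' An image with a single object yields a near-zero (no-neighbor) map.
#'
#' @param labels Integer label matrix.
#' @return Numeric matrix in `[0, 1]`, high near inter-object interfaces.
#' @export
make_neighbor_distance_map <- function(labels) {
  ids <- setdiff(sort(unique(as.vector(labels))), 0)
  ndp <- matrix(0, nrow(labels), ncol(labels))
  if (!length(ids)) return(ndp)
  for (k in ids) {
    mask <- labels == k
    others <- labels != 0 & !mask
    if (!any(others)) next  # no neighbors: contribution stays 0
    ## distance of every pixel to the nearest other-object pixel
    dt <- EBImage::distmap(EBImage::Image((!others) * 1),
                           metric = "euclidean")@.Data
    vals <- dt[mask]
    mx <- max(vals)
    if (mx > 0) ndp[mask] <- 1 - vals / mx else ndp[mask] <- 1
  }
  closed <- EBImage::closing(EBImage::Image(ndp),
                             EBImage::makeBrush(3, shape = "box"))@.Data
  pmin(pmax(closed, 0), 1)^10
}

#' Build both distance maps
#' @param labels Integer label matrix.
#' @return List `cdp`, `ndp`.
#' @export
make_distance_maps <- function(labels) {
  list(cdp = make_cell_distance_map(labels),
       ndp = make_neighbor_distance_map(labels))
}

## Meyer-style marker-constrained watershed on an elevation surface.
## seeds: integer label matrix (>0 marker pixels); mask: logical; 4-neighbor
## flooding in increasing elevation order.
.marker_watershed <- function(elevation, seeds, mask) {
  nr <- nrow(elevation); nc <- ncol(elevation)
  lab <- ifelse(mask, seeds, 0L)
  lab[!mask] <- -1L  # outside
  neigh <- function(i) {
    r <- ((i - 1) %% nr) + 1; c <- ((i - 1) %/% nr) + 1
    out <- integer()
    if (r > 1) out <- c(out, i - 1)
    if (r < nr) out <- c(out, i + 1)
    if (c > 1) out <- c(out, i - nr)
    if (c < nc) out <- c(out, i + nr)
    out
  }
  labeled <- which(lab > 0)
  frontier <- unique(unlist(lapply(labeled, neigh)))
  frontier <- frontier[lab[frontier] == 0L]
  in_front <- logical(nr * nc); in_front[frontier] <- TRUE
  while (length(frontier)) {
    j <- frontier[which.min(elevation[frontier])]
    frontier <- frontier[frontier != j]
    in_front[j] <- FALSE
    nb <- neigh(j)
    nb_lab <- lab[nb]
    src <- nb_lab[nb_lab > 0]
    if (length(src)) {
      lab[j] <- min(src)  # ties to the smallest marker id
      new <- nb[lab[nb] == 0L & !in_front[nb]]
      if (length(new)) {
        frontier <- c(frontier, new)
        in_front[new] <- TRUE
      }
    }
  }
  lab[lab < 0] <- 0L
  lab
}

#' Reconstruct a label image from predicted distance maps
#'
#' Both maps are Gaussian-smoothed (`sigma = 1.5`); the binary mask is the
#' smoothed CDP above 0.15; the seed map is the smoothed CDP minus the
#' squared smoothed NDP, thresholded at 0.25 and connected-component
#' labelled; a marker-constrained watershed on the negated smoothed CDP,
#' restricted to the mask, yields the final labels.
#'
#' @param cdp_pred,ndp_pred Real-valued prediction matrices (same shape).
#' @param sigma Gaussian smoothing sigma (default 1.5).
#' @param mask_threshold CDP mask threshold (default 0.15).
#' @param seed_threshold Seed-map threshold (default 0.25).
#' @return Integer label matrix (0 = background); a warning and an empty
#'   labeling when no seeds survive the threshold.
#' @export
reconstruct_labels <- function(cdp_pred, ndp_pred, sigma = 1.5,
                               mask_threshold = 0.15, seed_threshold = 0.25) {
  stopifnot(all(dim(cdp_pred) == dim(ndp_pred)))
  sc <- EBImage::gblur(EBImage::Image(cdp_pred), sigma = sigma)@.Data
  sn <- EBImage::gblur(EBImage::Image(ndp_pred), sigma = sigma)@.Data
  mask <- sc > mask_threshold
  seed_map <- sc - sn^2
  seeds_bin <- seed_map > seed_threshold
  if (!any(seeds_bin)) {
    warning("no seeds above threshold: empty labeling")
    return(matrix(0L, nrow(cdp_pred), ncol(cdp_pred)))
  }
  seeds <- EBImage::bwlabel(EBImage::Image(seeds_bin * 1))@.Data
  storage.mode(seeds) <- "integer"
  .marker_watershed(-sc, seeds, mask)
}

#' Read or write a single-channel image
#'
#' TIFF via the tiff package (float maps as 32-bit, labels as 16-bit
#' integer scaled), PNG via png. Matrices are stored row-major as written.
#'
#' @param path File path (.tif/.tiff/.png).
#' @param what `"map"` (float in `[0,1]`) or `"labels"` (integers).
#' @return Numeric or integer matrix.
#' @export
read_image_map <- function(path, what = c("map", "labels")) {
  what <- match.arg(what)
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the tiff package is required to read TIFF files")
    tiff::readTIFF(path)
  } else if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE))
      stop("the png package is required to read PNG files")
    png::readPNG(path)
  } else stop("unsupported image format: ", ext)
  if (length(dim(img)) == 3) img <- img[, , 1]
  if (what == "labels") {
    img <- round(img * 65535)
    storage.mode(img) <- "integer"
  }
  img
}

#' @rdname read_image_map
#' @param img Matrix to write.
#' @export
write_image_map <- function(img, path, what = c("map", "labels")) {
  what <- match.arg(what)
  ext <- tolower(tools::file_ext(path))
  if (what == "labels") img <- img / 65535
  img <- pmin(pmax(img, 0), 1)
  if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the tiff package is required to write TIFF files")
    tiff::writeTIFF(img, path,
                    bits.per.sample = if (what == "labels") 16L else 32L)
  } else if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE))
      stop("the png package is required to write PNG files")
    png::writePNG(img, path)
  } else stop("unsupported image format: ", ext)
  invisible(path)
}
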