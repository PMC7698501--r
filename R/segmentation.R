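#' Subtract a background image
#'
#' Per-pixel difference `image - background`, clamped below at zero
#' (8-bit arithmetic must not wrap).
#'
#' @param image,background Grayscale matrices of identical shape.
#' @return Integer matrix of the clamped difference.
#' @export
subtract_background <- function(image, background) {
  assert_gray_image(image); assert_gray_image(background, "background")
  if (!all(dim(image) == dim(background)))
    stop("image and background shapes differ: ",
         paste(dim(image), collapse = "x"), " vs ",
         paste(dim(background), collapse = "x"))
  out <- image - background
  out[out < 0] <- 0
  storage.mode(out) <- "integer"
  out
}

#' Binarize a grayscale image
#'
#' Foreground where intensity is strictly greater than the threshold.
#' `threshold` may be a number (absolute intensity level) or the policy
#' string `"half-contrast"`, which sets the threshold halfway between
#' the image minimum (taken as the residual background level of a
#' background-subtracted crop) and its maximum.
#'
#' @param image Grayscale matrix.
#' @param threshold Numeric level, or `"half-contrast"`.
#' @return Binary 0/1 integer matrix (an empty mask is legal).
#' @export
binarize <- function(image, threshold = 0) {
  assert_gray_image(image)
  if (identical(threshold, "half-contrast")) {
    lo <- min(image); hi <- max(image)
    threshold <- lo + 0.5 * (hi - lo)
  }
  stopifnot(is.numeric(threshold), length(threshold) == 1)
  out <- (image > threshold) + 0L
  storage.mode(out) <- "integer"
  out
}

# 3x3 cross (4-neighborhood) structuring element.
cross_kernel <- function() EBImage::makeBrush(3, shape = "diamond")

#' Morphological cleanup of a binary mask
#'
#' One iteration of morphological opening followed by closing with a
#' 3x3 cross structuring element: removes isolated noise pixels and
#' fills single-pixel cracks without measurably changing large convex
#' blobs.
#'
#' @param mask Binary 0/1 matrix.
#' @return Cleaned binary 0/1 integer matrix.
#' @export
clean_mask <- function(mask) {
  assert_binary_mask(mask)
  k <- cross_kernel()
  # pad with background so dilation/erosion at the image border do not
  # grow objects against the edge
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(0L, nr + 4, nc + 4)
  pad[3:(nr + 2), 3:(nc + 2)] <- mask
  out <- EBImage::closing(EBImage::opening(pad, k), k)
  out <- (as.matrix(EBImage::imageData(out))[3:(nr + 2), 3:(nc + 2)] > 0) + 0L
  storage.mode(out) <- "integer"
  out
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so labels that
# touch diagonally are merged with a union-find pass.
label_components_8 <- function(mask) {
  lab <- as.matrix(EBImage::imageData(EBImage::bwlabel(mask)))
  nlab <- max(lab)
  if (nlab < 2) return(lab)
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union_ <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  nr <- nrow(lab); nc <- ncol(lab)
  diag_pairs <- function(a, b) {
    sel <- a > 0 & b > 0 & a != b
    if (any(sel)) {
      pr <- unique(cbind(a[sel], b[sel]))
      for (i in seq_len(nrow(pr))) union_(pr[i, 1], pr[i, 2])
    }
  }
  diag_pairs(lab[-nr, -nc], lab[-1, -1])   # down-right neighbors
  diag_pairs(lab[-nr, -1], lab[-1, -nc])   # down-left neighbors
  roots <- vapply(seq_len(nlab), find, integer(1))
  dense <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- dense[lab[lab > 0]]
  out
}

#' Extract per-particle measurements from a binary mask
#'
#' 8-connected component labeling followed by morphometry of each
#' component: extents of the bounding box perpendicular (`x_extent_px`)
#' and parallel (`y_extent_px`, the most extended flow-axis length) to
#' the flow, foreground pixel count (`area_px`) and centroid. Components
#' touching the image border are flagged `truncated`; components whose
#' square analysis crop (side `optics$crop_px`, centered on the
#' centroid) would contain part of another component are flagged
#' `crowded`. Flagged particles should be excluded from velocimetry.
#'
#' Bounding boxes are half-open 0-based `[row0, row1) x [col0, col1)`,
#' so extent = difference of the two bounds.
#'
#' @param mask Binary 0/1 matrix.
#' @param optics An [optics_config()] (crop size and pixel size).
#' @return A data frame with one row per component: `label`,
#'   `x_extent_px`, `y_extent_px`, `area_px`, `centroid_row`,
#'   `centroid_col`, `row0`, `row1`, `col0`, `col1`, `truncated`,
#'   `crowded`. Zero rows for an empty mask.
#' @export
extract_particles <- function(mask, optics = optics_config()) {
  assert_binary_mask(mask)
  lab <- label_components_8(mask)
  n <- max(lab)
  empty <- data.frame(label = integer(), x_extent_px = integer(),
                      y_extent_px = integer(), area_px = integer(),
                      centroid_row = numeric(), centroid_col = numeric(),
                      row0 = integer(), row1 = integer(),
                      col0 = integer(), col1 = integer(),
                      truncated = logical(), crowded = logical())
  if (n == 0) return(empty)
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(lab > 0, arr.ind = TRUE)
  lbl <- lab[lab > 0]
  rows <- split(idx[, 1], lbl)
  cols <- split(idx[, 2], lbl)
  res <- empty[rep(1, n), ]
  for (i in seq_len(n)) {
    r <- rows[[i]]; cc <- cols[[i]]
    res$label[i] <- i
    res$row0[i] <- min(r) - 1L; res$row1[i] <- max(r)
    res$col0[i] <- min(cc) - 1L; res$col1[i] <- max(cc)
    res$y_extent_px[i] <- res$row1[i] - res$row0[i]
    res$x_extent_px[i] <- res$col1[i] - res$col0[i]
    res$area_px[i] <- length(r)
    res$centroid_row[i] <- mean(r) - 0.5  # 0-based pixel-center coords
    res$centroid_col[i] <- mean(cc) - 0.5
    res$truncated[i] <- res$row0[i] == 0 || res$col0[i] == 0 ||
      res$row1[i] == nr || res$col1[i] == nc
  }
  half <- optics$crop_px / 2
  for (i in seq_len(n)) {
    w_r0 <- res$centroid_row[i] - half; w_r1 <- res$centroid_row[i] + half
    w_c0 <- res$centroid_col[i] - half; w_c1 <- res$centroid_col[i] + half
    others <- setdiff(seq_len(n), i)
    res$crowded[i] <- any(res$row1[others] > w_r0 &
                          res$row0[others] < w_r1 &
                          res$col1[others] > w_c0 &
                          res$col0[others] < w_c1)
  }
  rownames(res) <- NULL
  res
}
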