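#' Validate a binary mask
#'
#' @param mask numeric or integer matrix whose entries must all be 0 or 1.
#' @param arg name used in error messages.
#' @return the mask, invisibly, as a numeric matrix.
#' @keywords internal
assert_binary_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask)) stop(sprintf("'%s' must be a matrix", arg))
  if (nrow(mask) < 1L || ncol(mask) < 1L) stop(sprintf("'%s' must be non-empty", arg))
  if (!all(mask == 0 | mask == 1)) {
    stop(sprintf("'%s' is not a binary mask: values must be exactly 0 or 1", arg))
  }
  invisible(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
}

#' Extract the inner boundary of a binary mask
#'
#' The boundary of a binary region is defined as the set of foreground pixels
#' having at least one background neighbour under the chosen connectivity
#' (4-connectivity by default). Pixels on the image border treat the outside of
#' the image as background, so a foreground pixel touching the border is always
#' a boundary pixel. This inner-boundary convention guarantees that the
#' boundary is a subset of the foreground.
#'
#' @param mask binary matrix (values 0/1), rows indexed top to bottom.
#' @param connectivity 4 or 8.
#' @return a data.frame with integer columns `row` and `col` (0-based, row 0 at
#'   the top), in row-major order, plus attribute `connectivity`. An all-0 mask
#'   yields an empty set; because the outside of the frame counts as
#'   background, an all-1 mask yields the image frame (a 1x1 mask equal to 1
#'   yields the single pixel (0,0)).
#' @export
extract_boundary <- function(mask, connectivity = 4) {
  assert_binary_mask(mask)
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  h <- nrow(mask); w <- ncol(mask)
  # pad with background so the image border sees the outside as background
  p <- matrix(0, h + 2L, w + 2L)
  p[2:(h + 1L), 2:(w + 1L)] <- mask
  core <- p[2:(h + 1L), 2:(w + 1L)]
  up    <- p[1:h,           2:(w + 1L)]
  down  <- p[3:(h + 2L),    2:(w + 1L)]
  left  <- p[2:(h + 1L),    1:w]
  right <- p[2:(h + 1L),    3:(w + 2L)]
  has_bg <- (up == 0) | (down == 0) | (left == 0) | (right == 0)
  if (connectivity == 8) {
    ul <- p[1:h,        1:w]
    ur <- p[1:h,        3:(w + 2L)]
    dl <- p[3:(h + 2L), 1:w]
    dr <- p[3:(h + 2L), 3:(w + 2L)]
    has_bg <- has_bg | (ul == 0) | (ur == 0) | (dl == 0) | (dr == 0)
  }
  sel <- core == 1 & has_bg
  idx <- which(t(sel))  # transpose for row-major ordering
  cols <- (idx - 1L) %% w
  rows <- (idx - 1L) %/% w
  out <- data.frame(row = as.integer(rows), col = as.integer(cols))
  attr(out, "connectivity") <- connectivity
  out
}

#' Unsigned Euclidean distance map to a boundary point set
#'
#' For every pixel of an `height` x `width` grid, the Euclidean distance (in
#' pixel units) to the nearest point of `boundary`. The transform is exact; it
#' delegates to the exact Euclidean distance transform in \pkg{EBImage}.
#'
#' @param boundary data.frame with 0-based `row`/`col` columns, as returned by
#'   [extract_boundary()]; must be non-empty.
#' @param height,width grid dimensions.
#' @return numeric `height` x `width` matrix of distances (0 on the points).
#' @export
distance_map <- function(boundary, height, width) {
  if (nrow(boundary) == 0L) {
    stop("degenerate mask: boundary is empty, distance map is undefined")
  }
  if (any(boundary$row < 0 | boundary$row >= height |
          boundary$col < 0 | boundary$col >= width)) {
    stop("boundary points fall outside the grid")
  }
  ind <- matrix(1, height, width)
  ind[cbind(boundary$row + 1L, boundary$col + 1L)] <- 0
  d <- EBImage::distmap(ind, metric = "euclidean")
  matrix(as.numeric(d), height, width)
}

#' Signed distance (level-set) map of a binary mask
#'
#' The level-set function of the ground-truth region: its magnitude is the
#' Euclidean distance to the nearest boundary pixel and its sign is negative on
#' interior foreground pixels, positive on background pixels, and zero on the
#' boundary itself. With this convention the boundary-loss integrand
#' `phi * pred` rewards predicted probability mass placed inside the region.
#'
#' @param mask binary matrix containing at least one foreground and one
#'   background pixel.
#' @return numeric matrix of signed distances.
#' @export
signed_distance <- function(mask) {
  assert_binary_mask(mask)
  s <- sum(mask)
  if (s == 0 || s == length(mask)) {
    stop("degenerate mask (all-0 or all-1): signed distance is undefined")
  }
  b <- extract_boundary(mask, connectivity = 4)
  d <- distance_map(b, nrow(mask), ncol(mask))
  ifelse(mask == 1, -d, d)
}
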