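#' @include io_stack.R
NULL

## Pixel membership for curved/polygonal ROIs uses the pixel-center rule:
## pixel (r, c) belongs iff its center, the point (r, c), lies inside or on
## the boundary. No antialiased partial weighting.

.pointsInPolygon <- function(pr, pc, vertices) {
  ## even-odd ray casting, horizontal ray to +col; boundary points count
  ## as inside
  n <- nrow(vertices)
  vr <- vertices[, 1]; vc <- vertices[, 2]
  inside <- logical(length(pr))
  onEdge <- logical(length(pr))
  j <- n
  for (i in seq_len(n)) {
    r1 <- vr[j]; c1 <- vc[j]; r2 <- vr[i]; c2 <- vc[i]
    ## boundary test: point on segment (r1,c1)-(r2,c2)
    dr <- r2 - r1; dc <- c2 - c1
    cross <- (pr - r1) * dc - (pc - c1) * dr
    dot <- (pr - r1) * dr + (pc - c1) * dc
    len2 <- dr * dr + dc * dc
    onEdge <- onEdge | (abs(cross) < 1e-9 * max(1, sqrt(len2)) &
                        dot >= -1e-9 & dot <= len2 + 1e-9)
    ## crossing test (half-open in row to handle vertices exactly once)
    crosses <- ((r1 > pr) != (r2 > pr)) &
      (pc < c1 + (pr - r1) / (r2 - r1) * (c2 - c1))
    crosses[is.na(crosses)] <- FALSE
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | onEdge
}

#' Realize an ROI as a boolean pixel mask
#'
#' Pixels outside the frame are clipped. A pixel belongs to an ellipse or
#' polygon iff its center lies inside or on the boundary; rectangles use
#' their inclusive 1-based row/col bounds.
#'
#' @param roi a \linkS4class{Roi}
#' @param shape frame shape c(rows, cols)
#' @return logical matrix rows x cols
#' @export
makeMask <- function(roi, shape) {
  stopifnot(is(roi, "Roi"), length(shape) == 2, all(shape >= 1))
  validObject(roi)
  rows <- shape[1]; cols <- shape[2]
  g <- roi@geometry
  mask <- matrix(FALSE, rows, cols)
  if (roi@kind == "rectangle") {
    if (g$rows[1] > g$rows[2] || g$cols[1] > g$cols[2])
      stop("rectangle bounds must satisfy first <= last")
    r0 <- max(1, ceiling(g$rows[1])); r1 <- min(rows, floor(g$rows[2]))
    c0 <- max(1, ceiling(g$cols[1])); c1 <- min(cols, floor(g$cols[2]))
    if (r0 > r1 || c0 > c1)
      stop("rectangle does not intersect the frame")
    mask[r0:r1, c0:c1] <- TRUE
  } else {
    pr <- rep(seq_len(rows), times = cols)
    pc <- rep(seq_len(cols), each = rows)
    inside <- if (roi@kind == "ellipse") {
      ((pr - g$center[1]) / g$semiAxes[1])^2 +
        ((pc - g$center[2]) / g$semiAxes[2])^2 <= 1 + 1e-12
    } else {
      .pointsInPolygon(pr, pc, g$vertices)
    }
    mask[cbind(pr[inside], pc[inside])] <- TRUE
  }
  if (!any(mask)) stop("ROI mask is empty after clipping to the frame")
  mask
}

#' Extract the mean-fluorescence trace of an ROI
#'
#' Value i is the arithmetic mean of the frame-i intensities over the mask
#' pixels.
#'
#' @param stack a \linkS4class{FrameStack}
#' @param roi a \linkS4class{Roi} or a logical mask matrix
#' @return a \linkS4class{RawTrace} (label taken from the ROI)
#' @export
extractTrace <- function(stack, roi) {
  stopifnot(is(stack, "FrameStack"))
  label <- ""
  if (is(roi, "Roi")) {
    label <- roi@label
    mask <- makeMask(roi, frameDim(stack))
  } else {
    mask <- roi
    stopifnot(is.logical(mask), all(dim(mask) == frameDim(stack)))
  }
  if (!any(mask)) stop("empty mask")
  idx <- which(mask)
  d <- stack@data
  nf <- dim(d)[1]
  flat <- matrix(d, nrow = nf)  # frames x (rows*cols), column-major pixels
  values <- rowMeans(flat[, idx, drop = FALSE])
  RawTrace(values, rate = stack@rate, label = label)
}

#' Perisomatic background mask (annulus around an ROI)
#'
#' The ROI mask is dilated by \code{width} pixels in the Chebyshev
#' (8-neighbor) metric; the annulus is the dilation minus the ROI itself
#' minus every exclusion mask. Used to sample scattered light from the
#' immediate surround of a cell.
#'
#' @param roi a \linkS4class{Roi} or logical mask
#' @param width annulus width in pixels (>= 1)
#' @param shape frame shape c(rows, cols)
#' @param exclude list of \linkS4class{Roi} or masks to subtract (e.g.
#'   neighboring cells)
#' @return logical matrix rows x cols
#' @export
perisomaticAnnulus <- function(roi, width, shape, exclude = list()) {
  stopifnot(width >= 1)
  toMask <- function(x) if (is(x, "Roi")) makeMask(x, shape) else x
  mask <- toMask(roi)
  dil <- .dilateChebyshev(mask, round(width))
  ann <- dil & !mask
  for (ex in exclude) ann <- ann & !toMask(ex)
  if (!any(ann)) stop("perisomatic annulus is empty (fully occluded)")
  ann
}

## Chebyshev dilation by w: OR of all shifts in [-w, w]^2
.dilateChebyshev <- function(mask, w) {
  rows <- nrow(mask); cols <- ncol(mask)
  out <- matrix(FALSE, rows, cols)
  for (dr in -w:w) {
    rSrc <- max(1, 1 + dr):min(rows, rows + dr)
    rDst <- rSrc - dr
    for (dc in -w:w) {
      cSrc <- max(1, 1 + dc):min(cols, cols + dc)
      cDst <- cSrc - dc
      out[rDst, cDst] <- out[rDst, cDst] | mask[rSrc, cSrc]
    }
  }
  out
}
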