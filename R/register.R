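#' @include preprocess.R
NULL

#' Estimate rigid (translation) movement of every frame
#'
#' For each frame, the integer displacement maximizing the normalized
#' cross-correlation (Pearson, over the overlap region) with the
#' reference image is found by exhaustive search over
#' [-maxShift, maxShift]^2, then refined to subpixel precision by
#' quadratic interpolation of the correlation peak over its 3x3
#' neighborhood.
#'
#' @param stack a \linkS4class{FrameStack} with >= 2 frames
#' @param reference "first", "mean" (mean image) or a frame index
#' @param maxShift largest displacement searched, in pixels
#' @param subpixel apply quadratic peak refinement (skipped automatically
#'   when the integer peak is already a perfect correlation)
#' @return a \linkS4class{ShiftSeries}
#' @export
estimateShifts <- function(stack, reference = "first", maxShift = 5,
                           subpixel = TRUE) {
  stopifnot(is(stack, "FrameStack"))
  nf <- nFrames(stack)
  if (nf < 2) stop("movement estimation needs at least 2 frames")
  refIdx <- NA_integer_
  ref <- if (identical(reference, "first")) {
    refIdx <- 1L
    getFrame(stack, 1)
  } else if (identical(reference, "mean")) {
    apply(stack@data, c(2, 3), mean)
  } else {
    refIdx <- as.integer(reference)
    getFrame(stack, refIdx)
  }
  if (stats::sd(ref) == 0) stop("reference image has zero variance")
  shifts <- matrix(0, nf, 2)
  for (i in seq_len(nf)) {
    fr <- getFrame(stack, i)
    if (stats::sd(fr) == 0) stop(sprintf("frame %d has zero variance", i))
    shifts[i, ] <- .bestShift(ref, fr, maxShift, subpixel)
  }
  new("ShiftSeries", shifts = shifts, reference = refIdx)
}

## NCC between ref and frame displaced by (dr, dc): frame content moved by
## +d relative to ref, compared over the overlap.
.nccAtShift <- function(ref, frame, dr, dc) {
  nr <- nrow(ref); nc <- ncol(ref)
  r1 <- max(1, 1 - dr):min(nr, nr - dr)   # ref rows
  c1 <- max(1, 1 - dc):min(nc, nc - dc)   # ref cols
  a <- ref[r1, c1]
  b <- frame[r1 + dr, c1 + dc]
  if (length(a) < 4) return(-Inf)
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (sa == 0 || sb == 0) return(-Inf)
  stats::cor(as.vector(a), as.vector(b))
}

.bestShift <- function(ref, frame, maxShift, subpixel = TRUE) {
  s <- -maxShift:maxShift
  cc <- matrix(-Inf, length(s), length(s))
  for (i in seq_along(s)) for (j in seq_along(s))
    cc[i, j] <- .nccAtShift(ref, frame, s[i], s[j])
  k <- which(cc == max(cc), arr.ind = TRUE)[1, ]  # earliest tie
  dr <- s[k[1]]; dc <- s[k[2]]
  ## a perfect integer peak cannot be improved on; refining it would only
  ## bias the estimate toward the larger neighbor
  if (!subpixel || cc[k[1], k[2]] >= 1 - 1e-9) return(c(dr, dc))
  ## subpixel: 1-D parabola through the peak and its axis neighbors
  refine <- function(cm, c0, cp) {
    den <- cm - 2 * c0 + cp
    if (!is.finite(den) || den >= 0) return(0)
    max(min(0.5 * (cm - cp) / den, 0.5), -0.5)
  }
  sub <- c(0, 0)
  if (k[1] > 1 && k[1] < length(s) && all(is.finite(cc[k[1] + c(-1, 1), k[2]])))
    sub[1] <- refine(cc[k[1] - 1, k[2]], cc[k[1], k[2]], cc[k[1] + 1, k[2]])
  if (k[2] > 1 && k[2] < length(s) && all(is.finite(cc[k[1], k[2] + c(-1, 1)])))
    sub[2] <- refine(cc[k[1], k[2] - 1], cc[k[1], k[2]], cc[k[1], k[2] + 1])
  c(dr + sub[1], dc + sub[2])
}

#' Undo estimated movement
#'
#' Each frame is translated by minus its displacement using bilinear
#' interpolation; pixels that leave the field of view are filled with the
#' frame's median intensity. The corrected stack is a first-class
#' \linkS4class{FrameStack} and can be written back to TIFF.
#'
#' @param stack a \linkS4class{FrameStack}
#' @param shifts a \linkS4class{ShiftSeries} of matching length
#' @return the corrected \linkS4class{FrameStack}
#' @export
applyShifts <- function(stack, shifts) {
  stopifnot(is(stack, "FrameStack"), is(shifts, "ShiftSeries"))
  if (nrow(shifts@shifts) != nFrames(stack))
    stop("shift series length does not match frame count")
  out <- stack@data
  for (i in seq_len(nFrames(stack))) {
    d <- shifts@shifts[i, ]
    if (all(d == 0)) next
    out[i, , ] <- .translateFrame(stack@data[i, , ], -d[1], -d[2])
  }
  initialize(stack, data = out)
}

## Translate a frame by (dr, dc) (content moves by +dr rows, +dc cols),
## bilinear interpolation, median fill outside.
.translateFrame <- function(frame, dr, dc) {
  nr <- nrow(frame); nc <- ncol(frame)
  fill <- stats::median(frame)
  ## output pixel (r, c) samples input at (r - dr, c - dc)
  rs <- seq_len(nr) - dr
  cs <- seq_len(nc) - dc
  r0 <- floor(rs); c0 <- floor(cs)
  fr <- rs - r0; fc <- cs - c0
  get <- function(ri, ci) {
    ok <- ri >= 1 & ri <= nr
    m <- matrix(fill, nr, nc)
    okc <- ci >= 1 & ci <= nc
    if (any(ok) && any(okc))
      m[ok, okc] <- frame[ri[ok], ci[okc], drop = FALSE]
    m
  }
  w00 <- outer(1 - fr, 1 - fc)
  w01 <- outer(1 - fr, fc)
  w10 <- outer(fr, 1 - fc)
  w11 <- outer(fr, fc)
  w00 * get(r0, c0) + w01 * get(r0, c0 + 1) +
    w10 * get(r0 + 1, c0) + w11 * get(r0 + 1, c0 + 1)
}
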