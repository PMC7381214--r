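## Shared fixtures and independent oracles, built in code at test time.

## quick ProcessedTrace builder (bypasses the pipeline for unit tests)
processed <- function(values, rate, label = "") {
  new("ProcessedTrace", values = as.numeric(values), rate = rate,
      label = label, steps = list(list(op = "dff", params = list())),
      inverted = FALSE)
}

## independent even-odd ray-casting point-in-polygon oracle (scalar,
## horizontal ray toward +col; boundary points count as inside)
pipOracle <- function(pr, pc, vertices) {
  n <- nrow(vertices)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    r1 <- vertices[j, 1]; c1 <- vertices[j, 2]
    r2 <- vertices[i, 1]; c2 <- vertices[i, 2]
    ## boundary check
    dr <- r2 - r1; dc <- c2 - c1
    len2 <- dr^2 + dc^2
    if (len2 > 0) {
      tt <- ((pr - r1) * dr + (pc - c1) * dc) / len2
      if (tt >= 0 && tt <= 1) {
        dist <- sqrt((pr - (r1 + tt * dr))^2 + (pc - (c1 + tt * dc))^2)
        if (dist < 1e-9) return(TRUE)
      }
    }
    if ((r1 > pr) != (r2 > pr)) {
      xint <- c1 + (pr - r1) / (r2 - r1) * (c2 - c1)
      if (pc < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

## brute-force spike oracle: enumerate supra-threshold runs, one spike
## per run at its argmax (earliest tie)
spikeOracle <- function(v, thr) {
  above <- v > thr
  peaks <- integer(0)
  i <- 1L; n <- length(v)
  while (i <= n) {
    if (above[i]) {
      j <- i
      while (j < n && above[j + 1L]) j <- j + 1L
      seg <- i:j
      peaks <- c(peaks, seg[which.max(v[seg])])
      i <- j + 1L
    } else i <- i + 1L
  }
  peaks
}

## exhaustive integer-shift NCC oracle
shiftOracle <- function(ref, frame, maxShift) {
  best <- c(NA, NA); bestC <- -Inf
  for (dr in -maxShift:maxShift) for (dc in -maxShift:maxShift) {
    nr <- nrow(ref); nc <- ncol(ref)
    r1 <- max(1, 1 - dr):min(nr, nr - dr)
    c1 <- max(1, 1 - dc):min(nc, nc - dc)
    a <- as.vector(ref[r1, c1]); b <- as.vector(frame[r1 + dr, c1 + dc])
    if (length(a) < 4 || sd(a) == 0 || sd(b) == 0) next
    cc <- cor(a, b)
    if (cc > bestC) { bestC <- cc; best <- c(dr, dc) }
  }
  best
}

## O(n^2) spike-correlogram oracle
spikeXcorrOracle <- function(ta, tb, maxLag, binWidth) {
  M <- round(maxLag / binWidth)
  counts <- setNames(numeric(2 * M + 1), as.character(-M:M))
  for (x in ta) for (y in tb) {
    d <- y - x
    if (abs(d) <= maxLag) {
      m <- min(max(round(d / binWidth), -M), M)
      counts[as.character(m)] <- counts[as.character(m)] + 1
    }
  }
  unname(counts)
}
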