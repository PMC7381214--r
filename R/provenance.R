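#' @include accessors.R
NULL

## Preprocessing stage ranks. The pipeline contract is
## crop -> background -> baseline/dF/F -> filter -> resample; applying a
## stage after a later one is an ordering error. Repeating a stage
## (e.g. crop twice, or several filters) is allowed.
.STAGE_RANK <- c(crop = 1, background = 2, baseline = 3, dff = 3,
                 filter = 4, smooth = 4, resample = 5, align = 6)

.stageOf <- function(op) {
  r <- .STAGE_RANK[[op]]
  if (is.null(r)) stop(sprintf("unknown pipeline operation '%s'", op))
  r
}

## Append a provenance step after checking the pipeline ordering.
.addStep <- function(steps, op, params = list()) {
  newRank <- .stageOf(op)
  for (s in steps) {
    if (.stageOf(s$op) > newRank)
      stop(sprintf(paste0(
        "pipeline ordering violated: '%s' cannot be applied after '%s' ",
        "(required order: crop -> background -> baseline/dff -> filter -> ",
        "resample)"), op, s$op))
  }
  c(steps, list(list(op = op, params = params)))
}

## Rebuild a trace of the same class with new values/steps.
.withValues <- function(x, values, rate = x@rate, steps = x@steps) {
  initialize(x, values = as.numeric(values), rate = rate, steps = steps)
}
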