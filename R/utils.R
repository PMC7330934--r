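# internal helpers shared across the package

stopf <- function(fmt, ..., class = "ihcquant_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}

validation_error <- function(fmt, ...) {
  stopf(fmt, ..., class = c("ihcquant_validation_error", "ihcquant_error"))
}

io_error <- function(fmt, ...) {
  stopf(fmt, ..., class = c("ihcquant_io_error", "ihcquant_error"))
}

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    validation_error("`%s` must be a single finite number", name)
  if (positive && x <= 0)
    validation_error("`%s` must be > 0 (got %g)", name, x)
  invisible(x)
}

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so library code never perturbs the global stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# binary dilation of a logical matrix by a (2r+1)x(2r+1) square structuring
# element, done with shifted copies (fast enough for the small radii used)
dilate_mask <- function(mask, radius = 1L) {
  if (radius < 1L) return(mask)
  H <- nrow(mask); W <- ncol(mask)
  out <- mask
  for (dr in -radius:radius) {
    rs <- max(1L, 1L + dr):min(H, H + dr)
    rt <- max(1L, 1L - dr):min(H, H - dr)
    for (dc in -radius:radius) {
      if (dr == 0L && dc == 0L) next
      cs <- max(1L, 1L + dc):min(W, W + dc)
      ct <- max(1L, 1L - dc):min(W, W - dc)
      out[rt, ct] <- out[rt, ct] | mask[rs, cs]
    }
  }
  out
}
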