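#' Stain matrix for optical-density colour deconvolution
#'
#' Absorbances of stains combine approximately additively in optical
#' density (Beer-Lambert), so the per-pixel OD vector is modelled as
#' `OD = M %*% c` where the columns of `M` are unit OD direction vectors of
#' the individual stains and `c` their concentrations. Deconvolution
#' inverts this 3x3 system per pixel.
#'
#' @param vectors 3 x n numeric matrix, one column per stain (n in 1..3);
#'   columns are normalized to unit Euclidean norm on construction. When
#'   fewer than 3 stains are given the matrix is completed to 3 columns
#'   with the normalized cross product (and, for a single stain, an
#'   orthogonal complement), so the system is square and invertible.
#' @param names character vector of stain names matching the columns.
#' @return Object of class `stain_matrix`: `$M` (3 x 3, columns unit norm)
#'   and `$names` (length 3).
#' @examples
#' sm <- default_stain_matrix()
#' colnames(sm$M)
#' @export
stain_matrix <- function(vectors, names = colnames(vectors)) {
  vectors <- as.matrix(vectors)
  if (nrow(vectors) != 3L || ncol(vectors) < 1L || ncol(vectors) > 3L)
    validation_error("`vectors` must be a 3 x n matrix with n in 1..3")
  if (any(vectors < 0))
    validation_error("stain OD vectors must have non-negative entries")
  if (is.null(names)) names <- paste0("stain", seq_len(ncol(vectors)))
  nrm <- sqrt(colSums(vectors^2))
  if (any(nrm == 0)) validation_error("stain vectors must be nonzero")
  M <- sweep(vectors, 2, nrm, "/")
  if (ncol(M) == 1L) {
    # complete with an arbitrary unit vector not collinear with the stain
    e <- if (abs(M[1, 1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v2 <- e - sum(e * M[, 1]) * M[, 1]
    M <- cbind(M, v2 / sqrt(sum(v2^2)))
    names <- c(names, "complement")
  }
  if (ncol(M) == 2L) {
    v3 <- c(M[2, 1] * M[3, 2] - M[3, 1] * M[2, 2],
            M[3, 1] * M[1, 2] - M[1, 1] * M[3, 2],
            M[1, 1] * M[2, 2] - M[2, 1] * M[1, 2])
    n3 <- sqrt(sum(v3^2))
    if (n3 < 1e-12)
      validation_error("stain vectors are collinear; cannot complete matrix")
    M <- cbind(M, abs(v3) / n3)
    names <- c(names, "residual")
  }
  if (abs(det(M)) < 1e-12 || !is.finite(kappa(M)))
    validation_error("stain matrix is singular or ill-conditioned")
  colnames(M) <- names
  rownames(M) <- c("R", "G", "B")
  structure(list(M = M, names = names), class = "stain_matrix")
}

#' @rdname stain_matrix
#' @details `default_stain_matrix()` pairs Harris hematoxylin with a fast
#'   red type chromogen (alkaline-phosphatase red reaction product) and a
#'   residual channel; override the vectors for other chromogens (e.g.
#'   DAB).
#' @export
default_stain_matrix <- function() {
  stain_matrix(cbind(counterstain = c(0.650, 0.704, 0.286),
                     chromogen = c(0.214, 0.851, 0.478)))
}

#' @export
print.stain_matrix <- function(x, ...) {
  cat("<stain_matrix>\n")
  print(round(x$M, 4))
  invisible(x)
}

OD_I0 <- 255
OD_EPS <- 1 / 255

#' RGB to optical density
#'
#' `OD_c = -log10((I_c + eps) / I0)` per channel with `I0 = 255` and
#' `eps = 1/255` guarding `log(0)`; values are floored at 0 so a pure-white
#' pixel maps exactly to the zero vector. OD is monotone decreasing in
#' intensity.
#'
#' @param image a [calibrated_image()] or an `H x W x 3` array in
#'   `[0, 255]`.
#' @return Numeric `H x W x 3` array of optical densities (>= 0).
#' @export
rgb_to_od <- function(image) {
  px <- if (inherits(image, "calibrated_image")) image$pixels else image
  if (!is.array(px) || length(dim(px)) != 3L)
    validation_error("`image` must be a calibrated_image or H x W x 3 array")
  od <- -log10((px + OD_EPS) / OD_I0)
  od[od < 0] <- 0
  od
}

#' Optical density to 8-bit RGB
#'
#' Inverse of [rgb_to_od()] up to integer rounding.
#'
#' @param od numeric `H x W x 3` array of optical densities.
#' @return Integer `H x W x 3` array in `[0, 255]`.
#' @export
od_to_rgb <- function(od) {
  px <- round(OD_I0 * 10^(-od) - OD_EPS)
  px[px < 0] <- 0
  px[px > 255] <- 255
  storage.mode(px) <- "integer"
  px
}

#' Colour deconvolution
#'
#' Solves the linear stain mixing model `OD = M %*% c` for every pixel,
#' yielding one concentration plane per stain. Concentrations can be
#' (slightly) negative under noise; they are stored unclipped so that
#' re-mixing with [remix()] reconstructs the OD exactly.
#'
#' @param od `H x W x 3` OD array (from [rgb_to_od()]).
#' @param stains a [stain_matrix()].
#' @return Numeric `H x W x 3` array; the third dimension is named by
#'   stain.
#' @export
deconvolve <- function(od, stains = default_stain_matrix()) {
  stopifnot(inherits(stains, "stain_matrix"))
  if (!is.array(od) || length(dim(od)) != 3L || dim(od)[3] != 3L)
    validation_error("`od` must be an H x W x 3 array")
  Minv <- tryCatch(solve(stains$M), error = function(e)
    validation_error("stain matrix is singular"))
  d <- dim(od)
  flat <- matrix(od, d[1] * d[2], 3L) # pixels x channels
  conc <- flat %*% t(Minv)
  out <- array(conc, c(d[1], d[2], 3L),
               dimnames = list(NULL, NULL, stains$names))
  out
}

#' Re-mix concentrations back to optical density
#'
#' @param conc `H x W x 3` concentration array from [deconvolve()].
#' @param stains the same [stain_matrix()] used to deconvolve.
#' @return `H x W x 3` OD array; `remix(deconvolve(od, S), S)` equals `od`
#'   to numerical precision.
#' @export
remix <- function(conc, stains = default_stain_matrix()) {
  stopifnot(inherits(stains, "stain_matrix"))
  d <- dim(conc)
  flat <- matrix(conc, d[1] * d[2], 3L)
  array(flat %*% t(stains$M), d)
}

#' Otsu threshold
#'
#' Maximizes the between-class variance over a 256-bin histogram of the
#' finite values; returns the bin edge separating the two classes.
#'
#' @param x numeric vector/matrix of values.
#' @param n_bins number of histogram bins.
#' @return The threshold (scalar).
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  v <- x[is.finite(x)]
  if (length(v) == 0L) validation_error("no finite values to threshold")
  lo <- min(v); hi <- max(v)
  if (lo == hi)
    validation_error(
      "channel is constant (value %g); Otsu is undefined - use a fixed threshold",
      lo)
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  counts <- as.numeric(
    tabulate(pmin(findInterval(v, edges, all.inside = TRUE), n_bins),
             nbins = n_bins))
  mids <- (edges[-1L] + edges[-(n_bins + 1L)]) / 2
  w <- cumsum(counts)
  m <- cumsum(counts * mids)
  total_w <- w[n_bins]
  total_m <- m[n_bins]
  w0 <- w[-n_bins]; m0 <- m[-n_bins]
  w1 <- total_w - w0
  valid <- w0 > 0 & w1 > 0
  between <- rep(-Inf, n_bins - 1L)
  between[valid] <- (total_m * w0 - m0 * total_w)[valid]^2 /
    (w0 * w1)[valid]
  k <- which.max(between)
  edges[k + 1L]
}

#' Binarize a concentration channel
#'
#' @param channel numeric `H x W` matrix (one plane of a deconvolved
#'   image). Negative values are treated as 0 for thresholding only.
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param fixed_threshold required when `method = "fixed"`.
#' @return List with `mask` (logical `H x W`, `TRUE` = stained) and
#'   `threshold` (the value actually applied).
#' @export
binarize <- function(channel, method = c("otsu", "fixed"),
                     fixed_threshold = NULL) {
  method <- match.arg(method)
  if (!is.matrix(channel)) {
    if (is.array(channel) && length(dim(channel)) == 3L && dim(channel)[3] == 1L)
      channel <- channel[, , 1L]
    else validation_error("`channel` must be an H x W matrix")
  }
  ch <- pmax(channel, 0)
  thr <- if (method == "otsu") otsu_threshold(ch) else {
    if (is.null(fixed_threshold))
      validation_error("method 'fixed' requires `fixed_threshold`")
    assert_scalar_number(fixed_threshold, "fixed_threshold")
    fixed_threshold
  }
  list(mask = ch > thr, threshold = thr, method = method)
}
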