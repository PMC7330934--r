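# Independent brute-force oracles used to cross-check the implementation.

# queue-based flood fill labelling; deliberately naive
flood_fill_label <- function(mask, connectivity = 8L) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  offs <- if (connectivity == 8L)
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  nxt <- 0L
  for (c0 in seq_len(W)) for (r0 in seq_len(H)) {
    if (!mask[r0, c0] || lab[r0, c0] > 0L) next
    nxt <- nxt + 1L
    queue <- list(c(r0, c0))
    lab[r0, c0] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(offs))) {
        r <- p[1] + offs[k, 1]; c <- p[2] + offs[k, 2]
        if (r >= 1 && r <= H && c >= 1 && c <= W &&
            mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- nxt
          queue[[length(queue) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# per-pixel least-squares deconvolution (no shared code with deconvolve)
deconvolve_oracle <- function(od, M) {
  d <- dim(od)
  out <- array(NA_real_, d)
  for (r in seq_len(d[1])) for (c in seq_len(d[2])) {
    out[r, c, ] <- qr.solve(M, od[r, c, ])
  }
  out
}

# full 2^n enumeration of the Wilcoxon signed-rank null distribution
wilcoxon_oracle <- function(pairs) {
  d <- pairs[, 1] - pairs[, 2]
  d <- d[d != 0]
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- signs %*% r
  p_le <- mean(vs <= v + 1e-12)
  p_ge <- mean(vs >= v - 1e-12)
  list(statistic = v, p_value = min(1, 2 * min(p_le, p_ge)))
}

# random full-rank stain matrix with non-negative unit columns
random_stain_matrix <- function() {
  repeat {
    m <- matrix(stats::runif(9, 0.05, 1), 3, 3)
    m <- sweep(m, 2, sqrt(colSums(m^2)), "/")
    if (abs(det(m)) > 0.05) return(stain_matrix(m, c("counterstain", "chromogen", "residual")))
  }
}

quantify_count <- function(scene, config = default_config()) {
  run <- run_quantify(scene$image, config, exclusion = scene$exclusion_mask)
  run$results$n_cells[run$results$region == "full"]
}
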