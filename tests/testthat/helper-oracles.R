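# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# IoU of two masks by an explicit double loop over pixels
naive_iou <- function(a, b) {
  inter <- 0L; uni <- 0L
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(ncol(a))) {
      if (a[i, j] && b[i, j]) inter <- inter + 1L
      if (a[i, j] || b[i, j]) uni <- uni + 1L
    }
  }
  inter / uni
}

# exhaustive Otsu: argmax of between-class variance over all 256 thresholds
# on quantized levels 0..255 (smallest maximizing threshold)
brute_otsu <- function(q) {
  q <- as.integer(q)
  n <- length(q)
  best_t <- NA_integer_; best_v <- -Inf
  for (t in 0:254) {
    lo <- q[q <= t]; hi <- q[q > t]
    if (!length(lo) || !length(hi)) next
    v <- (length(lo) / n) * (length(hi) / n) * (mean(lo) - mean(hi))^2
    if (v > best_v + 1e-12) { best_v <- v; best_t <- t }
  }
  best_t
}

# recursive-free flood-fill component count, 8-connectivity
brute_component_count <- function(mask) {
  seen <- matrix(FALSE, nrow(mask), ncol(mask))
  count <- 0L
  for (i in seq_len(nrow(mask))) {
    for (j in seq_len(ncol(mask))) {
      if (!mask[i, j] || seen[i, j]) next
      count <- count + 1L
      stack <- list(c(i, j)); seen[i, j] <- TRUE
      while (length(stack)) {
        p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        for (di in -1:1) for (dj in -1:1) {
          ii <- p[1] + di; jj <- p[2] + dj
          if (ii >= 1 && ii <= nrow(mask) && jj >= 1 && jj <= ncol(mask) &&
              mask[ii, jj] && !seen[ii, jj]) {
            seen[ii, jj] <- TRUE
            stack[[length(stack) + 1]] <- c(ii, jj)
          }
        }
      }
    }
  }
  count
}

# boundary-pixel count: foreground pixels with a 4-neighbour outside the mask
brute_perimeter <- function(mask) {
  n <- 0L
  nr <- nrow(mask); nc <- ncol(mask)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (!mask[i, j]) next
      nb <- c(if (i > 1) mask[i - 1, j] else FALSE,
              if (i < nr) mask[i + 1, j] else FALSE,
              if (j > 1) mask[i, j - 1] else FALSE,
              if (j < nc) mask[i, j + 1] else FALSE)
      if (!all(nb)) n <- n + 1L
    }
  }
  n
}

# majority vote of the k x k neighbourhood with reflect padding, one pixel
brute_binary_median_at <- function(mask, i, j, k) {
  h <- k %/% 2
  # edge-repeating reflection in 1-based indices: 0 -> 1, -1 -> 2,
  # n+1 -> n, n+2 -> n-1
  refl <- function(x, n) {
    while (x < 1 || x > n) {
      if (x < 1) x <- 1 - x
      if (x > n) x <- 2 * n + 1 - x
    }
    x
  }
  cnt <- 0L
  for (di in -h:h) for (dj in -h:h) {
    cnt <- cnt + mask[refl(i + di, nrow(mask)), refl(j + dj, ncol(mask))]
  }
  cnt > k * k / 2
}

# exact two-sided Fisher p by hypergeometric enumeration at fixed margins
brute_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(a) dhyper(a, r1, r2, c1), 0)
  obs <- dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# exact two-sided Mann-Whitney p by full enumeration over group assignments
brute_mwu_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  idx <- combn(na + nb, na)
  u_all <- apply(idx, 2, function(ix) sum(r[ix])) - na * (na + 1) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# digital disk mask (pixel-center rule, 0-based center)
digital_disk <- function(dims, center, radius) {
  dy <- matrix(0:(dims[1] - 1) - center[1], dims[1], dims[2])
  dx <- matrix(0:(dims[2] - 1) - center[2], dims[1], dims[2], byrow = TRUE)
  sqrt(dy^2 + dx^2) <= radius
}

# strip image_frame attributes for plain matrix comparisons
as_mat <- function(f) matrix(as.numeric(f), nrow(f), ncol(f))

# minimal stand-in chromatin object for tracking tests
fake_object <- function(area, row, col, frame = 0L) {
  structure(list(mask = NULL, area_px2 = area, area_um2 = area * 0.11^2,
                 centroid = c(row = row, col = col),
                 frame_index = as.integer(frame)),
            class = "chromatin_object")
}
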