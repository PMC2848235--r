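# Geometry fixtures ---------------------------------------------------------

# filled disc as a logical matrix, 0-based center (cy = row, cx = col)
fix_disc <- function(nr, nc, cy, cx, r) {
  m <- matrix(FALSE, nr, nc)
  m[outer((seq_len(nr) - 1 - cy)^2, (seq_len(nc) - 1 - cx)^2, "+") <= r^2] <- TRUE
  m
}

fix_discs <- function(nr, nc, centers, radii) {
  m <- matrix(FALSE, nr, nc)
  for (k in seq_len(nrow(centers)))
    m <- m | fix_disc(nr, nc, centers[k, 1], centers[k, 2], radii[k])
  m
}

# annulus (ring) fixture
fix_annulus <- function(nr, nc, cy, cx, r_in, r_out) {
  fix_disc(nr, nc, cy, cx, r_out) & !fix_disc(nr, nc, cy, cx, r_in)
}

# Independent oracles --------------------------------------------------------

# flood-fill 8-connected labeling, plain R
oracle_label8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    nxt <- nxt + 1L
    stack <- list(c(i, j)); lab[i, j] <- nxt
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (di in -1:1) for (dj in -1:1) {
        ii <- p[1] + di; jj <- p[2] + dj
        if (ii >= 1 && jj >= 1 && ii <= nr && jj <= nc &&
            mask[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- nxt
          stack[[length(stack) + 1L]] <- c(ii, jj)
        }
      }
    }
  }
  lab
}

# naive Otsu: minimize the weighted within-class variance over all cuts
oracle_otsu <- function(counts) {
  y <- 0:255
  wcv <- rep(Inf, 255)
  for (t in 0:254) {
    lo <- counts[y <= t]; ylo <- y[y <= t]
    hi <- counts[y > t]; yhi <- y[y > t]
    v <- 0
    if (sum(lo) > 0) {
      m <- sum(lo * ylo) / sum(lo)
      v <- v + sum(lo * (ylo - m)^2)
    }
    if (sum(hi) > 0) {
      m <- sum(hi * yhi) / sum(hi)
      v <- v + sum(hi * (yhi - m)^2)
    }
    wcv[t + 1] <- v
  }
  # same plateau-midpoint tie rule as the implementation: cuts inside an
  # unpopulated gap produce bit-identical objective values
  cand <- which(wcv <= min(wcv) + 1e-9) - 1L
  cand[(length(cand) + 1L) %/% 2L]
}

# naive 3-class Otsu: minimize within-class variance over all cut pairs
oracle_multiotsu <- function(counts) {
  y <- 0:255
  seg_wcv <- function(sel) {
    w <- counts[sel]
    if (sum(w) == 0) return(0)
    m <- sum(w * y[sel]) / sum(w)
    sum(w * (y[sel] - m)^2)
  }
  # precompute single-segment costs over contiguous ranges via direct sums
  best <- Inf; best_cuts <- c(NA, NA)
  for (t1 in 0:253) {
    c0 <- seg_wcv(y <= t1)
    for (t2 in (t1 + 1):254) {
      v <- c0 + seg_wcv(y > t1 & y <= t2) + seg_wcv(y > t2)
      if (v < best) { best <- v; best_cuts <- c(t1, t2) }
    }
  }
  best_cuts
}

# pixel-level EM for a univariate Gaussian mixture, independent of the
# package's histogram-weighted implementation (same initialization rule)
oracle_pixel_em <- function(pixels, n_classes, tol = 1e-4, max_iter = 500) {
  y <- as.numeric(pixels)
  part <- ceiling((floor(y) + 1) / (256 / n_classes))
  mu <- vapply(seq_len(n_classes), function(k) {
    sel <- part == k
    if (any(sel)) mean(y[sel]) else (k - 0.5) * 256 / n_classes
  }, numeric(1))
  sigma <- rep(max(y), n_classes)
  pk <- rep(1 / n_classes, n_classes)
  ll_prev <- -Inf
  for (it in seq_len(max_iter)) {
    ld <- vapply(seq_len(n_classes),
                 function(k) log(pk[k]) + dnorm(y, mu[k], sigma[k], log = TRUE),
                 numeric(length(y)))
    m <- apply(ld, 1, max)
    r <- exp(ld - m); r <- r / rowSums(r)
    for (k in seq_len(n_classes)) {
      nk <- sum(r[, k])
      pk[k] <- nk / length(y)
      mu[k] <- sum(r[, k] * y) / nk
      sigma[k] <- max(sqrt(sum(r[, k] * (y - mu[k])^2) / nk), 0.5)
    }
    pk <- pk / sum(pk)
    ll <- sum(m + log(rowSums(exp(ld - m))))
    if (it > 1 && abs(ll - ll_prev) < tol) break
    ll_prev <- ll
  }
  ord <- order(mu)
  list(mu = mu[ord], sigma = sigma[ord], pi = pk[ord])
}

# histogram sampled from a Gaussian mixture (counts over 0..255)
sample_mixture_hist <- function(n, mu, sigma, pi) {
  z <- sample.int(length(mu), n, replace = TRUE, prob = pi)
  v <- pmin(pmax(round(rnorm(n, mu[z], sigma[z])), 0), 255)
  tabulate(v + 1L, nbins = 256L)
}

# Printed-table agreement: a printed value matches a raw ratio when it is
# its rounding OR its truncation at the printed number of decimals (the
# reference tables were typeset with an inconsistent mix of the two).
agrees_with_printed <- function(raw, printed) {
  txt <- format(printed, drop0trailing = TRUE, scientific = FALSE)
  dec <- ifelse(grepl("\\.", txt), nchar(sub("^[^.]*\\.", "", txt)), 0L)
  p <- 10^dec
  rounded <- floor(raw * p + 0.5) / p
  truncated <- floor(raw * p) / p
  abs(rounded - printed) < 1e-9 | abs(truncated - printed) < 1e-9
}
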