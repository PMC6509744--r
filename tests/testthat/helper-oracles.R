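# Independent reference implementations used as oracles.  These are written
# as direct, scalar, textbook transcriptions on purpose: they share no code
# with the package internals they check.

# Reference sRGB (IEC 61966-2-1, D65) -> CIELAB for one pixel, using the
# textbook white point (0.95047, 1, 1.08883).
oracle_srgb_to_lab <- function(r, g, b) {
  degamma <- function(u) {
    u <- u / 255
    if (u <= 0.04045) u / 12.92 else ((u + 0.055) / 1.055)^2.4
  }
  rl <- degamma(r); gl <- degamma(g); bl <- degamma(b)
  X <- 0.4124564 * rl + 0.3575761 * gl + 0.1804375 * bl
  Y <- 0.2126729 * rl + 0.7151522 * gl + 0.0721750 * bl
  Z <- 0.0193339 * rl + 0.1191920 * gl + 0.9503041 * bl
  f <- function(t) if (t > (6 / 29)^3) t^(1 / 3) else t / (3 * (6 / 29)^2) + 4 / 29
  fx <- f(X / 0.95047); fy <- f(Y / 1); fz <- f(Z / 1.08883)
  c(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
}

# Brute-force Otsu: minimise the weighted within-class variance over every
# split of a 256-bin histogram, by direct evaluation.
oracle_otsu <- function(counts) {
  counts <- as.numeric(counts)
  vals <- 0:255
  best_t <- NA_integer_
  best_wcv <- Inf
  for (t in 0:254) {
    lo <- counts[1:(t + 1)]; hi <- counts[(t + 2):256]
    vlo <- vals[1:(t + 1)]; vhi <- vals[(t + 2):256]
    n0 <- sum(lo); n1 <- sum(hi)
    if (n0 == 0 || n1 == 0) next
    m0 <- sum(lo * vlo) / n0; m1 <- sum(hi * vhi) / n1
    v0 <- sum(lo * (vlo - m0)^2) / n0
    v1 <- sum(hi * (vhi - m1)^2) / n1
    wcv <- (n0 * v0 + n1 * v1) / (n0 + n1)
    if (wcv < best_wcv - 1e-12) {   # strict improvement: lowest bin on ties
      best_wcv <- wcv
      best_t <- t
    }
  }
  best_t
}

# Recursive flood fill connected-component count (oracle for small masks).
oracle_count_components <- function(fg, connectivity = 8) {
  h <- nrow(fg); w <- ncol(fg)
  seen <- matrix(FALSE, h, w)
  offs <- if (connectivity == 4) rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
          else expand.grid(dr = -1:1, dc = -1:1)[-5, ]
  n <- 0L
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (!fg[i, j] || seen[i, j]) next
    n <- n + 1L
    stack <- list(c(i, j)); seen[i, j] <- TRUE
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(offs))) {
        r <- p[1] + offs[k, 1]; cc <- p[2] + offs[k, 2]
        if (r >= 1 && r <= h && cc >= 1 && cc <= w && fg[r, cc] && !seen[r, cc]) {
          seen[r, cc] <- TRUE
          stack[[length(stack) + 1L]] <- c(r, cc)
        }
      }
    }
  }
  n
}

# Closed-form normalised 2-D Gaussian kernel response to a unit impulse.
oracle_gauss_response <- function(dr, dc, sigma, half_width) {
  w1 <- exp(-(-half_width:half_width)^2 / (2 * sigma^2))
  w1 <- w1 / sum(w1)
  ix <- function(d) if (abs(d) > half_width) 0 else w1[d + half_width + 1]
  ix(dr) * ix(dc)
}

# Closed-form OLS via the normal equations.
oracle_ols <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  c(slope = slope, intercept = mean(y) - slope * mean(x))
}

# Shared fixture: a small scene + config used by several test files.
make_test_config <- function(...) pipeline_config(pixels_per_cm = 5, ...)
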