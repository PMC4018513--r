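# Independent oracles used across tests. These deliberately use different
# algorithms from the package implementation.

# Non-negative LASSO by projected cyclic coordinate descent, for a fixed
# lambda: min ||y - Xb||^2 + lambda * sum(b), b >= 0.
cd_nnlasso <- function(X, y, lambda, iters = 50000, tol = 1e-13) {
  p <- ncol(X)
  b <- numeric(p)
  G <- crossprod(X)
  Xty <- drop(crossprod(X, y))
  for (it in seq_len(iters)) {
    b_old <- b
    for (i in seq_len(p)) {
      r <- Xty[i] - sum(G[i, -i] * b[-i])
      b[i] <- max(0, (r - lambda / 2) / G[i, i])
    }
    if (sum(abs(b - b_old)) < tol) break
  }
  b
}

# Aggregated isotope distribution by joint enumeration over heavy-isotope
# counts of every element (multinomial probabilities), rather than by
# sequential convolution. comp: named integer counts of C,H,N,O,S.
enumerate_isotope_dist <- function(comp, max_shift = 12) {
  # per element: enumerate counts of each heavy isotope up to max_shift
  abunds <- list(
    C = c(0.9893, 0.0107), H = c(0.999885, 0.000115),
    N = c(0.99636, 0.00364), O = c(0.99757, 0.00038, 0.00205),
    S = c(0.9499, 0.0075, 0.0425, 0, 0.0001)
  )
  total <- numeric(max_shift + 1)
  # element-wise tables of P(shift = s) computed by explicit enumeration
  elem_table <- function(ab, n) {
    shifts <- seq_along(ab) - 1L
    probs <- ab / sum(ab)
    out <- numeric(max_shift + 1)
    heavy <- which(shifts > 0 & probs > 0)
    # enumerate counts k of each heavy isotope jointly (at most 2 heavies/elem)
    if (length(heavy) == 0 || n == 0) {
      out[1] <- 1
      return(out)
    }
    k_max <- pmin(n, ceiling(max_shift / shifts[heavy]))
    grid <- expand.grid(lapply(k_max, function(k) 0:k))
    for (r in seq_len(nrow(grid))) {
      ks <- as.numeric(grid[r, ])
      if (sum(ks) > n) next
      s <- sum(ks * shifts[heavy])
      if (s > max_shift) next
      # multinomial probability
      lp <- lgamma(n + 1) - sum(lgamma(ks + 1)) - lgamma(n - sum(ks) + 1) +
        sum(ks * log(probs[heavy])) + (n - sum(ks)) * log(probs[shifts == 0])
      out[s + 1] <- out[s + 1] + exp(lp)
    }
    out
  }
  tabs <- lapply(names(abunds), function(el) {
    elem_table(abunds[[el]], as.integer(round(comp[[el]] %||% 0)))
  })
  # combine by enumerating shift partitions across the five elements
  total <- tabs[[1]]
  for (t2 in tabs[-1]) {
    new <- numeric(max_shift + 1)
    for (a in 0:max_shift) {
      for (b in 0:(max_shift - a)) {
        new[a + b + 1] <- new[a + b + 1] + total[a + 1] * t2[b + 1]
      }
    }
    total <- new
  }
  total / max(total)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# densest fixed-width window mode by brute force over all pairs
densest_window_mode <- function(errors, width) {
  errors <- sort(errors)
  best_n <- -1
  best_center <- NA
  for (i in seq_along(errors)) {
    inside <- errors[errors >= errors[i] & errors <= errors[i] + width]
    if (length(inside) > best_n) {
      best_n <- length(inside)
      best_center <- median(inside)
    }
  }
  best_center
}

# small synthetic segment: sampled peak intensities for a few Averagine
# patterns plus Gaussian noise, on their theoretical m/z positions
make_segment <- function(masses, charges, abundances, snr = 20, seed = 1) {
  set.seed(seed)
  pats <- mapply(function(m, z) averagine_pattern(m, z, 0.01),
                 masses, charges, SIMPLIFY = FALSE)
  mz <- sort(unique(unlist(lapply(pats, function(p)
    p$mono_mz + (seq_along(p$intensities) - 1) * p$spacing))))
  y <- numeric(length(mz))
  for (k in seq_along(pats)) {
    p <- pats[[k]]
    pos <- p$mono_mz + (seq_along(p$intensities) - 1) * p$spacing
    idx <- match(round(pos, 9), round(mz, 9))
    y[idx] <- y[idx] + abundances[k] * p$intensities
  }
  y <- pmax(y + rnorm(length(y), 0, max(abundances) / snr), 0)
  list(mz = mz, intensity = y, patterns = pats)
}
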