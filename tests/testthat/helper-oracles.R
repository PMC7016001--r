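# Independent brute-force oracles used across the test files. These are
# deliberately naive (per-pixel loops, dense grids, exhaustive
# enumeration) and share no code with the package internals they check.

# one-pixel 8-neighbourhood erosion, pixel by pixel
erode_oracle <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!mask[r, c]) next
    keep <- TRUE
    for (dr in -1:1) for (dc in -1:1) {
      rr <- r + dr; cc <- c + dc
      if (rr < 1 || rr > nr || cc < 1 || cc > nc || !mask[rr, cc])
        keep <- FALSE
    }
    out[r, c] <- keep
  }
  out
}

# per-pixel column-third classification by pixel centre
thirds_oracle <- function(mask, apex_side = "left") {
  cols <- which(colSums(mask) > 0)
  x_min <- min(cols); x_max <- max(cols)
  w <- x_max + 1 - x_min
  out <- matrix(0L, nrow(mask), ncol(mask))
  for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask))) {
    if (!mask[r, c]) next
    f <- (c + 0.5 - x_min) / w
    z <- if (f <= 1 / 3) 1L else if (f <= 2 / 3) 2L else 3L
    if (apex_side == "right") z <- 4L - z
    out[r, c] <- z
  }
  out
}

# random blob mask: union of a few filled ellipses on a small grid
random_blob_mask <- function(nr = 32, nc = 32) {
  repeat {
    m <- matrix(FALSE, nr, nc)
    for (i in seq_len(sample(2:4, 1))) {
      cx <- runif(1, 6, nc - 6); cy <- runif(1, 6, nr - 6)
      ax <- runif(1, 3, 8); ay <- runif(1, 3, 8)
      for (r in seq_len(nr)) for (c in seq_len(nc))
        if (((c - cx) / ax)^2 + ((r - cy) / ay)^2 <= 1) m[r, c] <- TRUE
    }
    cols <- which(colSums(m) > 0)
    if (length(cols) >= 3 && any(erode_oracle(m))) return(m)
  }
}

# dense grid search for A * exp(-t / T) with profiled amplitude
monoexp_grid_oracle <- function(signal, times, t_grid) {
  best_t <- NA_real_; best_rss <- Inf
  for (tt in t_grid) {
    e <- exp(-times / tt)
    a <- sum(signal * e) / sum(e^2)
    rss <- sum((signal - a * e)^2)
    if (rss < best_rss) { best_rss <- rss; best_t <- tt }
  }
  best_t
}

# exhaustive sign-pattern x dense-grid search for magnitude IR
ir_grid_oracle <- function(signal, TI, t_grid) {
  n <- length(TI)
  best <- list(rss = Inf, t1 = NA_real_)
  for (k in 0:n) {
    y <- signal * c(rep(-1, k), rep(1, n - k))
    for (tt in t_grid) {
      x <- exp(-TI / tt)
      X <- cbind(1, x)
      beta <- solve(crossprod(X), crossprod(X, y))
      rss <- sum((y - X %*% beta)^2)
      if (rss < best$rss) best <- list(rss = rss, t1 = tt)
    }
  }
  best$t1
}

# dense grid search for sigma = c (exp(b eps) - 1) with profiled c
biomech_grid_oracle <- function(strain, stress, b_grid) {
  best <- list(rss = Inf, b = NA_real_, c = NA_real_)
  for (b in b_grid) {
    g <- exp(b * strain) - 1
    cc <- sum(stress * g) / sum(g^2)
    rss <- sum((stress - cc * g)^2)
    if (rss < best$rss) best <- list(rss = rss, b = b, c = cc)
  }
  best
}

# exhaustive permutation distribution of the Kruskal-Wallis H statistic
# for three groups of 3 (1680 distinct assignments), independent H formula
kw_exact_oracle <- function(values) {
  n <- 9L
  r <- rank(values)
  h_of <- function(assign) {
    s <- tapply(r, assign, sum)
    12 / (n * (n + 1)) * sum(s^2 / 3) - 3 * (n + 1)
  }
  obs <- h_of(rep(1:3, each = 3))
  count <- 0L; total <- 0L
  first <- utils::combn(9, 3)
  for (i in seq_len(ncol(first))) {
    rest <- setdiff(1:9, first[, i])
    second <- utils::combn(rest, 3)
    for (j in seq_len(ncol(second))) {
      assign <- integer(9)
      assign[first[, i]] <- 1L
      assign[second[, j]] <- 2L
      assign[assign == 0L] <- 3L
      total <- total + 1L
      if (h_of(assign) >= obs - 1e-12) count <- count + 1L
    }
  }
  list(p = count / total, observed = obs, total = total)
}

# exact within-block permutation distribution of the Friedman chi-square
# for k = 3 treatments (6^n rank configurations), untied formula
friedman_exact_oracle <- function(y) {
  n <- nrow(y); k <- 3L
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  chisq <- function(rk) {
    cs <- colSums(rk)
    12 / (n * k * (k + 1)) * sum(cs^2) - 3 * n * (k + 1)
  }
  obs <- chisq(t(apply(y, 1, rank)))
  idx <- rep(1L, n)
  count <- 0L; total <- 6L^n
  for (code in 0:(total - 1L)) {
    z <- code
    rk <- matrix(0, n, k)
    for (b in seq_len(n)) {
      rk[b, ] <- perms[z %% 6L + 1L, ]
      z <- z %/% 6L
    }
    if (chisq(rk) >= obs - 1e-12) count <- count + 1L
  }
  list(p = count / total, observed = obs)
}
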