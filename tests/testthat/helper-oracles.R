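# Independent oracles used across test files.

# Brute-force 3D connected-component labeling by iterative flood fill,
# independent of the graph-based implementation in the package.
flood_fill_label_3d <- function(fg, connectivity = 26) {
  dims <- dim(fg)
  lab <- array(0L, dims)
  offs <- expand.grid(dr = -1:1, dc = -1:1, dz = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0 & offs$dz == 0), ]
  ord <- abs(offs$dr) + abs(offs$dc) + abs(offs$dz)
  offs <- switch(as.character(connectivity),
                 "6" = offs[ord == 1, ], "18" = offs[ord <= 2, ], "26" = offs)
  nxt <- 0L
  for (z in seq_len(dims[3])) for (cc in seq_len(dims[2])) for (r in seq_len(dims[1])) {
    if (!fg[r, cc, z] || lab[r, cc, z] != 0L) next
    nxt <- nxt + 1L
    stack_ <- list(c(r, cc, z))
    lab[r, cc, z] <- nxt
    while (length(stack_)) {
      v <- stack_[[length(stack_)]]
      stack_[[length(stack_)]] <- NULL
      for (k in seq_len(nrow(offs))) {
        r2 <- v[1] + offs$dr[k]; c2 <- v[2] + offs$dc[k]; z2 <- v[3] + offs$dz[k]
        if (r2 < 1 || r2 > dims[1] || c2 < 1 || c2 > dims[2] ||
            z2 < 1 || z2 > dims[3]) next
        if (fg[r2, c2, z2] && lab[r2, c2, z2] == 0L) {
          lab[r2, c2, z2] <- nxt
          stack_[[length(stack_) + 1L]] <- c(r2, c2, z2)
        }
      }
    }
  }
  lab
}

# Do two label arrays define the same partition of the foreground?
same_partition <- function(a, b) {
  if (!all((a > 0) == (b > 0))) return(FALSE)
  fg <- a > 0
  key <- paste(a[fg], b[fg])
  length(unique(key)) == length(unique(a[fg])) &&
    length(unique(key)) == length(unique(b[fg]))
}

# Two-pass third-moment skewness, independent of the package implementation.
skewness_two_pass <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  d <- x - mu
  m2 <- sum(d^2) / n
  m3 <- sum(d^3) / n
  m3 / m2^1.5
}

# Exact two-sided Mann-Whitney p by direct enumeration over rank subsets,
# written independently of the package's null-distribution code.
mw_exact_p_oracle <- function(a, b) {
  n_a <- length(a); n_b <- length(b)
  r <- rank(c(a, b))
  ua_obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  combos <- combn(n_a + n_b, n_a)
  ua_all <- apply(combos, 2, function(ix) sum(ix) - n_a * (n_a + 1) / 2)
  lower <- mean(ua_all <= ua_obs)
  upper <- mean(ua_all >= ua_obs)
  min(1, 2 * min(lower, upper))
}
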