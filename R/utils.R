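#' @keywords internal
"_PACKAGE"

## Shared conventions
##
## Masks and images are numeric/integer matrices indexed [row, col]; a pixel
## at matrix position (r, c) has image coordinates x = c - 1, y = r - 1 in
## pixels (0-based), converted to micrometres by multiplying with pixel_size.
## Angles are measured in degrees from the image x-axis towards increasing y
## (rows), and orientations are reported modulo 180 in [0, 180).

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL runs on the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  withr::with_seed(as.integer(seed), expr)
}

mask_area_px <- function(mask) sum(mask != 0)

assert_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask)) stop(sprintf("`%s` must be a matrix", arg))
  if (mask_area_px(mask) == 0L) stop(sprintf("`%s` is empty", arg))
  invisible(mask)
}

# Otsu threshold on an arbitrary intensity vector (256-bin histogram),
# delegated to EBImage after rescaling to [0, 1].
otsu_threshold <- function(x) {
  x <- as.numeric(x)
  rng <- range(x, finite = TRUE)
  if (diff(rng) <= 0) return(rng[1])
  scaled <- (x - rng[1]) / diff(rng)
  n <- length(scaled)
  side <- ceiling(sqrt(n))
  padded <- c(scaled, rep(scaled[n], side * side - n))
  thr <- EBImage::otsu(EBImage::Image(matrix(padded, side)), range = c(0, 1))
  thr * diff(rng) + rng[1]
}

# Label connected components of a logical/0-1 matrix with 8-connectivity.
# Returns an integer matrix of labels (0 = background).
label_components_8 <- function(mask) {
  idx <- which(mask != 0)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  if (length(idx) == 0L) return(lab)
  nr <- nrow(mask)
  pos <- match(idx, idx)
  rr <- (idx - 1L) %% nr + 1L
  cc <- (idx - 1L) %/% nr + 1L
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  edges <- integer(0)
  for (k in seq_len(nrow(offs))) {
    r2 <- rr + offs$dr[k]; c2 <- cc + offs$dc[k]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= ncol(mask)
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- match(nb, idx)
    keep <- !is.na(hit)
    if (any(keep)) edges <- c(edges, rbind(pos[ok][keep], hit[keep]))
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership
  lab[idx] <- as.integer(comp)
  lab
}
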