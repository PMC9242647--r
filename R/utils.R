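# Internal helpers shared across modules: local RNG scoping, mirrored-border
# convolution, morphology and connected components on logical matrices.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `expr` under set.seed(seed) without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Whole-sample mirror reflection of indices into 1..n (1,2,...,n,n-1,...).
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  per <- 2L * (n - 1L)
  j <- (i - 1L) %% per
  j <- ifelse(j < 0L, j + per, j)
  as.integer(ifelse(j >= n, per - j, j) + 1L)
}

# Separable 1-D convolution along rows or columns with mirrored borders and
# an optional dilation factor (holes) between taps.
conv_sep1d <- function(mat, kernel, along = c("row", "col"), step = 1L) {
  along <- match.arg(along)
  half <- (length(kernel) - 1L) %/% 2L
  offs <- (-half:half) * step
  if (along == "row") {
    n <- nrow(mat)
    out <- matrix(0, n, ncol(mat))
    for (k in seq_along(offs)) {
      idx <- reflect_index(seq_len(n) + offs[k], n)
      out <- out + kernel[k] * mat[idx, , drop = FALSE]
    }
  } else {
    n <- ncol(mat)
    out <- matrix(0, nrow(mat), n)
    for (k in seq_along(offs)) {
      idx <- reflect_index(seq_len(n) + offs[k], n)
      out <- out + kernel[k] * mat[, idx, drop = FALSE]
    }
  }
  out
}

# Separable 2-D convolution (same kernel both axes), mirrored borders.
conv_sep2d <- function(mat, kernel, step = 1L) {
  conv_sep1d(conv_sep1d(mat, kernel, "row", step), kernel, "col", step)
}

gaussian_kernel1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

gaussian_blur <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  conv_sep2d(mat, gaussian_kernel1d(sigma))
}

# Shift a logical matrix by (dy, dx), padding with FALSE.
shift_logical <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(FALSE, h, w)
  ys <- max(1L, 1L + dy):min(h, h + dy)
  xs <- max(1L, 1L + dx):min(w, w + dx)
  if (length(ys) < 1L || length(xs) < 1L) return(out)
  out[ys, xs] <- m[ys - dy, xs - dx, drop = FALSE]
  out
}

# Binary dilation with a disk of the given radius (radius 0 = identity).
dilate_disk <- function(mask, radius) {
  if (radius <= 0) return(mask)
  r <- as.integer(ceiling(radius))
  out <- mask
  for (dy in -r:r) for (dx in -r:r) {
    if (dy == 0L && dx == 0L) next
    if (dy * dy + dx * dx > radius^2 + 1e-9) next
    out <- out | shift_logical(mask, dy, dx)
  }
  out
}

# Connected components (8-connectivity) by iterative label minimisation.
# Returns an integer matrix with 0 = background, 1..k component ids.
label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0, h, w)
  lab[mask] <- which(mask)
  neigh <- list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L),
                c(1L, 1L), c(1L, -1L), c(-1L, 1L), c(-1L, -1L))
  repeat {
    new <- lab
    for (d in neigh) {
      sh <- matrix(Inf, h, w)
      ys <- max(1L, 1L + d[1]):min(h, h + d[1])
      xs <- max(1L, 1L + d[2]):min(w, w + d[2])
      if (length(ys) && length(xs))
        sh[ys, xs] <- lab[ys - d[1], xs - d[2], drop = FALSE]
      sh[!mask | sh == 0] <- Inf
      upd <- mask & is.finite(sh) & sh < new
      new[upd] <- sh[upd]
    }
    if (identical(new, lab)) break
    lab <- new
  }
  ids <- sort(unique(lab[lab > 0]))
  out <- matrix(0L, h, w)
  if (length(ids)) out[lab > 0] <- match(lab[lab > 0], ids)
  out
}

# Drop connected components smaller than min_area pixels.
remove_small_components <- function(mask, min_area) {
  if (min_area <= 1 || !any(mask)) return(mask)
  lab <- label_components(mask)
  keep <- which(tabulate(lab[lab > 0]) >= min_area)
  lab > 0 & lab %in% keep
}

# Bilinear sampling of matrix `img` at fractional (row, col) positions
# (1-based). Positions outside [1, h] x [1, w] return `fill`.
bilinear_sample <- function(img, r, c, fill = 0) {
  h <- nrow(img); w <- ncol(img)
  use <- r >= 1 & r <= h & c >= 1 & c <= w & is.finite(r) & is.finite(c)
  val <- rep(fill, length(r))
  if (any(use)) {
    # clamp base index so exact far-edge hits stay in range (frac = 0 there)
    r0 <- pmin(floor(r[use]), h - 1L); c0 <- pmin(floor(c[use]), w - 1L)
    if (h == 1L) r0 <- pmax(r0, 1L)
    if (w == 1L) c0 <- pmax(c0, 1L)
    f1 <- r[use] - r0; f2 <- c[use] - c0
    r1 <- pmin(r0 + 1L, h); c1 <- pmin(c0 + 1L, w)
    val[use] <- img[cbind(r0, c0)] * (1 - f1) * (1 - f2) +
      img[cbind(r0, c1)] * (1 - f1) * f2 +
      img[cbind(r1, c0)] * f1 * (1 - f2) +
      img[cbind(r1, c1)] * f1 * f2
  }
  val
}

# Translate an image by (dy, dx) (content moves down/right for positive
# values); vacated pixels take `fill`. Bilinear for fractional shifts.
shift_image <- function(img, dy, dx, fill = 0) {
  h <- nrow(img); w <- ncol(img)
  if (dy == round(dy) && dx == round(dx)) {
    out <- matrix(fill, h, w)
    dy <- as.integer(round(dy)); dx <- as.integer(round(dx))
    ys <- max(1L, 1L + dy):min(h, h + dy)
    xs <- max(1L, 1L + dx):min(w, w + dx)
    if (length(ys) && length(xs))
      out[ys, xs] <- img[ys - dy, xs - dx, drop = FALSE]
    return(out)
  }
  grid_r <- matrix(seq_len(h), h, w) - dy
  grid_c <- matrix(seq_len(w), h, w, byrow = TRUE) - dx
  matrix(bilinear_sample(img, as.vector(grid_r), as.vector(grid_c), fill), h, w)
}

# Binary erosion with a disk (complement of dilation of the complement).
erode_disk <- function(mask, radius) {
  if (radius <= 0) return(mask)
  !dilate_disk(!mask, radius)
}
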