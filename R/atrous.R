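#' À trous B3-spline wavelet decomposition
#'
#' Undecimated (stationary) wavelet transform with the separable B3-spline
#' kernel `[1, 4, 6, 4, 1] / 16`: at level j the kernel taps are spaced
#' `2^(j-1)` pixels apart (the "holes"), borders are mirrored, and the
#' detail plane is the difference of successive smooths. The decomposition
#' is exactly additive: `image = sum(details) + smooth`.
#'
#' @param image numeric matrix.
#' @param levels number of detail levels J (>= 1). The image's smaller
#'   dimension must exceed `2^levels * 4` so the dilated kernel fits.
#' @return an `AtrousDecomposition` list: `details` (list of J matrices),
#'   `smooth` (residual), `levels`, `kernel`.
#' @export
atrous_decompose <- function(image, levels = 3L) {
  if (levels < 1L) stop("levels must be >= 1")
  if (min(dim(image)) <= 2^levels * 4)
    stop(sprintf("image min dimension %d too small for %d levels (needs > %d)",
                 min(dim(image)), levels, 2^levels * 4))
  kernel <- c(1, 4, 6, 4, 1) / 16
  s <- image
  details <- vector("list", levels)
  for (j in seq_len(levels)) {
    s_next <- conv_sep2d(s, kernel, step = 2L^(j - 1L))
    details[[j]] <- s - s_next
    s <- s_next
  }
  structure(list(details = details, smooth = s, levels = levels,
                 kernel = kernel), class = "AtrousDecomposition")
}

#' Reconstruct the input of a decomposition
#' @param dec an [atrous_decompose()] result.
#' @return numeric matrix; equals the original image to floating tolerance.
#' @export
atrous_reconstruct <- function(dec) {
  Reduce(`+`, dec$details) + dec$smooth
}

# Per-level noise sigma of the detail planes for unit-variance white noise:
# the L2 norm of each level's equivalent (linear, shift-invariant) filter,
# computed once from an impulse response and cached.
.atrous_cache <- new.env(parent = emptyenv())
atrous_noise_sigmas <- function(levels) {
  key <- as.character(levels)
  if (!is.null(.atrous_cache[[key]])) return(.atrous_cache[[key]])
  n <- 2^levels * 8 + 1
  imp <- matrix(0, n, n); imp[(n + 1) / 2, (n + 1) / 2] <- 1
  dec <- atrous_decompose(imp, levels)
  sig <- vapply(dec$details, function(d) sqrt(sum(d^2)), numeric(1))
  .atrous_cache[[key]] <- sig
  sig
}
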