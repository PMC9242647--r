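# Shared fixtures, built in code at test time (no binary files).

# Smooth synthetic frame: sum of random Gaussian blobs (used for
# registration and kymograph tests).
blob_frame <- function(h = 128L, w = 128L, n = 30L, sigma = 4, seed = 1L) {
  set.seed(seed)
  img <- matrix(0, h, w)
  ys <- runif(n, 15, h - 15); xs <- runif(n, 15, w - 15)
  a <- runif(n, 50, 200)
  gr <- matrix(seq_len(h), h, w)
  gc <- matrix(seq_len(w), h, w, byrow = TRUE)
  for (i in seq_len(n))
    img <- img + a[i] * exp(-((gr - ys[i])^2 + (gc - xs[i])^2) / (2 * sigma^2))
  img
}

# Stack of two frames: a reference and a shifted copy.
shift_pair_stack <- function(ref, dy, dx, noise_sd = 0, seed = 1L) {
  set.seed(seed)
  mov <- pmindex:::shift_image(ref, dy, dx, fill = 0)
  if (noise_sd > 0)
    mov <- mov + matrix(rnorm(length(mov), 0, noise_sd), nrow(mov))
  arr <- array(0, dim = c(2L, 1L, nrow(ref), ncol(ref)))
  arr[1, 1, , ] <- ref; arr[2, 1, , ] <- mov
  image_stack(arr)
}

# Rectangular ROI helper (0-based, half-open: covers h x w pixel centers).
rect_roi <- function(r0, c0, h, w, label = "rect", kind = "junction") {
  roi_spec(label, rbind(c(r0, c0), c(r0, c0 + w), c(r0 + h, c0 + w),
                        c(r0 + h, c0)), kind = kind)
}

# A small cached tissue simulation shared by several test files
# (9 cells, 128 px, 40 frames, compressed timeline with the same phase
# structure as the defaults).
small_model <- function() default_kinetic_model(t_hypoxia = 300, t_reoxy = 1500)

small_sim_cache <- new.env(parent = emptyenv())
small_sim <- function() {
  if (is.null(small_sim_cache$sim)) {
    geom <- generate_geometry(9, c(128, 128), "tissue", seed = 11)
    model <- small_model()
    sim <- render_stack(geom, model, channels = c("PIP2", "PI4P", "dye"),
                        n_frames = 40L, frame_interval = 60,
                        noise = list(gain = 2, read_sigma = 2),
                        drift = list(step_sigma = 0.3), seed = 12)
    small_sim_cache$sim <- list(geom = geom, model = model, sim = sim)
  }
  small_sim_cache$sim
}

# Independent oracle for the a trous transform: direct (non-separable)
# 2-D convolution with the dilated outer-product kernel and mirrored
# borders, implemented with plain loops.
oracle_atrous_smooth <- function(img, level) {
  k1 <- c(1, 4, 6, 4, 1) / 16
  step <- 2^(level - 1)
  h <- nrow(img); w <- ncol(img)
  refl <- function(i, n) {
    while (any(i < 1 | i > n)) {
      i[i < 1] <- 2 - i[i < 1]
      i[i > n] <- 2 * n - i[i > n]
    }
    i
  }
  out <- matrix(0, h, w)
  for (a in -2:2) for (b in -2:2) {
    ys <- refl(seq_len(h) + a * step, h)
    xs <- refl(seq_len(w) + b * step, w)
    out <- out + k1[a + 3] * k1[b + 3] * img[ys, xs]
  }
  out
}
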