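#' Parameters for one synthetic organoid image
#'
#' Describes a bright-field-like scene: an ovoid organoid body (anisotropic
#' ellipse, optionally with a low-frequency boundary perturbation), a bright
#' neuroepithelial-like rim with speckle texture just inside the boundary, a
#' sparse halo of dispersed dark cells outside the body, all on a
#' light-to-dark vertical gradient background, with optional acquisition
#' artifacts, Gaussian blur and additive noise.
#'
#' @param canvas_size Integer length-2, image height and width in pixels.
#' @param center Length-2 numeric, body centre (row, col) in pixels.
#' @param semi_axes Length-2 numeric, ellipse semi-axes (rows, cols) in pixels.
#' @param boundary_amp Relative amplitude of the low-frequency boundary
#'   perturbation (0 gives an exact ellipse).
#' @param rim_width Width of the bright rim band, pixels.
#' @param rim_texture_amplitude Speckle amplitude on the rim, intensity units.
#' @param halo_density Fraction of near-body background pixels seeded with
#'   dispersed dark cells, in \[0, 1\].
#' @param background_gradient Length-2 numeric, background intensity at the
#'   top and bottom rows.
#' @param artifact_count Number of random acquisition artifacts (small bright
#'   or dark blobs).
#' @param blur_sigma Gaussian blur sigma, pixels (0 = none).
#' @param noise_sigma Additive Gaussian noise sd, intensity units (0 = none).
#' @param seed Integer seed; identical params + seed give bit-identical output.
#'
#' @return An object of class `organoid_params` (a named list).
#' @export
#' @examples
#' p <- organoid_params(canvas_size = c(64, 64), semi_axes = c(20, 14), seed = 1)
#' img <- make_organoid(p)
organoid_params <- function(canvas_size = c(250, 250),
                            center = canvas_size / 2,
                            semi_axes = c(70, 55),
                            boundary_amp = 0,
                            rim_width = 8,
                            rim_texture_amplitude = 25,
                            halo_density = 0.004,
                            background_gradient = c(215, 120),
                            artifact_count = 0,
                            blur_sigma = 0,
                            noise_sigma = 0,
                            seed = 1L) {
  p <- list(
    canvas_size = as.integer(canvas_size), center = as.numeric(center),
    semi_axes = as.numeric(semi_axes), boundary_amp = boundary_amp,
    rim_width = rim_width, rim_texture_amplitude = rim_texture_amplitude,
    halo_density = halo_density, background_gradient = as.numeric(background_gradient),
    artifact_count = as.integer(artifact_count), blur_sigma = blur_sigma,
    noise_sigma = noise_sigma, seed = as.integer(seed)
  )
  if (any(p$semi_axes <= 0)) abort("`semi_axes` must be positive.")
  if (p$center[1] + p$semi_axes[1] > p$canvas_size[1] ||
      p$center[1] - p$semi_axes[1] < 1 ||
      p$center[2] + p$semi_axes[2] > p$canvas_size[2] ||
      p$center[2] - p$semi_axes[2] < 1) {
    abort("`semi_axes` must fit inside the canvas around `center`.")
  }
  if (p$blur_sigma < 0 || p$noise_sigma < 0) abort("Sigmas must be >= 0.")
  if (p$halo_density < 0 || p$halo_density > 1) abort("`halo_density` must be in [0, 1].")
  structure(p, class = "organoid_params")
}

#' Render one synthetic organoid image and its ground-truth mask
#'
#' The mask is the exact pixel support of the body: with `boundary_amp = 0`
#' it is the discrete ellipse `((r-cr)/a)^2 + ((c-cc)/b)^2 <= 1`. The
#' background outside the body is a monotone vertical gradient (plus halo
#' cells and artifacts when those are enabled). Rendering is a pure function
#' of the parameter object, including its seed.
#'
#' @param params An [organoid_params()] object.
#' @return A list with elements `image` (numeric matrix, \[0, 255\]) and
#'   `mask` (0/1 integer matrix of the same size).
#' @export
make_organoid <- function(params) {
  if (!inherits(params, "organoid_params")) params <- do.call(organoid_params, params)
  p <- params
  h <- p$canvas_size[1]; w <- p$canvas_size[2]
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)

  with_seed(p$seed, {
    # normalized elliptical radius, optionally modulated at low frequency
    dr <- (rr - p$center[1]) / p$semi_axes[1]
    dc <- (cc - p$center[2]) / p$semi_axes[2]
    rho <- sqrt(dr^2 + dc^2)
    if (p$boundary_amp > 0) {
      theta <- atan2(dr, dc)
      ph <- runif(3, 0, 2 * pi)
      mod <- 1 + p$boundary_amp * (sin(2 * theta + ph[1]) * 0.6 +
                                     sin(3 * theta + ph[2]) * 0.3 +
                                     sin(5 * theta + ph[3]) * 0.1)
    } else {
      mod <- 1
    }
    inside <- rho <= mod
    mask <- matrix(0L, h, w)
    mask[inside] <- 1L

    # light-to-dark vertical gradient background
    g0 <- p$background_gradient[1]; g1 <- p$background_gradient[2]
    img <- matrix(g0 + (g1 - g0) * (seq_len(h) - 1) / (h - 1), h, w)

    # body: dark interior with mild radial shading (darker toward the centre)
    body_int <- 95 + 25 * rho[inside] / max(mod)
    img[inside] <- body_int

    # rim: bright textured band just inside the boundary
    rim_frac <- p$rim_width / mean(p$semi_axes)
    rim <- inside & (rho >= pmax(0, mod - rim_frac))
    if (any(rim)) {
      speckle <- runif(sum(rim), -1, 1) * p$rim_texture_amplitude
      img[rim] <- 165 + speckle
    }

    # halo: dispersed dark cells in an annulus outside the body
    halo_zone <- !inside & rho <= 1.45
    if (p$halo_density > 0 && any(halo_zone)) {
      n_halo <- round(p$halo_density * sum(halo_zone))
      if (n_halo > 0) {
        pick <- sample(which(halo_zone), n_halo)
        img[pick] <- img[pick] - runif(n_halo, 50, 90)
      }
    }

    # acquisition artifacts: small random bright/dark blobs
    if (p$artifact_count > 0) {
      for (i in seq_len(p$artifact_count)) {
        ar <- sample.int(h, 1); ac <- sample.int(w, 1)
        rad <- sample(2:5, 1)
        amp <- sample(c(-1, 1), 1) * runif(1, 40, 80)
        zone <- (rr - ar)^2 + (cc - ac)^2 <= rad^2
        img[zone] <- img[zone] + amp
      }
    }

    if (p$blur_sigma > 0) img <- gaussian_blur(img, p$blur_sigma)
    if (p$noise_sigma > 0) img <- img + rnorm(h * w, 0, p$noise_sigma)
    img <- clamp255(img)
    list(image = img, mask = mask)
  })
}

#' Generate a dataset of synthetic organoid images
#'
#' Per-image seeds are derived deterministically from `seed`, so two calls
#' with the same arguments return identical datasets. `params_sampler` is
#' called with `(index, seed)` and must return an [organoid_params()];
#' the default varies the semi-axes, boundary shape and blur between images.
#'
#' @param n Number of images (>= 1).
#' @param params_sampler Function `(i, seed)` -> [organoid_params()].
#' @param seed Master seed.
#' @param group Provenance label attached to every image.
#' @return A tibble with columns `id`, `group`, `image` (list of matrices),
#'   `mask` (list of 0/1 matrices).
#' @export
#' @examples
#' ds <- make_dataset(4, seed = 7)
#' nrow(ds)
make_dataset <- function(n, params_sampler = default_params_sampler(), seed = 1L,
                         group = "original") {
  if (!is.numeric(n) || n < 1) abort("`n` must be >= 1.")
  n <- as.integer(n)
  seeds <- derive_seeds(seed, n)
  items <- purrr::map(seq_len(n), function(i) {
    make_organoid(params_sampler(i, seeds[i]))
  })
  tibble(
    id = sprintf("%s_%03d", group, seq_len(n)),
    group = group,
    image = purrr::map(items, "image"),
    mask = purrr::map(items, "mask")
  )
}

#' Default parameter sampler for [make_dataset()]
#'
#' Varies body size, eccentricity, boundary perturbation, halo density and a
#' mild acquisition blur between images, emulating the batch-to-batch
#' morphological variability of cultured organoids.
#'
#' @param canvas_size Canvas size passed through to [organoid_params()].
#' @return A function `(i, seed)` -> [organoid_params()].
#' @export
default_params_sampler <- function(canvas_size = c(250, 250)) {
  force(canvas_size)
  function(i, seed) {
    s <- canvas_size
    with_seed(seed, {
      a <- runif(1, 0.18, 0.32) * s[1]
      b <- runif(1, 0.18, 0.32) * s[2]
      organoid_params(
        canvas_size = s,
        center = c(
          runif(1, a + 1, s[1] - a - 1),
          runif(1, b + 1, s[2] - b - 1)
        ),
        semi_axes = c(a, b),
        boundary_amp = runif(1, 0.02, 0.08),
        halo_density = runif(1, 0.001, 0.008),
        artifact_count = sample(0:2, 1),
        blur_sigma = runif(1, 0.3, 1.2),
        noise_sigma = runif(1, 1, 5),
        seed = sample.int(.Machine$integer.max - 1L, 1)
      )
    })
  }
}

#' Degrade an image with blur and noise
#'
#' With both sigmas zero the input is returned bit-identical. Output is
#' clamped to \[0, 255\].
#'
#' @param image Numeric matrix in \[0, 255\].
#' @param blur_sigma Gaussian blur sigma (pixels), >= 0.
#' @param noise_sigma Additive Gaussian noise sd (intensity units), >= 0.
#' @param seed Seed for the noise draw.
#' @return Degraded image matrix.
#' @export
degrade <- function(image, blur_sigma = 0, noise_sigma = 0, seed = 1L) {
  assert_image(image)
  if (blur_sigma < 0 || noise_sigma < 0) abort("Sigmas must be >= 0.")
  if (blur_sigma == 0 && noise_sigma == 0) return(image)
  out <- image
  if (blur_sigma > 0) out <- gaussian_blur(out, blur_sigma)
  if (noise_sigma > 0) {
    out <- with_seed(seed, out + rnorm(length(out), 0, noise_sigma))
  }
  clamp255(out)
}
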