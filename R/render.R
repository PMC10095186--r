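#' Multi-channel event image
#'
#' Container for the three-channel image of one acquired object:
#' brightfield (`bf`), RedoxSensor Green fluorescence (`rsg`) and propidium
#' iodide fluorescence (`pi`), all matrices of identical dimensions, plus the
#' pixel size in µm.
#'
#' @param bf,rsg,pi Numeric matrices of identical dimensions.
#' @param pixel_size Pixel edge length (µm).
#' @return An object of class `event_image`.
#' @export
event_image <- function(bf, rsg, pi, pixel_size) {
  stopifnot(is.matrix(bf), identical(dim(bf), dim(rsg)),
            identical(dim(bf), dim(pi)))
  stopifnot_scalar_number(pixel_size, "pixel_size", positive = TRUE)
  structure(list(channels = list(bf = bf, rsg = rsg, pi = pi),
                 pixel_size = pixel_size),
            class = "event_image")
}

#' @export
print.event_image <- function(x, ...) {
  d <- dim(x$channels$bf)
  cat(sprintf("<event_image> %d x %d px, %.3g um/px, channels: %s\n",
              d[1], d[2], x$pixel_size,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

get_channel <- function(image, channel) {
  stopifnot(inherits(image, "event_image"))
  if (!channel %in% names(image$channels)) {
    abort(sprintf("Channel '%s' not present (have: %s).", channel,
                  paste(names(image$channels), collapse = ", ")))
  }
  image$channels[[channel]]
}

ellipse_mask <- function(nr, nc, cx, cy, a, b, theta) {
  x <- matrix(rep(seq_len(nc), each = nr), nr) - cx
  y <- matrix(rep(seq_len(nr), nc), nr) - cy
  xr <- x * cos(theta) + y * sin(theta)
  yr <- -x * sin(theta) + y * cos(theta)
  (xr / a)^2 + (yr / b)^2 <= 1
}

gaussian_blur <- function(mat, sigma_px) {
  size <- max(3L, 2L * ceiling(3 * sigma_px) + 1L)
  if (size >= min(dim(mat))) size <- min(dim(mat)) - (1 - min(dim(mat)) %% 2)
  k <- EBImage::makeBrush(size, shape = "Gaussian", sigma = sigma_px)
  EBImage::filter2(mat, k)
}

#' Render the multi-channel image of one event
#'
#' Draws a brightfield silhouette (dark object on a bright, noisy
#' background) and the two fluorescence channels, whose integrated
#' within-mask signal equals the record's `rsg_intensity` / `pi_intensity`
#' up to additive pixel noise. Single cells are ellipses with dimensions
#' drawn from the shape spec; aggregates are clusters of adjacent ellipses;
#' debris is an irregular union of low-contrast blobs; defocused events are
#' convolved with a Gaussian blur.
#'
#' @param record One event: a one-row event table (or list) with
#'   `true_label`, `rsg_intensity`, `pi_intensity`.
#' @param shape A [shape_spec()].
#' @param image_size Image edge length in pixels.
#' @param pixel_size Pixel edge length (µm).
#' @param seed Integer RNG seed.
#' @return An [event_image()].
#' @export
render_event_image <- function(record, shape = shape_spec(), image_size = 48L,
                               pixel_size = 0.3, seed = 1L) {
  label <- record$true_label
  if (is.null(label) || is.na(label)) {
    abort("`record` must carry a ground-truth `true_label`.")
  }
  n <- as.integer(image_size)
  with_seed(seed, {
    ctr <- (n + 1) / 2
    draw_cell <- function(cx, cy) {
      len <- max(stats::rnorm(1, shape$length_mean, shape$length_sd), 0.2)
      wid <- min(max(stats::rnorm(1, shape$width_mean, shape$width_sd), 0.1), len)
      a <- len / 2 / pixel_size
      b <- wid / 2 / pixel_size
      if (2 * a > n - 4) {
        abort("Image too small to contain the sampled cell.",
              class = "ifcgate_size_error")
      }
      ellipse_mask(n, n, cx, cy, a, b, stats::runif(1, 0, pi))
    }
    if (label %in% c(cell_classes(), "out_of_focus")) {
      mask <- draw_cell(ctr + stats::rnorm(1), ctr + stats::rnorm(1))
    } else if (label == "aggregate") {
      k <- 2L + stats::rpois(1, shape$aggregate_lambda)
      step <- shape$width_mean / pixel_size * 0.9
      ang <- stats::runif(1, 0, 2 * pi)
      offs <- cbind(cos(ang) * step * (seq_len(k) - (k + 1) / 2),
                    sin(ang) * step * (seq_len(k) - (k + 1) / 2))
      mask <- matrix(FALSE, n, n)
      for (i in seq_len(k)) {
        mask <- mask | draw_cell(ctr + offs[i, 1], ctr + offs[i, 2])
      }
    } else { # debris: irregular union of small blobs
      nb <- sample(3:6, 1)
      mask <- matrix(FALSE, n, n)
      for (i in seq_len(nb)) {
        r <- stats::runif(1, 1, 2.5)
        mask <- mask | ellipse_mask(n, n, ctr + stats::rnorm(1, 0, 2),
                                    ctr + stats::rnorm(1, 0, 2),
                                    r, r * stats::runif(1, 0.5, 1),
                                    stats::runif(1, 0, pi))
      }
    }
    contrast <- if (label == "debris") 25 else 70
    bf <- matrix(200 + stats::rnorm(n * n, 0, 2), n) - contrast * mask
    fluor <- function(total) {
      w <- mask / max(sum(mask), 1L)
      matrix(stats::rnorm(n * n, 0, 0.05), n) + w * total
    }
    rsg <- fluor(record$rsg_intensity)
    pim <- fluor(record$pi_intensity)
    if (label == "out_of_focus") {
      sig <- stats::runif(1, shape$defocus_sigma_um[1],
                          shape$defocus_sigma_um[2]) / pixel_size
      bf <- gaussian_blur(bf, sig)
      rsg <- gaussian_blur(rsg, sig)
      pim <- gaussian_blur(pim, sig)
    }
    event_image(bf, rsg, pim, pixel_size)
  })
}
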