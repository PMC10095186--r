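#' Binary object mask for an event image channel
#'
#' Segments the foreground object of one channel. Brightfield images are
#' inverted first (cells are darker than the illuminated background); on
#' fluorescence channels the signal itself is foreground. `otsu_threshold`
#' is the plain histogram threshold; `morphology_combined` additionally
#' dilates the threshold mask by one pixel and fills interior holes, giving
#' the wider footprint used for intensity-type features. An all-background
#' (constant) channel yields an empty mask.
#'
#' @param image An [event_image()].
#' @param channel `"bf"`, `"rsg"` or `"pi"`.
#' @param method Mask derivation method.
#' @return An object of class `ifc_mask`: logical matrix `pixels` plus the
#'   derivation `method` tag.
#' @export
compute_mask <- function(image, channel,
                         method = c("otsu_threshold", "morphology_combined")) {
  method <- match.arg(method)
  x <- get_channel(image, channel)
  v <- if (channel == "bf") max(x) - x else x
  if (diff(range(v)) == 0) {
    m <- matrix(FALSE, nrow(v), ncol(v))
  } else {
    m <- v > otsu_threshold(as.numeric(v))
  }
  if (method == "morphology_combined" && any(m)) {
    m <- EBImage::dilate(m * 1, EBImage::makeBrush(3, "box"))
    m <- EBImage::fillHull(m) > 0
  }
  structure(list(pixels = m, method = method), class = "ifc_mask")
}

as_mask_matrix <- function(mask) {
  if (inherits(mask, "ifc_mask")) mask$pixels else mask > 0
}

#' Gradient RMS focus metric
#'
#' Root mean square of the central-difference gradient magnitude over the
#' masked pixels, normalized by the mean masked intensity so that the value
#' is invariant under intensity rescaling. Sharp (in-focus) objects score
#' high, defocused objects low. Returns `NA` (undefined-feature sentinel)
#' for an empty mask.
#'
#' @inheritParams compute_mask
#' @param mask An `ifc_mask` or logical matrix.
#' @return A nonnegative scalar, or `NA_real_`.
#' @export
gradient_rms <- function(image, channel, mask) {
  x <- get_channel(image, channel)
  m <- as_mask_matrix(mask)
  if (!any(m)) return(NA_real_)
  nr <- nrow(x); nc <- ncol(x)
  gx <- matrix(0, nr, nc); gy <- matrix(0, nr, nc)
  gy[2:(nr - 1), ] <- (x[3:nr, ] - x[1:(nr - 2), ]) / 2
  gx[, 2:(nc - 1)] <- (x[, 3:nc] - x[, 1:(nc - 2)]) / 2
  gm2 <- gx^2 + gy^2
  mu <- mean(x[m])
  if (mu == 0) return(NA_real_)
  sqrt(mean(gm2[m])) / mu
}

#' Shape features of a mask
#'
#' Area (pixel count times pixel area), object axes from the eigenvalues of
#' the second-order central moments of the mask pixel coordinates (axis
#' length `4 * sqrt(eigenvalue)`, the full axis of the equivalent ellipse)
#' and the aspect ratio minor/major, so 1 is perfectly round. Returns
#' sentinels for an empty mask.
#'
#' @param mask An `ifc_mask` or logical matrix.
#' @param pixel_size Pixel edge length (µm).
#' @return A list with `area_um2`, `aspect_ratio`, `major_axis_um`,
#'   `minor_axis_um`.
#' @export
shape_features <- function(mask, pixel_size) {
  m <- as_mask_matrix(mask)
  npix <- sum(m)
  if (npix == 0) {
    return(list(area_um2 = NA_real_, aspect_ratio = NA_real_,
                major_axis_um = NA_real_, minor_axis_um = NA_real_))
  }
  area <- npix * pixel_size^2
  if (npix == 1) {
    return(list(area_um2 = area, aspect_ratio = 1,
                major_axis_um = pixel_size, minor_axis_um = pixel_size))
  }
  co <- which(m, arr.ind = TRUE)
  cc <- sweep(co, 2, colMeans(co))
  S <- crossprod(cc) / npix
  ev <- sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ev <- pmax(ev, 1 / 12)  # single-pixel-row floor
  major <- 4 * sqrt(ev[1]) * pixel_size
  minor <- 4 * sqrt(ev[2]) * pixel_size
  list(area_um2 = area, aspect_ratio = minor / major,
       major_axis_um = major, minor_axis_um = minor)
}

# quantize masked pixel values to `levels` gray levels (equal-width bins)
quantize_masked <- function(x, m, levels) {
  q <- matrix(NA_integer_, nrow(x), ncol(x))
  v <- x[m]
  rng <- range(v)
  if (diff(rng) == 0) {
    q[m] <- 1L
  } else {
    q[m] <- pmin(as.integer((v - rng[1]) / diff(rng) * levels) + 1L, levels)
  }
  q
}

# symmetric normalized GLCM at offset (dr, dc); both pixels must be in-mask
glcm_offset <- function(q, dr, dc, levels) {
  nr <- nrow(q); nc <- ncol(q)
  r1 <- max(1, 1 - dr):min(nr, nr - dr)
  c1 <- max(1, 1 - dc):min(nc, nc - dc)
  if (!length(r1) || !length(c1)) return(NULL)
  a <- q[r1, c1, drop = FALSE]
  b <- q[r1 + dr, c1 + dc, drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(NULL)
  i <- a[ok]; j <- b[ok]
  counts <- matrix(0, levels, levels)
  tab <- table(factor(i, levels = seq_len(levels)),
               factor(j, levels = seq_len(levels)))
  counts <- unclass(tab) + t(unclass(tab))  # symmetric
  counts / sum(counts)
}

glcm_entropy <- function(p) {
  nz <- p[p > 0]
  -sum(nz * log2(nz))
}

glcm_homogeneity <- function(p) {
  idx <- abs(row(p) - col(p))
  sum(p / (1 + idx))
}

#' Haralick co-occurrence texture statistics
#'
#' Quantizes the masked pixels to `levels` gray levels, builds symmetric
#' normalized gray-level co-occurrence matrices at pixel offset
#' `granularity` for the four directions 0°, 45°, 90° and 135°, and returns
#' the entropy (`-sum p log2 p`) and homogeneity (`sum p / (1 + |i - j|)`)
#' summarized as mean and standard deviation across the four directions.
#' Only pixel pairs that both fall inside the mask contribute. Returns
#' sentinels when the mask is too small to form any pair at the requested
#' offset.
#'
#' @inheritParams gradient_rms
#' @param granularity Co-occurrence pixel offset (>= 1).
#' @param levels Number of gray levels for quantization.
#' @return A list with `entropy_mean`, `entropy_std`, `homogeneity_mean`,
#'   `homogeneity_std`.
#' @export
haralick_stats <- function(image, channel, mask, granularity = 1L,
                           levels = 32L) {
  stopifnot(granularity >= 1L, levels >= 2L)
  x <- get_channel(image, channel)
  m <- as_mask_matrix(mask)
  sentinel <- list(entropy_mean = NA_real_, entropy_std = NA_real_,
                   homogeneity_mean = NA_real_, homogeneity_std = NA_real_)
  if (sum(m) < 2) return(sentinel)
  q <- quantize_masked(x, m, levels)
  g <- as.integer(granularity)
  offsets <- list(c(0L, g), c(-g, g), c(-g, 0L), c(-g, -g))  # 0/45/90/135 deg
  ent <- hom <- numeric(0)
  for (o in offsets) {
    p <- glcm_offset(q, o[1], o[2], levels)
    if (is.null(p)) return(sentinel)
    ent <- c(ent, glcm_entropy(p))
    hom <- c(hom, glcm_homogeneity(p))
  }
  list(entropy_mean = mean(ent), entropy_std = stats::sd(ent),
       homogeneity_mean = mean(hom), homogeneity_std = stats::sd(hom))
}

#' Intensity-weighted major axis length
#'
#' Major axis of the intensity-weighted second-moment ellipse over the
#' masked pixels, in µm. With uniform weights this equals the mask's own
#' major axis; weight concentrated at the object's ends lengthens it. The
#' value is invariant under intensity scaling. Sub-background (negative)
#' pixels carry no weight; when no positive weight remains the sentinel is
#' returned.
#'
#' @inheritParams gradient_rms
#' @param pixel_size Pixel edge length (µm).
#' @return Axis length in µm, or `NA_real_`.
#' @export
major_axis_intensity <- function(image, channel, mask, pixel_size) {
  x <- get_channel(image, channel)
  m <- as_mask_matrix(mask)
  if (!any(m)) return(NA_real_)
  co <- which(m, arr.ind = TRUE)
  w <- pmax(x[m], 0)
  sw <- sum(w)
  if (sw <= 0) return(NA_real_)
  w <- w / sw
  mu <- colSums(co * w)
  cc <- sweep(co, 2, mu)
  S <- t(cc) %*% (cc * w)
  ev <- max(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  4 * sqrt(max(ev, 1 / 12)) * pixel_size
}

#' Background-subtracted channel intensity
#'
#' Sum of masked pixel intensities after subtracting the background level,
#' estimated as the median of the unmasked pixels. The value is invariant
#' under a constant offset applied to the whole image. An empty mask gives 0.
#'
#' @inheritParams gradient_rms
#' @return Integrated intensity (RFU).
#' @export
channel_intensity <- function(image, channel, mask) {
  x <- get_channel(image, channel)
  m <- as_mask_matrix(mask)
  if (!any(m)) return(0)
  bg <- if (all(m)) 0 else stats::median(x[!m])
  sum(x[m] - bg)
}

#' Extract the canonical feature vector from an event image
#'
#' Computes all schema feature columns from one [event_image()]: focus
#' (gradient RMS on brightfield), shape (area, aspect ratio, major axis)
#' from the brightfield threshold mask, brightfield texture on the threshold
#' mask, fluorescence texture and intensity-weighted axis on the
#' morphology-combined mask, and background-subtracted RSG/PI intensities.
#' Events whose brightfield mask is empty return sentinels throughout and
#' are routed to `unclassified` downstream.
#'
#' @param image An [event_image()].
#' @param granularity Co-occurrence offset for the texture statistics.
#' @param levels Gray levels for the texture statistics.
#' @return A one-row tibble with the columns of [feature_columns()].
#' @export
extract_features <- function(image, granularity = 1L, levels = 32L) {
  px <- image$pixel_size
  m_bf <- compute_mask(image, "bf", "otsu_threshold")
  m_mc <- compute_mask(image, "bf", "morphology_combined")
  sf <- shape_features(m_bf, px)
  h_bf <- haralick_stats(image, "bf", m_bf, granularity, levels)
  h_rsg <- haralick_stats(image, "rsg", m_mc, granularity, levels)
  tibble::tibble(
    gradient_rms = gradient_rms(image, "bf", m_bf),
    area_um2 = sf$area_um2,
    aspect_ratio = sf$aspect_ratio,
    major_axis_um = sf$major_axis_um,
    major_axis_intensity_um = major_axis_intensity(image, "rsg", m_mc, px),
    h_entropy_mean_bf = h_bf$entropy_mean,
    h_entropy_std_bf = h_bf$entropy_std,
    h_homogeneity_mean_bf = h_bf$homogeneity_mean,
    h_homogeneity_std_bf = h_bf$homogeneity_std,
    h_entropy_mean_rsg = h_rsg$entropy_mean,
    h_entropy_std_rsg = h_rsg$entropy_std,
    rsg_intensity = max(channel_intensity(image, "rsg", m_mc), 0),
    pi_intensity = max(channel_intensity(image, "pi", m_mc), 0)
  )
}
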