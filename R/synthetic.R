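# Seeded synthetic image/mask generator. The fixtures emulate the
# statistical shape of desk-scale biomedical segmentation data: binary
# "lesion/mitochondria-like" blobs on a textured background, and a 3-class
# cardiac-like geometry (an inner chamber nested in a muscular ring with an
# adjacent atrium below). Identical specs produce byte-identical datasets.

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

#' Specification of a synthetic dataset
#'
#' @param n_images number of image/mask pairs.
#' @param image_size square side in pixels (>= 32; default 128, the size
#'   all training data is rescaled to).
#' @param task `"binary"` (blob-on-texture) or `"multiclass3"` (nested
#'   cardiac-like geometry with labels 0..3).
#' @param channels 1 (grayscale) or 3.
#' @param noise_sd standard deviation of the additive Gaussian pixel noise
#'   (intensity units on the [0, 1] scale).
#' @param blob_count integer range (min, max) of blobs per binary image.
#' @param contrast intensity offset of foreground structures over the
#'   background (intensity units).
#' @param fg_range admissible per-image foreground fraction band for the
#'   binary task (class imbalance control).
#' @param seed integer RNG seed; the whole dataset is a pure function of
#'   the spec.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_images, image_size = 128,
                           task = c("binary", "multiclass3"), channels = 1,
                           noise_sd = 0.05, blob_count = c(1, 3),
                           contrast = 0.35, fg_range = c(0.02, 0.40),
                           seed = 1) {
  task <- match.arg(task)
  if (image_size < 32) abort("`image_size` must be at least 32")
  if (!channels %in% c(1, 3)) abort("`channels` must be 1 or 3")
  if (n_images < 1) abort("`n_images` must be positive")
  structure(list(n_images = n_images, image_size = image_size, task = task,
                 channels = channels, noise_sd = noise_sd,
                 blob_count = blob_count, contrast = contrast,
                 fg_range = fg_range, seed = seed),
            class = "synthetic_spec")
}

# Smooth low-frequency background texture in roughly [-1, 1].
random_texture <- function(s) {
  xy <- seq(0, 1, length.out = s)
  tex <- matrix(0, s, s)
  for (k in 1:4) {
    fx <- runif(1, 0.5, 3); fy <- runif(1, 0.5, 3)
    ph <- runif(1, 0, 2 * pi); amp <- runif(1, 0.2, 0.5)
    tex <- tex + amp * outer(xy, xy, function(a, b) cos(2 * pi * (fx * a + fy * b) + ph))
  }
  tex / max(abs(tex))
}

# Indicator matrix of a randomly perturbed ellipse ("blurred-boundary"
# blob): radial low-order Fourier perturbation of an oriented ellipse.
random_blob_mask <- function(s, cx, cy, rx, ry, theta = runif(1, 0, pi),
                             wobble = 0.15) {
  eps <- runif(3, 0, wobble)
  psi <- runif(3, 0, 2 * pi)
  xg <- matrix(seq_len(s), s, s)
  yg <- t(xg)
  dx <- xg - cx; dy <- yg - cy
  xr <- cos(theta) * dx + sin(theta) * dy
  yr <- -sin(theta) * dx + cos(theta) * dy
  phi <- atan2(yr / ry, xr / rx)
  rho <- 1 + eps[1] * cos(2 * phi + psi[1]) + eps[2] * cos(3 * phi + psi[2]) +
    eps[3] * cos(4 * phi + psi[3])
  ((xr / rx)^2 + (yr / ry)^2 <= rho^2) * 1
}

ellipse_mask <- function(s, cx, cy, rx, ry) {
  xg <- matrix(seq_len(s), s, s)
  yg <- t(xg)
  (((xg - cx) / rx)^2 + ((yg - cy) / ry)^2 <= 1) * 1
}

minmax01 <- function(m) {
  rng <- range(m)
  if (rng[2] - rng[1] < .Machine$double.eps) return(m * 0)
  (m - rng[1]) / (rng[2] - rng[1])
}

to_channels <- function(img, channels) {
  if (channels == 1) return(array(img, c(dim(img), 1)))
  tint <- 1 + runif(3, -0.05, 0.05)
  out <- array(0, c(dim(img), 3))
  for (c in 1:3) out[, , c] <- pmin(pmax(img * tint[c], 0), 1)
  out
}

#' Generate a binary synthetic dataset
#'
#' Each image is a smooth textured background plus 1-3 smooth random blobs
#' offset by `contrast`, with additive Gaussian noise, min-max normalised
#' to `[0, 1]`. The mask is the blob indicator; per-image foreground
#' fractions are kept inside `fg_range` (default 2-40%) so the fixtures
#' exercise class imbalance.
#'
#' @param spec a [synthetic_spec()] with `task = "binary"`.
#' @return list with `images` (array `(H, W, C, N)`), `masks` (binary array
#'   `(H, W, 1, N)`) and the `spec`.
#' @export
generate_binary <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$task != "binary") abort('`spec$task` must be "binary"')
  s <- spec$image_size
  with_local_seed(spec$seed, {
    images <- array(0, c(s, s, spec$channels, spec$n_images))
    masks <- array(0, c(s, s, 1, spec$n_images))
    for (i in seq_len(spec$n_images)) {
      mask <- NULL
      for (try in 1:50) {
        counts <- seq(spec$blob_count[1], spec$blob_count[2])
        nb <- counts[sample.int(length(counts), 1)]
        m <- matrix(0, s, s)
        for (b in seq_len(nb)) {
          r1 <- runif(1, 0.07, 0.18) * s
          r2 <- runif(1, 0.07, 0.18) * s
          cx <- runif(1, 0.2, 0.8) * s
          cy <- runif(1, 0.2, 0.8) * s
          m <- pmax(m, random_blob_mask(s, cx, cy, r1, r2))
        }
        frac <- mean(m)
        if (frac >= spec$fg_range[1] && frac <= spec$fg_range[2]) {
          mask <- m
          break
        }
      }
      if (is.null(mask)) mask <- m
      img <- 0.45 + 0.12 * random_texture(s) + spec$contrast * mask +
        rnorm(s * s, sd = spec$noise_sd)
      img <- minmax01(matrix(img, s, s))
      images[, , , i] <- to_channels(img, spec$channels)
      masks[, , 1, i] <- mask
    }
    list(images = images, masks = masks, spec = spec)
  })
}

#' Generate a 3-class nested-structure dataset
#'
#' Cardiac-like geometry with labels 0 (background), 1 (inner chamber,
#' endocardium-like), 2 (surrounding muscular ring, epicardium-like), and
#' 3 (adjacent atrium-like ellipse below). Label 1 sits strictly inside the
#' label-2 ring (outer radii 1.5x the inner, so the ring is the larger
#' structure) and the classes are mutually exclusive.
#'
#' @param spec a [synthetic_spec()] with `task = "multiclass3"`.
#' @return list with `images`, integer `masks` with labels {0, 1, 2, 3},
#'   and the `spec`.
#' @export
generate_multiclass3 <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$task != "multiclass3") abort('`spec$task` must be "multiclass3"')
  s <- spec$image_size
  with_local_seed(spec$seed, {
    images <- array(0, c(s, s, spec$channels, spec$n_images))
    masks <- array(0, c(s, s, 1, spec$n_images))
    for (i in seq_len(spec$n_images)) {
      r1x <- runif(1, 0.10, 0.16) * s
      r1y <- runif(1, 0.13, 0.20) * s
      cx <- runif(1, 0.40, 0.60) * s
      cy <- runif(1, 0.30, 0.42) * s
      inner <- ellipse_mask(s, cx, cy, r1x, r1y)
      outer_ <- ellipse_mask(s, cx, cy, 1.5 * r1x, 1.5 * r1y)
      r3x <- runif(1, 0.10, 0.16) * s
      r3y <- runif(1, 0.08, 0.12) * s
      cy3 <- cy + 1.5 * r1y + r3y + 2
      atrium <- ellipse_mask(s, cx + runif(1, -0.05, 0.05) * s, cy3, r3x, r3y)
      lab <- matrix(0, s, s)
      lab[outer_ == 1] <- 2
      lab[inner == 1] <- 1
      lab[atrium == 1 & lab == 0] <- 3
      base <- c(0.25, 0.75, 0.45, 0.65)
      img <- base[lab + 1] + 0.08 * random_texture(s) +
        rnorm(s * s, sd = spec$noise_sd)
      img <- minmax01(matrix(img, s, s))
      images[, , , i] <- to_channels(img, spec$channels)
      masks[, , 1, i] <- lab
    }
    list(images = images, masks = masks, spec = spec)
  })
}

#' Min-max normalise and resize an image
#'
#' Normalises a 2-D image to `[0, 1]` (a constant image maps to zeros) and
#' resizes it with half-pixel-centred bilinear interpolation (images) or
#' nearest-neighbour sampling (label masks, which must not be blended).
#' Resizing to the same size is the identity; a 2x bilinear downsampling
#' equals the 2x2 block average.
#'
#' @param image numeric matrix.
#' @param target_size output side length in pixels.
#' @param method `"bilinear"` for intensity images, `"nearest"` for masks.
#' @param normalize min-max normalise before resizing (skip for masks).
#' @return `target_size x target_size` matrix.
#' @export
normalize_and_resize <- function(image, target_size,
                                 method = c("bilinear", "nearest"),
                                 normalize = TRUE) {
  method <- match.arg(method)
  if (!is.matrix(image)) abort("`image` must be a matrix")
  if (normalize) image <- minmax01(image)
  resize_matrix(image, target_size, target_size, method)
}

resize_matrix <- function(m, out_h, out_w, method = "bilinear") {
  h <- nrow(m); w <- ncol(m)
  if (h == out_h && w == out_w) return(m)
  ry <- h / out_h; rx <- w / out_w
  yc <- (seq_len(out_h) - 0.5) * ry - 0.5
  xc <- (seq_len(out_w) - 0.5) * rx - 0.5
  if (method == "nearest") {
    yi <- pmin(pmax(round(yc) + 1, 1), h)
    xi <- pmin(pmax(round(xc) + 1, 1), w)
    return(m[yi, xi, drop = FALSE])
  }
  y0 <- pmin(pmax(floor(yc), 0), h - 1)
  x0 <- pmin(pmax(floor(xc), 0), w - 1)
  y1 <- pmin(y0 + 1, h - 1)
  x1 <- pmin(x0 + 1, w - 1)
  wy <- pmin(pmax(yc - y0, 0), 1)
  wx <- pmin(pmax(xc - x0, 0), 1)
  a <- m[y0 + 1, x0 + 1, drop = FALSE]
  b <- m[y0 + 1, x1 + 1, drop = FALSE]
  c_ <- m[y1 + 1, x0 + 1, drop = FALSE]
  d <- m[y1 + 1, x1 + 1, drop = FALSE]
  wym <- matrix(wy, out_h, out_w)
  wxm <- matrix(wx, out_h, out_w, byrow = TRUE)
  (1 - wym) * ((1 - wxm) * a + wxm * b) + wym * ((1 - wxm) * c_ + wxm * d)
}

#' Paired augmentation of an image and its mask
#'
#' `apply_augmentation()` is the deterministic core: horizontal/vertical
#' flips, rotation by multiples of 90 degrees, and (image-only) intensity
#' gain/offset jitter with clipping to `[0, 1]`. Geometric transforms are
#' applied identically to the mask so labels are preserved as a set.
#' `augment_pair()` draws the transform parameters from a seeded RNG.
#'
#' @param image array `(H, W, C)` or matrix.
#' @param mask matrix of labels.
#' @param hflip,vflip logical flips.
#' @param rot90 number of counter-clockwise quarter turns (0-3).
#' @param gain,offset intensity jitter applied to the image only.
#' @return list with `image` and `mask`.
#' @export
apply_augmentation <- function(image, mask, hflip = FALSE, vflip = FALSE,
                               rot90 = 0, gain = 1, offset = 0) {
  img <- if (is.matrix(image)) array(image, c(dim(image), 1)) else image
  squeeze <- is.matrix(image)
  geo <- function(m) {
    if (hflip) m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
    if (vflip) m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
    for (k in seq_len(rot90 %% 4)) m <- t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
    m
  }
  out <- array(0, dim(img))
  for (c in seq_len(dim(img)[3])) {
    out[, , c] <- pmin(pmax(geo(img[, , c]) * gain + offset, 0), 1)
  }
  if (squeeze) out <- out[, , 1]
  list(image = out, mask = geo(mask))
}

#' @rdname apply_augmentation
#' @param seed integer seed for the transform draw.
#' @export
augment_pair <- function(image, mask, seed) {
  with_local_seed(seed, {
    apply_augmentation(image, mask,
                       hflip = runif(1) < 0.5, vflip = runif(1) < 0.5,
                       rot90 = sample(0:3, 1),
                       gain = runif(1, 0.9, 1.1),
                       offset = runif(1, -0.05, 0.05))
  })
}

#' Train/validation/test split
#'
#' Seeded shuffle of `1..n` into disjoint, exhaustive index sets of sizes
#' `floor(0.8 n)` (train), `floor(0.1 n)` (validation), and the remainder
#' (test) by default, following the 80/10/10 protocol.
#'
#' @param n number of samples (>= 10).
#' @param seed integer shuffle seed.
#' @param fractions length-3 non-negative vector summing to 1 (train,
#'   validation, test).
#' @return list of integer vectors `train`, `val`, `test`.
#' @export
split_dataset <- function(n, seed, fractions = c(0.8, 0.1, 0.1)) {
  if (n < 10) abort("`n` must be at least 10")
  if (length(fractions) != 3 || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-8) {
    abort("`fractions` must be three non-negative numbers summing to 1")
  }
  with_local_seed(seed, {
    idx <- sample.int(n)
    n_train <- floor(fractions[1] * n)
    n_val <- floor(fractions[2] * n)
    list(train = sort(idx[seq_len(n_train)]),
         val = sort(idx[n_train + seq_len(n_val)]),
         test = sort(idx[(n_train + n_val + 1):n]))
  })
}

#' Write / read a dataset as paired PNG files
#'
#' Images are written as `img_%04d.png`, masks as `msk_%04d.png` (labels
#' scaled by 1/255 so they round-trip exactly), plus a `manifest.json`
#' describing the generating spec.
#'
#' @param data list with `images`, `masks` (and optionally `spec`).
#' @param dir output directory (created if needed).
#' @return `write_dataset()` the directory, invisibly; `read_dataset()` a
#'   list with `images`, `masks`, `manifest`.
#' @export
write_dataset <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- dim(data$images)[4]
  for (i in seq_len(n)) {
    img <- data$images[, , , i]
    if (length(dim(img)) == 3 && dim(img)[3] == 1) img <- img[, , 1]
    png::writePNG(img, file.path(dir, sprintf("img_%04d.png", i)))
    png::writePNG(data$masks[, , 1, i] / 255,
                  file.path(dir, sprintf("msk_%04d.png", i)))
  }
  manifest <- list(n_images = n, dim = dim(data$images))
  if (!is.null(data$spec)) manifest$spec <- unclass(data$spec)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  imgs <- sort(list.files(dir, "^img_\\d+\\.png$", full.names = TRUE))
  msks <- sort(list.files(dir, "^msk_\\d+\\.png$", full.names = TRUE))
  if (length(imgs) == 0) abort("no image files found")
  first <- png::readPNG(imgs[1])
  ch <- if (length(dim(first)) == 2) 1 else dim(first)[3]
  h <- dim(first)[1]; w <- dim(first)[2]
  images <- array(0, c(h, w, ch, length(imgs)))
  masks <- array(0, c(h, w, 1, length(msks)))
  for (i in seq_along(imgs)) {
    im <- png::readPNG(imgs[i])
    images[, , , i] <- if (ch == 1) array(im, c(h, w, 1)) else im[, , seq_len(ch)]
    masks[, , 1, i] <- round(png::readPNG(msks[i]) * 255)
  }
  manifest_path <- file.path(dir, "manifest.json")
  manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  }
  list(images = images, masks = masks, manifest = manifest)
}
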