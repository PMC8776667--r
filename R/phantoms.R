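# Synthetic CT phantom generator. Real pancreatic-cyst cohorts are not
# publicly deposited, so the pipeline is exercised on seeded 2-D phantoms:
# one elliptical cystic lesion per slice, hypodense fluid partitioned into
# locules by thin septa, surrounded by brighter parenchyma, plus additive
# Gaussian noise. The two classes differ in internal architecture the way
# the lesions do radiologically: SCN-like lesions are microcystic
# ("honeycomb", many small locules), MCN-like lesions are uni/oligo-locular.

#' Phantom generator parameters
#'
#' Defaults encode plausible unenhanced-CT soft-tissue contrast (cyst fluid
#' near water, enhancing septa, pancreatic parenchyma) and the radiological
#' honeycomb-vs-unilocular distinction between the two lesion classes.
#'
#' @param image_size pixels per side of the square slice (>= 64).
#' @param fluid_hu,septum_hu,parenchyma_hu mean intensities in Hounsfield
#'   units; must satisfy `fluid_hu < septum_hu < parenchyma_hu`.
#' @param noise_sigma SD of additive Gaussian noise, in HU (>= 0).
#' @param scn_locules,mcn_locules integer ranges `c(min, max)` for the number
#'   of locules per lesion in each class (SCN many/small, MCN few/large).
#' @param lesion_radius range `c(min, max)` of the lesion semi-axes, pixels.
#' @param seed integer RNG seed used when no explicit seed is passed to the
#'   generator functions.
#' @return A validated list of class `"phantom_params"`.
#' @export
phantom_params <- function(image_size = 128L,
                           fluid_hu = 10, septum_hu = 60, parenchyma_hu = 90,
                           noise_sigma = 10,
                           scn_locules = c(6L, 12L),
                           mcn_locules = c(1L, 3L),
                           lesion_radius = c(15, 30),
                           seed = 1L) {
  if (image_size < 64) cyst_error("image_size must be >= 64", "cystct_param_error")
  if (!(fluid_hu < septum_hu && septum_hu < parenchyma_hu)) {
    cyst_error("need fluid_hu < septum_hu < parenchyma_hu (cyst fluid is hypodense)",
               "cystct_param_error")
  }
  if (noise_sigma < 0) cyst_error("noise_sigma must be >= 0", "cystct_param_error")
  for (rng in list(scn_locules, mcn_locules, lesion_radius)) {
    if (length(rng) != 2 || rng[1] > rng[2] || rng[1] < 1) {
      cyst_error("ranges must be c(min, max) with 1 <= min <= max", "cystct_param_error")
    }
  }
  if (lesion_radius[2] > image_size / 3) {
    cyst_error("lesion_radius too large for image_size", "cystct_param_error")
  }
  structure(list(
    image_size = as.integer(image_size),
    fluid_hu = fluid_hu, septum_hu = septum_hu, parenchyma_hu = parenchyma_hu,
    noise_sigma = noise_sigma,
    scn_locules = as.integer(scn_locules), mcn_locules = as.integer(mcn_locules),
    lesion_radius = lesion_radius, seed = as.integer(seed)
  ), class = "phantom_params")
}

phantom_labels <- c("SCN", "MCN")

# Sample one lesion's geometry (ellipse + internal locule seed points).
# Separated from rendering so several slices of one synthetic patient can
# share geometry and differ only in the noise realisation.
sample_geometry <- function(label, params) {
  s <- params$image_size
  rr <- params$lesion_radius
  a <- runif(1, rr[1], rr[2])
  b <- runif(1, rr[1], rr[2])
  theta <- runif(1, 0, pi)
  m <- max(a, b) + 3
  centre <- runif(2, m + 1, s - m)
  nloc_rng <- if (label == "SCN") params$scn_locules else params$mcn_locules
  nloc <- if (nloc_rng[1] == nloc_rng[2]) nloc_rng[1] else
    sample(seq(nloc_rng[1], nloc_rng[2]), 1)
  # locule seeds: rejection-sample points well inside the ellipse
  seeds <- matrix(NA_real_, 0, 2)
  while (nrow(seeds) < nloc) {
    p <- runif(2, -1, 1)
    if (sum(p^2) < 0.85^2) {
      ct <- cos(theta); st <- sin(theta)
      pt <- centre + c(ct * p[1] * a - st * p[2] * b,
                       st * p[1] * a + ct * p[2] * b)
      seeds <- rbind(seeds, pt)
    }
  }
  list(centre = centre, a = a, b = b, theta = theta, seeds = seeds,
       n_locules = nloc)
}

# Render the noise-free slice for a geometry: parenchyma background, fluid
# inside the ellipse, septa on the rim and on boundaries between the
# Voronoi cells of the locule seeds (~2 px wide).
render_geometry <- function(geom, params) {
  s <- params$image_size
  img <- matrix(params$parenchyma_hu, s, s)
  rg <- matrix(seq_len(s), s, s)         # row index of each pixel
  cg <- matrix(seq_len(s), s, s, byrow = TRUE)
  ct <- cos(geom$theta); st <- sin(geom$theta)
  dx <- rg - geom$centre[1]; dy <- cg - geom$centre[2]
  u <- (ct * dx + st * dy) / geom$a
  v <- (-st * dx + ct * dy) / geom$b
  rad2 <- u^2 + v^2
  inside <- rad2 <= 1
  # rim: ~2 px thick band just inside the ellipse boundary
  rim_frac <- 2 / min(geom$a, geom$b)
  rim <- inside & (sqrt(rad2) >= 1 - rim_frac)
  img[inside] <- params$fluid_hu
  septa <- rim
  if (nrow(geom$seeds) >= 2) {
    best1 <- matrix(Inf, s, s); best2 <- matrix(Inf, s, s)
    for (i in seq_len(nrow(geom$seeds))) {
      d <- sqrt((rg - geom$seeds[i, 1])^2 + (cg - geom$seeds[i, 2])^2)
      closer <- d < best1
      best2[closer] <- best1[closer]
      best1[closer] <- d[closer]
      mid <- !closer & (d < best2)
      best2[mid] <- d[mid]
    }
    ridge <- (best2 - best1) < 1.0   # Voronoi ridge, ~2 px wide
    septa <- septa | (inside & ridge)
  }
  img[septa & inside] <- params$septum_hu
  list(image = img, mask = inside)
}

#' Generate one synthetic CT slice
#'
#' @param label `"SCN"` (honeycomb, many small locules) or `"MCN"`
#'   (one/few large locules).
#' @param params a [phantom_params()] object.
#' @param seed integer seed; defaults to `params$seed`. Identical
#'   `(label, params, seed)` give bit-identical output.
#' @return A list of class `"phantom_sample"` with elements `image` (HU
#'   matrix), `mask` (logical matrix, lesion support), `label`, `patient_id`,
#'   `slice_index`.
#' @examples
#' p <- generate_phantom("SCN", phantom_params(), seed = 7)
#' range(p$image)
#' @export
generate_phantom <- function(label, params = phantom_params(), seed = params$seed) {
  if (!is.character(label) || length(label) != 1 || !(label %in% phantom_labels)) {
    cyst_error("label must be \"SCN\" or \"MCN\"", "cystct_label_error")
  }
  stopifnot(inherits(params, "phantom_params"))
  with_seed(seed, {
    geom <- sample_geometry(label, params)
    base <- render_geometry(geom, params)
    img <- base$image
    if (params$noise_sigma > 0) {
      img <- img + matrix(stats::rnorm(length(img), 0, params$noise_sigma),
                          nrow(img), ncol(img))
    }
    structure(list(image = img, mask = base$mask, label = label,
                   patient_id = NA_character_, slice_index = 1L),
              class = "phantom_sample")
  })
}

#' Generate a phantom dataset on disk
#'
#' Writes one lesion per synthetic patient, `slices_per_patient` slices each:
#' slices of a patient share the lesion geometry and differ only in the noise
#' realisation, which creates the intra-patient correlation that makes
#' image-level vs patient-level splitting meaningfully different. Images are
#' 16-bit grayscale TIFF storing `HU + 1024`; masks are 8-bit 0/255 PNG; the
#' manifest is a CSV with columns `path,mask_path,label,patient_id,slice_index`.
#'
#' @param n_per_class synthetic patients per class (>= 1).
#' @param slices_per_patient slices per patient (>= 1).
#' @param params a [phantom_params()] object; `params$seed` fixes the whole
#'   dataset.
#' @param dir output directory (created if needed).
#' @param write if `FALSE`, keep everything in memory and return the samples
#'   alongside the manifest (no files written; `path`/`mask_path` empty).
#' @return Invisibly, a list with `manifest` (data.frame) and, when
#'   `write = FALSE`, `samples` (list of `phantom_sample`).
#' @export
generate_dataset <- function(n_per_class, slices_per_patient = 1L,
                             params = phantom_params(), dir = NULL,
                             write = !is.null(dir)) {
  if (n_per_class < 1) cyst_error("n_per_class must be >= 1", "cystct_param_error")
  if (slices_per_patient < 1) cyst_error("slices_per_patient must be >= 1", "cystct_param_error")
  if (write) {
    if (is.null(dir)) cyst_error("dir required when write = TRUE", "cystct_io_error")
    ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || file.access(dir, 2) != 0) {
      cyst_error(sprintf("output directory not writable: %s", dir), "cystct_io_error")
    }
  }
  rows <- list(); samples <- list(); k <- 0L
  for (label in phantom_labels) {
    for (i in seq_len(n_per_class)) {
      pid <- sprintf("%s%03d", label, i)
      geom_seed <- derive_seed(params$seed, paste0("geom/", pid))
      geom <- with_seed(geom_seed, sample_geometry(label, params))
      base <- render_geometry(geom, params)
      for (sl in seq_len(slices_per_patient)) {
        noise_seed <- derive_seed(params$seed, sprintf("noise/%s/%d", pid, sl))
        img <- base$image
        if (params$noise_sigma > 0) {
          img <- img + with_seed(noise_seed,
            matrix(stats::rnorm(length(img), 0, params$noise_sigma),
                   nrow(img), ncol(img)))
        }
        k <- k + 1L
        path <- mask_path <- ""
        if (write) {
          # manifest paths stay relative to the dataset directory so the
          # written files are byte-identical wherever the dataset lands
          path <- sprintf("%s_s%02d.tif", pid, sl)
          mask_path <- sprintf("%s_s%02d_mask.png", pid, sl)
          write_hu_tiff(img, file.path(dir, path))
          png::writePNG(matrix(as.numeric(base$mask), nrow(img)),
                        file.path(dir, mask_path))
        }
        rows[[k]] <- data.frame(path = path, mask_path = mask_path,
                                label = label, patient_id = pid,
                                slice_index = sl, stringsAsFactors = FALSE)
        if (!write) {
          samples[[k]] <- structure(
            list(image = img, mask = base$mask, label = label,
                 patient_id = pid, slice_index = sl),
            class = "phantom_sample")
        }
      }
    }
  }
  manifest <- do.call(rbind, rows)
  if (write) {
    utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  invisible(list(manifest = manifest, samples = if (!write) samples))
}

# HU image <-> 16-bit grayscale TIFF with a +1024 offset (air -1024 -> 0).
write_hu_tiff <- function(image, path) {
  stored <- pmin(pmax(round(image) + 1024, 0), 65535)
  tiff::writeTIFF(stored / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

read_hu_tiff <- function(path) {
  if (!file.exists(path)) cyst_error(sprintf("no such file: %s", path), "cystct_io_error")
  round(tiff::readTIFF(path) * 65535) - 1024
}

#' Read one slice (and optional mask) written by [generate_dataset()]
#'
#' @param path 16-bit HU-offset TIFF image path.
#' @param mask_path optional 0/255 PNG mask path.
#' @return A `phantom_sample`-shaped list with `image` (HU matrix) and
#'   `mask` (logical matrix or `NULL`).
#' @export
read_slice <- function(path, mask_path = NULL) {
  img <- read_hu_tiff(path)
  mask <- NULL
  if (!is.null(mask_path) && nzchar(mask_path)) {
    if (!file.exists(mask_path)) {
      cyst_error(sprintf("no such file: %s", mask_path), "cystct_io_error")
    }
    m <- png::readPNG(mask_path)
    if (length(dim(m)) == 3) m <- m[, , 1]
    mask <- m > 0.5
  }
  list(image = img, mask = mask)
}
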