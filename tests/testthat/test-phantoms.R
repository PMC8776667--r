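test_that("phantom generation is seed-deterministic and label-checked", {
  p1 <- generate_phantom("SCN", phantom_params(), seed = 0)
  p2 <- generate_phantom("SCN", phantom_params(), seed = 0)
  expect_identical(p1$image, p2$image)
  expect_identical(p1$mask, p2$mask)
  p3 <- generate_phantom("SCN", phantom_params(), seed = 1)
  expect_false(identical(p1$image, p3$image))
  expect_error(generate_phantom("IPMN", phantom_params()), class = "cystct_label_error")
})

test_that("noise-free phantoms take only the three tissue intensities", {
  prm <- phantom_params(noise_sigma = 0)
  for (lab in c("SCN", "MCN")) {
    p <- generate_phantom(lab, prm, seed = 4)
    expect_setequal(unique(as.vector(p$image)),
                    c(prm$fluid_hu, prm$septum_hu, prm$parenchyma_hu))
    # mask fidelity: inside the lesion only fluid and septum occur
    expect_true(all(p$image[p$mask] %in% c(prm$fluid_hu, prm$septum_hu)))
    expect_true(all(p$image[!p$mask] == prm$parenchyma_hu))
  }
})

test_that("parameter invariants are enforced", {
  expect_error(phantom_params(image_size = 32), class = "cystct_param_error")
  expect_error(phantom_params(fluid_hu = 100), class = "cystct_param_error")
  expect_error(phantom_params(noise_sigma = -1), class = "cystct_param_error")
  expect_error(phantom_params(scn_locules = c(5, 2)), class = "cystct_param_error")
})

test_that("honeycomb SCN phantoms carry more internal edge structure than MCN", {
  prm <- phantom_params()
  cp <- canny_params()
  w <- window_spec()
  edge_frac <- function(label, seed) {
    p <- generate_phantom(label, prm, seed = seed)
    e <- canny_edges(window_image(p$image, w), cp)
    sum(e[p$mask]) / sum(p$mask)
  }
  scn <- vapply(1:50, function(s) edge_frac("SCN", s), 0)
  mcn <- vapply(1:50, function(s) edge_frac("MCN", s), 0)
  expect_gt(mean(scn), mean(mcn))
})

test_that("dataset bookkeeping: counts, patient-label mapping, determinism", {
  prm <- phantom_params(seed = 5)
  ds <- generate_dataset(10, 7, prm, write = FALSE)
  m <- ds$manifest
  expect_equal(nrow(m), 140)
  expect_equal(as.vector(table(m$label)), c(70, 70))
  expect_true(all(tapply(m$label, m$patient_id, function(x) length(unique(x))) == 1))
  expect_equal(sum(m$slice_index == 3), 20)
  # same-patient slices share geometry (masks identical), differ in noise
  s1 <- ds$samples[[1]]; s2 <- ds$samples[[2]]
  expect_identical(s1$patient_id, s2$patient_id)
  expect_identical(s1$mask, s2$mask)
  expect_false(identical(s1$image, s2$image))
})

test_that("on-disk datasets round-trip HU exactly and are byte-stable", {
  prm <- phantom_params(seed = 9)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_dataset(2, 2, prm, dir = d1)
  generate_dataset(2, 2, prm, dir = d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  m <- load_manifest(file.path(d1, "manifest.csv"))
  s <- read_slice(m$path[1], m$mask_path[1])
  mem <- generate_dataset(2, 2, prm, write = FALSE)
  expect_equal(s$image, round(mem$samples[[1]]$image), tolerance = 0)
  expect_identical(s$mask, mem$samples[[1]]$mask)
})

test_that("unwritable output directory raises an I/O error", {
  expect_error(generate_dataset(1, 1, phantom_params(), dir = "/proc/nope"),
               class = "cystct_io_error")
})
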