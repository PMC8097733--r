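make_tiff <- function(planes, path, depth = 16L) {
  tiff::writeTIFF(lapply(planes, function(p) p / (2^depth - 1)), path,
                  bits.per.sample = depth, compression = "none")
  path
}

test_that("a multi-page TIFF round-trips through the lazy reader", {
  planes <- lapply(1:3, function(i) matrix(round(seq(0, 1000, length.out = 35)) + i,
                                           5, 7))
  path <- withr::local_tempfile(fileext = ".tif")
  make_tiff(planes, path)
  st <- open_stack(path)
  expect_equal(st$n_z, 3)
  expect_equal(st$n_c, 1)
  expect_equal(c(st$height, st$width), c(5L, 7L))
  for (z in 0:2) expect_equal(st$get_plane(0, 0, z), planes[[z + 1]])
  expect_identical(st$get_plane(0, 0, 1), st$get_plane(0, 0, 1))
  expect_error(st$get_plane(0, 0, 3), "out of range")
})

test_that("axis extents come from flags or embedded hyperstack metadata", {
  planes <- lapply(1:8, function(i) matrix(i * 10, 4, 4))
  path <- withr::local_tempfile(fileext = ".tif")
  make_tiff(planes, path)
  st <- open_stack(path, channels = 2, slices = 4)
  expect_equal(c(st$n_c, st$n_z, st$n_t), c(2L, 4L, 1L))
  # pages are channel-fastest: plane (t=0, c=1, z=2) is page 6
  expect_equal(st$get_plane(0, 1, 2), planes[[6]])
  expect_error(open_stack(path, channels = 3), "do not match")

  meta <- devils:::parse_imagej_description("ImageJ=1.53t\nimages=8\nchannels=2\nslices=4\nframes=1")
  expect_equal(meta$channels, 2L)
  expect_equal(meta$slices, 4L)
  expect_equal(meta$frames, 1L)
})

test_that("unreadable or non-grayscale input fails with a clear error", {
  bad <- withr::local_tempfile(fileext = ".tif")
  writeBin(as.raw(c(0x49, 0x49, 0x2a, 0x00, 0x08)), bad)   # truncated header
  expect_error(open_stack(bad), "cannot read TIFF")
  rgb <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(array(0.5, c(4, 4, 3)), rgb, bits.per.sample = 8L)
  expect_error(open_stack(rgb), "grayscale")
  expect_error(open_stack(withr::local_tempfile(fileext = ".tif")), "exist")
})

test_that("processing a stack is worker-count invariant, complete, and correctly named", {
  planes <- lapply(1:4, function(i) {
    pl <- matrix(10, 24, 24)
    pl[6:12 + i, 6:12] <- 400 * i
    pl
  })
  st <- as_lazy_stack(planes)
  pr <- devils_params(p = 4, division_scale = 100)
  d1 <- withr::local_tempdir()
  d4 <- withr::local_tempdir()
  r1 <- process_stack(st, pr, d1, workers = 1, stem = "toy")
  r4 <- process_stack(st, pr, d4, workers = 4, stem = "toy")
  expect_setequal(r1$files, sprintf("toy_t000_c00_z%04d.tif", 0:3))
  expect_equal(length(list.files(d1, pattern = "\\.tif$")), 4)
  for (f in r1$files) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d4, f))))
  }
  expect_equal(r1$stats$z, 0:3)
  expect_true(all(r1$stats$mean <= r1$stats$max))
  expect_true(file.exists(file.path(d1, "plane_stats.tsv")))
})

test_that("a constant stack converts to the single predicted 16-bit value", {
  st <- as_lazy_stack(replicate(2, matrix(123, 16, 16), simplify = FALSE))
  d <- withr::local_tempdir()
  run <- process_stack(st, devils_params(p = 3, division_scale = 10), d)
  # devils output is 0; with bounds (-100, 10000), 0 maps to this bin:
  expected <- round(100 / 10100 * 65535)
  re <- open_devils_folder(d)
  expect_true(all(re$get_plane(0, 0, 0) == expected))
  expect_true(all(run$stats$mean == expected))
})

test_that("per-channel parameters broadcast by channel, not by plane", {
  planes <- lapply(1:4, function(i) random_plane(20, seed = i, lo = 0, hi = 500))
  st <- as_lazy_stack(planes, n_c = 2)    # planes 1,3 -> c0; 2,4 -> c1
  pr <- list(devils_params(p = 3, division_scale = 50),
             devils_params(p = 6, division_scale = 50))
  d <- withr::local_tempdir()
  process_stack(st, pr, d, stem = "mc")
  re <- open_devils_folder(d)
  for (ci in 0:1) {
    want <- convert_bit_depth(devils_transform(planes[[ci + 1]], pr[[ci + 1]]),
                              -100, 10000, 16)
    expect_equal(re$get_plane(0, ci, 0), want)
  }
  expect_error(process_stack(st, list(pr[[1]], pr[[1]], pr[[2]]), d),
               "channel")
})

test_that("a processed folder reopens exactly and gaps are reported by name", {
  planes <- lapply(1:6, function(i) random_plane(12, seed = i, lo = 0, hi = 300))
  st <- as_lazy_stack(planes, n_c = 1)
  d <- withr::local_tempdir()
  run <- process_stack(st, devils_params(p = 3, division_scale = 40), d, stem = "rt")
  re <- open_devils_folder(d)
  expect_equal(re$n_z, 6)
  for (z in 0:5) {
    want <- convert_bit_depth(
      devils_transform(planes[[z + 1]], devils_params(p = 3, division_scale = 40)),
      -100, 10000, 16)
    expect_equal(re$get_plane(0, 0, z), want)
  }
  file.remove(file.path(d, "rt_t000_c00_z0003.tif"))
  expect_error(open_devils_folder(d), "rt_t000_c00_z0003")
  expect_error(open_devils_folder(withr::local_tempdir()), "no plane files")
})

test_that("32-bit output stores real values to float precision", {
  pl <- random_plane(16, seed = 2, lo = 0, hi = 900)
  st <- as_lazy_stack(list(pl))
  d <- withr::local_tempdir()
  process_stack(st, devils_params(p = 3, division_scale = 40, out_depth = 32), d,
                stem = "f32")
  re <- open_devils_folder(d)
  want <- devils_transform(pl, devils_params(p = 3, division_scale = 40))
  got <- re$get_plane(0, 0, 0)
  expect_equal(got, pmax(want, 0), tolerance = 1e-5)
})

test_that("HDF5 export lays out a BigDataViewer dataset and round-trips", {
  planes <- withr::with_seed(4, lapply(1:8, function(i)
    matrix(round(stats::runif(256, 0, 60000)), 16, 16)))
  st <- as_lazy_stack(planes, n_c = 2)    # 2 channels x 4 slices
  h5 <- file.path(withr::local_tempdir(), "bdv.h5")
  paths <- export_hdf5(st, h5)
  ls <- rhdf5::h5ls(h5)
  rhdf5::h5closeAll()
  paths_in_file <- file.path(ls$group, ls$name)
  expect_true("/s00/resolutions" %in% paths_in_file)
  expect_true("/s01/subdivisions" %in% paths_in_file)
  expect_true("/t00000/s01/0/cells" %in% paths_in_file)
  cells <- ls[ls$name == "cells", ]
  expect_equal(nrow(cells), 2)
  expect_true(all(cells$dim == "16 x 16 x 4"))
  for (ci in 0:1) {
    a <- read_hdf5_cells(h5, t = 0, c = ci)
    for (z in 0:3) {
      expect_equal(a[, , z + 1], t(st$get_plane(0, ci, z)))
    }
  }
  xml <- xml2::read_xml(paths[["xml"]])
  expect_equal(length(xml2::xml_find_all(xml, "//ViewSetup")), 2)
  expect_equal(xml2::xml_text(xml2::xml_find_first(xml, "//ImageLoader/hdf5")),
               basename(h5))
})

test_that("preview processes exactly one plane and resolves 'middle'", {
  planes <- lapply(1:5, function(i) random_plane(16, seed = i, lo = 0, hi = 200))
  st <- as_lazy_stack(planes)
  pr <- devils_params(p = 3, division_scale = 30)
  pv <- preview_plane(st, params = pr)
  expect_equal(unname(pv$indices), c(0, 0, 2))
  expect_identical(pv$original, planes[[3]])
  expect_equal(pv$processed, devils_transform(planes[[3]], pr))
  expect_error(preview_plane(st, z = 7, params = pr), "out of range")
  # constant plane previews to zero
  stc <- as_lazy_stack(list(matrix(9, 8, 8)))
  expect_lt(max(abs(preview_plane(stc, params = pr)$processed)), 1e-6)
})

test_that("plane statistics report one row per plane with its mean and max", {
  st <- as_lazy_stack(replicate(6, matrix(5, 8, 8), simplify = FALSE), n_c = 2)
  ps <- plane_stats(st)
  expect_equal(nrow(ps), 6)
  expect_true(all(ps$mean == 5 & ps$max == 5))
  planes <- replicate(3, matrix(0, 10, 10), simplify = FALSE)
  planes[[2]][4, 7] <- 100
  ps2 <- plane_stats(as_lazy_stack(planes))
  expect_equal(ps2$max, c(0, 100, 0))
  expect_equal(ps2$mean[2], 1)
})

test_that("planes are loaded on demand, once each, during processing", {
  loads <- new.env(); loads$n <- integer(4)
  st <- devils:::new_lazy_stack(
    get_plane = function(t, c, z) {
      loads$n[z + 1] <- loads$n[z + 1] + 1L
      matrix(50 + z, 12, 12)
    },
    n_t = 1, n_c = 1, n_z = 4, height = 12, width = 12
  )
  expect_equal(loads$n, rep(0L, 4))     # opening reads nothing
  process_stack(st, devils_params(p = 3, division_scale = 20),
                withr::local_tempdir())
  expect_equal(loads$n, rep(1L, 4))     # each plane read exactly once
})

test_that("tone mapping flattens the bell-shaped per-plane mean profile", {
  st <- generate_bell_stack(n_z = 12, side = 64, seed = 1)
  before <- plane_stats(st)$mean
  d <- withr::local_tempdir()
  run <- process_stack(st, devils_params(p = 7, division_scale = 150), d)
  after <- run$stats$mean
  cv <- function(x) stats::sd(x) / mean(x)
  expect_lt(cv(after), cv(before))
})
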