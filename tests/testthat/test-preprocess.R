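# Macular preprocessing chain: selection, crop, binarization, dilation,
# foreground extraction, volume assembly.

test_that("slice selection yields 140 then 70 slices under the defaults", {
  # a lightweight stand-in stack: 400 tiny slices
  stack <- structure(list(slices = replicate(400, matrix(0L, 8, 8),
                                             simplify = FALSE),
                          patient_id = "P", eye_id = "P_OD", label = 0L),
                     class = "bscan_stack")
  cfg <- preprocess_config()
  expect_length(select_slices(stack, cfg, apply_stride = FALSE), 140)
  expect_length(select_slices(stack, cfg), 70)
  id_cfg <- preprocess_config(slice_lo = 0, slice_hi = 400, sample_stride = 1,
                              out_depth = 400)
  expect_length(select_slices(stack, id_cfg), 400)
  short <- stack; short$slices <- short$slices[1:200]
  expect_error(select_slices(short, cfg), "at least 270")
})

test_that("inconsistent slice range / stride / depth configurations are rejected", {
  expect_error(preprocess_config(slice_lo = 130, slice_hi = 270,
                                 sample_stride = 2, out_depth = 60),
               "out_depth")
  expect_error(preprocess_config(slice_lo = 270, slice_hi = 130), "slice_hi")
  expect_error(preprocess_config(dilation_kernel = 4), "odd")
})

test_that("center crop keeps the middle columns with the documented margin", {
  sl <- matrix(0, 640, 400)
  sl[, 201] <- 255   # bright column at 0-based x = 200
  out <- center_crop(sl, 140)
  expect_equal(dim(out), c(640, 140))
  expect_equal(which(out[1, ] > 0) - 1L, 70L)  # 0-based x = 70 after crop
  expect_identical(center_crop(sl, 400), sl)
  expect_error(center_crop(sl, 401), "exceeds")
})

test_that("binarization thresholds at >= and is monotone in the threshold", {
  cfg_fixed <- small_cfg(binarize_method = "fixed", fixed_threshold = 25)
  expect_true(all(binarize_slice(matrix(0, 6, 6), cfg_fixed) == 0))
  cb <- matrix(c(0, 255), 8, 8)
  expect_equal(binarize_slice(cb, cfg_fixed), (cb / 255) * 1L,
               ignore_attr = TRUE)
  sl <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
  ones <- vapply(c(0, 50, 100, 180, 256), function(thr) {
    sum(binarize_slice(sl, small_cfg(binarize_method = "fixed",
                                     fixed_threshold = thr)))
  }, 0)
  expect_true(all(diff(ones) <= 0))
})

test_that("otsu binarization separates a bimodal slice and falls back on constants", {
  sl <- matrix(10, 30, 30); sl[10:20, 5:25] <- 200
  bm <- binarize_slice(sl, small_cfg(binarize_method = "otsu"))
  expect_equal(bm, (sl > 100) * 1L, ignore_attr = TRUE)
  # constant slice: otsu undefined, fixed fallback applies
  cst <- matrix(30, 5, 5)
  bm2 <- binarize_slice(cst, small_cfg(binarize_method = "otsu",
                                       fixed_threshold = 25))
  expect_true(all(bm2 == 1))
})

test_that("dilation matches a brute-force oracle and is extensive", {
  cfg1 <- small_cfg(dilation_kernel = 5, dilation_iters = 1)
  m <- matrix(0L, 11, 11); m[6, 6] <- 1L
  se <- EBImage::makeBrush(5, "disc")
  expect_equal(dilate_mask(m, cfg1), brute_dilate(m, se), ignore_attr = TRUE)
  expect_true(all(dilate_mask(matrix(0L, 7, 7), cfg1) == 0))
  set.seed(3)
  for (i in 1:3) {
    rm_ <- matrix(rbinom(100, 1, 0.2), 10, 10)
    dm <- dilate_mask(rm_, small_cfg())
    expect_true(all(dm[rm_ == 1] == 1))  # input is a subset of the output
  }
})

test_that("foreground extraction keeps only the largest component's filled region", {
  sl <- matrix(7, 20, 20)
  mask <- matrix(0L, 20, 20)
  mask[2:11, 2:11] <- 1L    # area 100
  mask[15:16, 15:20] <- 1L  # area 12
  out <- extract_foreground(sl, mask)
  expect_true(all(out[2:11, 2:11] == 7))
  expect_true(all(out[15:16, 15:20] == 0))
  # one rectangular component: nonzero exactly inside it
  m1 <- matrix(0L, 10, 10); m1[3:6, 4:8] <- 1L
  o1 <- extract_foreground(sl[1:10, 1:10], m1)
  expect_equal((o1 != 0) * 1L, m1, ignore_attr = TRUE)
  expect_warning(o2 <- extract_foreground(sl, matrix(0L, 20, 20)), "empty mask")
  expect_identical(o2, sl)
})

test_that("volume assembly yields the configured shape, [0,1] range and is deterministic", {
  ds <- generate_dataset(1, 1, small_spec(seed = 6), seed = 6)
  v1 <- assemble_volume(ds[[1]], small_cfg())
  expect_s3_class(v1, "oct_volume")
  expect_equal(dim(v1$data), c(48, 48, 16))
  expect_true(all(is.finite(v1$data)))
  expect_gte(min(v1$data), 0)
  expect_lte(max(v1$data), 1)
  v2 <- assemble_volume(ds[[1]], small_cfg())
  expect_identical(v1$data, v2$data)
  expect_equal(v1$label, 1L)
})

test_that("an all-black stack yields an all-zero volume", {
  stack <- structure(list(slices = replicate(64, matrix(0L, 96, 96),
                                             simplify = FALSE),
                          patient_id = "P", eye_id = "P_OD", label = 0L),
                     class = "bscan_stack")
  w <- capture_warnings(v <- assemble_volume(stack, small_cfg()))
  expect_true(length(w) > 0 && all(grepl("empty mask", w)))
  expect_true(all(v$data == 0))
})

test_that("preprocess_dataset writes volumes plus a manifest", {
  dir <- withr::local_tempdir()
  ds <- generate_dataset(2, 0.5, small_spec(seed = 8), seed = 8)
  vols <- preprocess_dataset(ds, small_cfg(), out_dir = dir)
  man <- read.delim(file.path(dir, "manifest.tsv"))
  expect_equal(nrow(man), 2)
  expect_true(all(file.exists(man$path)))
  v <- readRDS(man$path[1])
  expect_equal(v$data, vols[[1]]$data)
})
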