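test_that("NIfTI volumes round-trip with affine and voxel size intact", {
  tmp <- withr::local_tempdir()
  vol <- array(rnorm(4 * 5 * 6), c(4, 5, 6))
  p <- file.path(tmp, "vol.nii.gz")
  write_nifti_volume(vol, p, voxel_size = 2)
  back <- read_nifti_volume(p)
  expect_equal(array(back, dim(vol)), vol, tolerance = 1e-12)
  expect_equal(attr(back, "voxel_size"), 2)
  # masks survive as 0/1
  m <- array(c(TRUE, FALSE), c(4, 5, 6))
  pm <- file.path(tmp, "mask.nii.gz")
  write_nifti_volume(m, pm, voxel_size = 2)
  backm <- read_nifti_volume(pm)
  expect_identical(array(backm != 0, dim(m)), m)
})

test_that("DWI write/read preserves signal and gradient table", {
  tmp <- withr::local_tempdir()
  ph <- simulate_tensor_field(phantom_spec())
  dwi <- tensor_to_dwi(ph, std_gradients())
  prefix <- file.path(tmp, "subj")
  write_dwi(dwi, prefix)
  back <- read_dwi(prefix)
  expect_equal(back$signal, dwi$signal, tolerance = 1e-9)
  expect_equal(back$gradients$bvals, dwi$gradients$bvals)
  expect_equal(back$gradients$bvecs, dwi$gradients$bvecs, tolerance = 1e-6)
})

test_that("label/ROI mask sets round-trip through uint8 NIfTI", {
  tmp <- withr::local_tempdir()
  ph <- simulate_tensor_field(phantom_spec())
  write_mask_set(ph$labels, file.path(tmp, "labels"), voxel_size = 2)
  back <- read_mask_set(file.path(tmp, "labels"))
  for (h in c("left", "right")) for (t in c("proj", "assoc"))
    expect_identical(back[[h]][[t]], ph$labels[[h]][[t]])
})

test_that("scalar map export writes the full set of volumes", {
  tmp <- withr::local_tempdir()
  ch <- std_phantom_chain()
  paths <- write_scalar_maps(ch$fit, file.path(tmp, "maps"))
  expect_true(all(file.exists(paths)))
  expect_true(all(c("fa", "md", "dxx", "dyy", "dzz") %in%
                    sub("[.]nii[.]gz$", "", basename(paths))))
  fa <- read_nifti_volume(file.path(tmp, "maps", "fa.nii.gz"))
  expect_true(all(fa >= 0 & fa <= 1))
})

test_that("ALPS records serialize to JSON with version and parameters", {
  tmp <- withr::local_tempdir()
  ch <- std_phantom_chain()
  res <- compute_alps(ch$fit, ch$rois)
  p <- file.path(tmp, "alps.json")
  write_alps_record(res, p, parameters = list(fraction = 0.87))
  rec <- jsonlite::read_json(p)
  expect_equal(rec$mean_alps_index, 1.5, tolerance = 1e-8)
  expect_equal(rec$parameters$fraction, 0.87)
  expect_equal(rec$software$package, "glymphalps")
})

test_that("run configurations round-trip losslessly through YAML", {
  cfg <- default_run_config(seed = 11)
  cfg$roi$fraction <- 0.75
  cfg$cohort <- list(n_pd = 20L, n_control = 10L)
  tmp <- withr::local_tempfile(fileext = ".yaml")
  write_run_config(cfg, tmp)
  back <- read_run_config(tmp)
  expect_equal(unclass(back), unclass(cfg))
})

test_that("invalid configurations fail before any computation", {
  cfg <- default_run_config()
  cfg$stages <- c("simulate", "roi")      # not contiguous
  expect_error(run_pipeline(cfg), "contiguous")
  cfg2 <- default_run_config()
  cfg2$stages <- "roi"                    # needs labels when not simulating
  expect_error(run_pipeline(cfg2), "labels")
  cfg3 <- default_run_config()
  cfg3$roi$fraction <- 0
  expect_error(run_pipeline(cfg3), "fraction")
})

test_that("the synthetic end-to-end run reports the planted coupling", {
  cfg <- default_run_config(seed = 7)
  cfg$with_dwi <- TRUE
  cfg$n_dwi_subjects <- 2L
  out <- withr::local_tempdir()
  res <- run_pipeline(cfg, out_dir = out)
  expect_s3_class(res, "run_result")
  # imaging chain reproduced each subject's ALPS from raw synthetic DWI
  expect_equal(nrow(res$alps), 2)
  expect_equal(res$alps$mean_alps,
               pmax(res$cohort$alps_true[1:2], 1), tolerance = 1e-6)
  # cohort report: PD ALPS-AHI correlation is negative
  cc <- res$stats$correlations
  expect_lt(cc$rho[cc$group == "PD" & cc$variable == "ahi"], 0)
  expect_true(file.exists(file.path(out, "manifest.json")))
  expect_true(file.exists(file.path(out, "cohort.csv")))
})

test_that("identical configurations reproduce identical outputs", {
  cfg <- default_run_config(seed = 3)
  cfg$stages <- c("simulate", "fit", "roi", "compute", "stats")
  cfg$with_dwi <- TRUE
  cfg$n_dwi_subjects <- 1L
  out1 <- withr::local_tempdir(); out2 <- withr::local_tempdir()
  r1 <- run_pipeline(cfg, out_dir = out1)
  r2 <- run_pipeline(cfg, out_dir = out2)
  for (f in c("cohort.csv", "alps_computed.csv", "stats_correlations.csv")) {
    expect_identical(unname(tools::md5sum(file.path(out1, f))),
                     unname(tools::md5sum(file.path(out2, f))))
  }
  expect_identical(r1$manifest$input_checksums[[1]],
                   r2$manifest$input_checksums[[1]])
})
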