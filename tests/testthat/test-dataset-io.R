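test_that("manifests round-trip field-identically through write/load", {
  man <- tiny_dataset(10, seed = 3, seg_share = 0.5)
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_manifest(man, p2)
  man2 <- load_manifest(p2)
  attr(man2, "base_dir") <- attr(man, "base_dir")
  expect_equal(as.data.frame(man2), as.data.frame(man))
  expect_equal(attr(man2, "resolution_um_per_px"),
               attr(man, "resolution_um_per_px"))
})

test_that("schema and range violations are rejected", {
  p <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(sample_id = "a", image_path = "a.png", tissue = "human_skin",
                   staining = "CPD", s_nuclei = 1.3)
  utils::write.csv(df, p, row.names = FALSE)
  expect_error(load_manifest(p), "s_nuclei", class = "epiderm_validation_error")

  utils::write.csv(df[, setdiff(names(df), "s_nuclei")], p, row.names = FALSE)
  expect_error(load_manifest(p), "missing required column",
               class = "epiderm_schema_error")

  df2 <- data.frame(sample_id = c("a", "a"), image_path = "a.png",
                    tissue = "human_skin", staining = "CPD", s_nuclei = 0.5)
  utils::write.csv(df2, p, row.names = FALSE)
  expect_error(load_manifest(p), "duplicate", class = "epiderm_validation_error")
})

test_that("cohort-shaped manifest yields the expected stratum counts", {
  p <- withr::local_tempfile(fileext = ".csv")
  cohort_manifest(p)
  man <- load_manifest(p)
  expect_equal(nrow(man), 804)
  expect_equal(sum(man$has_segmentation), 202)
  rep <- validate_dataset(man)
  expect_equal(unname(rep$by_tissue),
               c(487L, 269L, 48L))
  expect_equal(unname(rep$by_staining), c(415L, 317L, 36L, 36L))
  expect_equal(rep$n_with_segmentation, 202L)
})

test_that("empty manifests validate to all-zero counts without error", {
  p <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(sample_id = character(), image_path = character(),
                   tissue = character(), staining = character(),
                   s_nuclei = numeric())
  utils::write.csv(df, p, row.names = FALSE)
  rep <- validate_dataset(load_manifest(p))
  expect_equal(rep$n, 0L)
  expect_true(all(rep$by_tissue == 0))
  expect_length(rep$unreadable, 0)
})

test_that("missing files are reported as unreadable, not fatal", {
  man <- tiny_dataset(4, seed = 5)
  df <- as.data.frame(man)
  file.remove(file.path(attr(man, "base_dir"), df$image_path[2]))
  rep <- validate_dataset(man)
  expect_equal(rep$unreadable, df$image_path[2])
  expect_equal(rep$n, 4L)
})

test_that("masks decode through the palette and bad masks are named", {
  d <- withr::local_tempdir()
  # RGB palette mask: black/green/red -> 0/1/2
  m <- matrix(c(0L, 1L, 2L, 1L), 2, 2)
  write_mask(m, file.path(d, "m.png"))
  img <- array(runif(2 * 2 * 3), c(2, 2, 3))
  png::writePNG(img, file.path(d, "i.png"))
  smp <- load_sample(list(image_path = "i.png", mask_path = "m.png"),
                     base_dir = d)
  expect_identical(smp$mask, m)

  # grayscale class-index mask works too
  png::writePNG(matrix(c(0, 1, 2, 2) / 255, 2, 2), file.path(d, "g.png"))
  smp <- load_sample(list(image_path = "i.png", mask_path = "g.png"),
                     base_dir = d)
  expect_equal(sort(unique(c(smp$mask))), c(0L, 1L, 2L))

  # unknown scalar value is named in the error
  png::writePNG(matrix(7 / 255, 2, 2), file.path(d, "bad.png"))
  expect_error(
    load_sample(list(image_path = "i.png", mask_path = "bad.png"), base_dir = d),
    "unknown mask value 7", class = "epiderm_mask_error")

  # shape mismatch
  png::writePNG(matrix(1 / 255, 4, 4), file.path(d, "big.png"))
  expect_error(
    load_sample(list(image_path = "i.png", mask_path = "big.png"), base_dir = d),
    "do not match", class = "epiderm_shape_error")
})

test_that("loaded masks never contain values outside the class set", {
  man <- tiny_dataset(5, seed = 11)
  for (i in seq_len(5)) {
    smp <- load_sample(man[i, , drop = FALSE])
    expect_true(all(smp$mask %in% 0:2))
    expect_equal(dim(smp$image)[1:2], dim(smp$mask))
  }
})
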