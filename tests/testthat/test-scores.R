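test_that("S_nuclei is the damaged fraction of counted nuclei", {
  expect_equal(s_nuclei_from_counts(nuclei_counts(3, 10)), 0.3)
  for (n in c(1, 7, 100)) {
    expect_equal(s_nuclei_from_counts(nuclei_counts(0, n)), 0)
    expect_equal(s_nuclei_from_counts(nuclei_counts(n, n)), 1)
  }
  expect_error(s_nuclei_from_counts(list(n_dmg = 0, n_all = 0)),
               class = "epiderm_undefined_score")
  expect_error(nuclei_counts(5, 3), "exceed")
})

test_that("S_area counts damaged pixels over all epidermis pixels", {
  mask <- matrix(c(rep(0L, 100), rep(1L, 150), rep(2L, 50)), 30, 10)
  out <- s_area_from_mask(mask)
  expect_equal(out$a_dmg, 50)
  expect_equal(out$a_epi, 200)
  expect_equal(out$s_area, 0.25)

  all_dmg <- matrix(c(0L, 2L, 2L, 2L), 2, 2)
  expect_equal(s_area_from_mask(all_dmg)$s_area, 1)

  expect_error(s_area_from_mask(matrix(0L, 4, 4)),
               class = "epiderm_undefined_score")
  expect_error(s_area_from_mask(matrix(c(0L, 5L), 2, 2)),
               "unknown mask value 5", class = "epiderm_mask_error")
})

test_that("S_area matches a brute-force per-pixel tally on random masks", {
  set.seed(401)
  for (i in 1:50) {
    mask <- random_mask(64, 64)
    # independent oracle: explicit loop over pixels
    a_dmg <- 0L; a_epi <- 0L
    for (v in as.vector(mask)) {
      if (v == 2L) { a_dmg <- a_dmg + 1L; a_epi <- a_epi + 1L }
      if (v == 1L) a_epi <- a_epi + 1L
    }
    out <- s_area_from_mask(mask)
    expect_identical(c(out$a_dmg, out$a_epi), c(a_dmg, a_epi))
    expect_equal(out$s_area, a_dmg / a_epi)
  }
})

test_that("S_area is invariant to flips, rotations and added background", {
  set.seed(402)
  mask <- random_mask(20, 12)
  ref <- s_area_from_mask(mask)$s_area
  expect_equal(s_area_from_mask(mask[20:1, ])$s_area, ref)
  expect_equal(s_area_from_mask(mask[, 12:1])$s_area, ref)
  expect_equal(s_area_from_mask(t(mask))$s_area, ref)
  padded <- rbind(matrix(0L, 5, 12), mask)
  expect_equal(s_area_from_mask(padded)$s_area, ref)
})

test_that("cross-score conversion is the identity on the available score", {
  expect_equal(cross_score(score_pair(s_area = 0.4), "nuclei"), 0.4)
  expect_equal(cross_score(score_pair(s_nuclei = 0.7), "area"), 0.7)
  both <- score_pair(s_nuclei = 0.7, s_area = 0.4)
  expect_equal(cross_score(both, "area"), 0.4)
  expect_equal(cross_score(both, "nuclei"), 0.7)
  expect_error(score_pair(), class = "epiderm_validation_error")
  expect_error(score_pair(s_nuclei = 1.2), class = "epiderm_validation_error")
})
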