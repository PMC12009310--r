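test_that("docking classification: tolerance rule, boundaries, tie-break and symmetry", {
  peak_at <- function(i, n = 9) replace(rep(0.1, n), i, 1)
  expect_equal(docking_classify(peak_at(5), peak_at(6)), "docked")
  expect_equal(docking_classify(peak_at(2), peak_at(5)), "undocked")
  expect_equal(docking_classify(peak_at(4), peak_at(6)), "docked")  # offset 2
  expect_equal(docking_classify(peak_at(3), peak_at(7)), "undocked") # offset 4
  # symmetric in the sign of the offset
  expect_equal(docking_classify(peak_at(6), peak_at(4)),
               docking_classify(peak_at(4), peak_at(6)))
  # tolerance 0 reduces to exact peak coincidence
  expect_equal(docking_classify(peak_at(5), peak_at(5), 0), "docked")
  expect_equal(docking_classify(peak_at(5), peak_at(6), 0), "undocked")
  # argmax ties resolve to the lowest slice
  tied <- c(0, 1, 1, 0, 0, 0, 0, 0, 0)
  expect_equal(docking_classify(tied, peak_at(2)), "docked")
  expect_equal(docking_classify(rep(0, 9), peak_at(5)), "unclassifiable")
  expect_error(docking_classify(c(-1, 2, 3), c(1, 2, 3)), "non-negative")
})

test_that("docking rate recovers simulator ground truth exactly", {
  expect_equal(docking_rate(list(
    list(intensity_a = c(0, 1, 0), intensity_b = c(0, 1, 0)),
    list(intensity_a = c(1, 0, 0, 0, 0, 0), intensity_b = c(1, 0, 0, 0, 0, 0)),
    list(intensity_a = c(0, 0, 1), intensity_b = c(0, 1, 0)),
    list(intensity_a = c(1, 0, 0, 0, 0, 0), intensity_b = c(0, 0, 0, 0, 1, 0))
  ))$percent_docked, 75.0)
  sim <- simulate_zprofiles(1000, docked_fraction = 0.5, n_slices = 9,
                            seed = 9)
  rate <- docking_rate(sim$pairs)
  expect_equal(rate$percent_docked, 50.0)
  expect_equal(rate$n, 1000L)
  # docked-without-axoneme rate from per-pair ciliation flags
  cil <- rep(c(TRUE, FALSE), 500)
  rate2 <- docking_rate(sim$pairs, ciliated = cil)
  manual <- 100 * mean(sim$label == "docked" & !cil)
  expect_equal(rate2$percent_docked_unciliated, manual)
  # all-unclassifiable input is an error carrying the count
  zz <- list(list(intensity_a = rep(0, 5), intensity_b = rep(1, 5)))
  expect_error(docking_rate(zz), "1 profile pairs")
  expect_error(docking_rate(list()), "empty")
})

test_that("RAB8A: per-ROI max over the stack, then mean across ROIs", {
  expect_equal(rab8a_ciliary_intensity(list(c(1, 5, 3)))$per_roi_max, 5)
  r <- rab8a_ciliary_intensity(list(c(1, 5, 3), c(2, 7, 1)))
  expect_equal(r$image_mean, 6)
  single <- rab8a_ciliary_intensity(list(3, 8))
  expect_equal(single$per_roi_max, c(3, 8))
})

test_that("SMO occupancy: ratio, zero-cilia flag, pooling additivity", {
  expect_equal(smo_occupancy(120, 40), 3.0)
  expect_equal(smo_occupancy(0, 40), 0.0)
  expect_warning(r <- smo_occupancy(10, 0), "undefined")
  expect_true(is.na(r))
  # splitting a field of view and pooling areas/counts leaves the ratio fixed
  a1 <- 70; n1 <- 20; a2 <- 50; n2 <- 20
  expect_equal(smo_occupancy(a1 + a2, n1 + n2),
               (a1 + a2) / (n1 + n2))
  expect_equal(smo_occupancy(a1 + a2, n1 + n2), smo_occupancy(120, 40))
})

test_that("Gabor score: zero on constant images, grating far above uniform", {
  expect_identical(gabor_fibre_score(simulate_fibre_image(64, "uniform")), 0)
  g <- gabor_fibre_score(simulate_fibre_image(64, "grating", wavelength = 8))
  expect_gt(g, 10 * gabor_fibre_score(simulate_fibre_image(64, "uniform")))
  expect_gt(g, 1)
})

test_that("Gabor score is stable under rotation to each bank angle", {
  scores <- vapply((0:7) * 22.5, function(a)
    gabor_fibre_score(simulate_fibre_image(64, "grating", wavelength = 8,
                                           angle = a)), 0)
  expect_lt(max(scores) / min(scores), 1.05)
})

test_that("Gabor response is offset-invariant before normalization and at most linear in contrast", {
  img <- simulate_fibre_image(64, "grating", wavelength = 8, contrast = 0.5)
  s <- gabor_fibre_score(img)
  # numerator is DC-free: shifting the image rescales the score exactly by
  # the regional-intensity ratio
  s_off <- gabor_fibre_score(img + 0.25)
  idx <- 8:57  # default interior mask at one kernel radius (7 px)
  expect_equal(s_off * mean((img + 0.25)[idx, idx]),
               s * mean(img[idx, idx]), tolerance = 1e-9)
  # contrast scaling at fixed mean: response scales (sub)linearly
  img2 <- simulate_fibre_image(64, "grating", wavelength = 8, contrast = 1)
  expect_lte(gabor_fibre_score(img2) / s, 2 * 1.001)
  expect_equal(gabor_fibre_score(img2) / s, 2, tolerance = 0.01)
})

test_that("Gabor input handling: masks, small images, file input", {
  img <- simulate_fibre_image(64, "grating", wavelength = 8)
  expect_error(gabor_fibre_score(matrix(0.5, 10, 10)), "kernel support")
  expect_error(gabor_fibre_score(img, mask = matrix(FALSE, 64, 64)),
               "empty mask")
  expect_error(gabor_params(wavelength = 1), "Nyquist")
  # whitespace-delimited matrix file round trip
  f <- tempfile(fileext = ".txt")
  write.table(img, f, row.names = FALSE, col.names = FALSE)
  expect_equal(gabor_fibre_score(f), gabor_fibre_score(img),
               tolerance = 1e-6)
})

test_that("tubule area is pi*a*b, axis-ordered, and strictly monotone", {
  expect_equal(tubule_area(1, 1), pi)
  expect_equal(tubule_area(4, 2), 8 * pi)
  expect_equal(tubule_area(2, 2) / tubule_area(1, 1), 4)  # doubling axes
  expect_error(tubule_area(2, 4), "longest axis")
  expect_error(tubule_area(1, 0), "positive")
  expect_lt(tubule_area(3, 2), tubule_area(3.5, 2))
  expect_lt(tubule_area(3, 2), tubule_area(3, 2.5))
  expect_equal(tubule_area(4, 2, axes_are_semi_axes = FALSE), 2 * pi)
})

test_that("cysts are stage >= 2 anomalies; per-organoid mean as reported", {
  g <- data.frame(organoid = 1:5, stage = c(0, 1, 2, 3, 1))
  res <- cyst_count(g)
  expect_equal(res$n_cysts, 2L)
  expect_equal(cyst_count(data.frame(organoid = 1:4,
                                     stage = 0))$n_cysts, 0L)
  # 13 organoids carrying 24 stage>=2 anomalies -> 1.846 cysts/organoid
  g13 <- data.frame(organoid = rep(1:13, length.out = 26),
                    stage = c(rep(2, 24), 0, 0))
  res13 <- cyst_count(g13)
  expect_equal(res13$n_organoids, 13L)
  expect_equal(round(res13$mean_per_organoid, 3), 1.846)
  expect_error(cyst_count(data.frame(organoid = 1, stage = 4)),
               "invalid stage")
})

test_that("luciferase normalisation: reference identity, ratio and scale invariance", {
  expect_equal(luciferase_normalize(100, 100, 1), 1.0)
  expect_equal(luciferase_normalize(200, 100, 1), 2.0)
  f <- c(120, 340, 90); r <- c(100, 200, 80)
  ref <- mean(f / r)
  # reference wells normalised to their own mean ratio centre at 1
  expect_equal(mean(luciferase_normalize(f, r, ref)), 1.0)
  # common scaling of firefly and the reference cancels
  expect_equal(luciferase_normalize(3 * f, r, 3 * ref),
               luciferase_normalize(f, r, ref))
  expect_error(luciferase_normalize(c(1, 2), c(1, 0), 1), "well\\(s\\) 2")
})

test_that("dose-response table: vehicle identity, fold-change, planted monotone ladder", {
  set.seed(51)
  mk <- function(dose, n, p) {
    cells <- rnbinom(n, mu = 2000, size = 200)
    data.frame(dose = dose, cell_count = cells,
               ciliated_count = rbinom(n, cells, p))
  }
  vehicle <- mk("vehicle", 40, 0.40)
  # a dose group drawn identically to vehicle: z ~ 0, fold-change ~ 1
  same <- mk("d0", 40, 0.40)
  tab0 <- dose_response_table(same, vehicle)
  expect_lt(abs(tab0$z_cilia), 0.6)
  expect_equal(tab0$fold_change, 1.0, tolerance = 0.02)
  # 40% -> 60% incidence is a 1.5 fold-change
  tab <- dose_response_table(mk("d1", 40, 0.60), vehicle)
  expect_equal(tab$fold_change, 1.5, tolerance = 0.02)
  expect_gt(tab$z_cilia, 2)
  # monotone planted ladder gives monotone fold-changes
  ladder <- rbind(mk("a_low", 30, 0.42), mk("b_mid", 30, 0.48),
                  mk("c_high", 30, 0.55))
  tabs <- dose_response_table(ladder, vehicle)
  tabs <- tabs[order(tabs$dose), ]
  expect_true(all(diff(tabs$fold_change) > 0))
})
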