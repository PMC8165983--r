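test_that("composition masses reproduce the printed sodium-adduct peaks", {
  # feruloylated, acetylated xylooligosaccharides reported at 919.3 / 1081.3
  expect_equal(composition_mass(glycan_composition(P = 5, Fa = 1, Ac = 1)),
               919.2692, tolerance = 1e-6)
  expect_equal(composition_mass(glycan_composition(P = 5, H = 1, Fa = 1, Ac = 1)),
               1081.322, tolerance = 1e-6)
  # degenerate empty composition: water + sodium
  expect_equal(composition_mass(glycan_composition()), 41.00, tolerance = 0.005)
  # per-acetylated xylobiose (X2Ac5) and its deacetylation product
  x2ac5 <- composition_mass(glycan_composition(P = 2, Ac = 5))
  x2ac4 <- composition_mass(glycan_composition(P = 2, Ac = 4))
  expect_equal(x2ac5, 515.14, tolerance = 0.005)
  expect_equal(x2ac5 - x2ac4, 42.0106, tolerance = 1e-6)
  expect_error(composition_mass(c(P = 1, Z = 2)), "unknown residue")
})

test_that("mass additivity holds over random composition pairs", {
  set.seed(5)
  na <- 22.9892; water <- 18.0106
  for (i in 1:200) {
    a <- glycan_composition(P = sample(0:6, 1), H = sample(0:3, 1),
                            Ac = sample(0:5, 1), Fa = sample(0:3, 1),
                            U = sample(0:2, 1))
    b <- glycan_composition(P = sample(0:6, 1), H = sample(0:3, 1),
                            Ac = sample(0:5, 1), Fa = sample(0:3, 1),
                            U = sample(0:2, 1))
    ab <- do.call(glycan_composition,
                  as.list(setNames(as.integer(a) + as.integer(b), names(a))))
    expect_equal(composition_mass(a) + composition_mass(b) - (water + na),
                 composition_mass(ab), tolerance = 1e-9)
  }
})

test_that("peak decomposition enumerates, ranks, and filters feasibly", {
  ann_off <- decompose_peak(919.3, tolerance = 0.3, feasibility = FALSE)
  keys <- comp_keys(ann_off$matches)
  expect_true("P5H0Ac1Fa1U0" %in% keys)
  expect_true("P1H0Ac1Fa4U0" %in% keys)
  ann_on <- decompose_peak(919.3, tolerance = 0.3, feasibility = TRUE)
  keys_on <- comp_keys(ann_on$matches)
  expect_true("P5H0Ac1Fa1U0" %in% keys_on)
  expect_false("P1H0Ac1Fa4U0" %in% keys_on)  # feruloyl exceeds pentose carriers
  # all matches within tolerance and ranked by |delta|
  expect_true(all(abs(ann_on$matches$delta) <= 0.3))
  expect_true(!is.unsorted(abs(ann_on$matches$delta)))
  # no composition reaches 100 Da
  expect_equal(nrow(decompose_peak(100, tolerance = 0.3)$matches), 0)
  # zero tolerance on an exact theoretical mass returns that composition
  m <- composition_mass(glycan_composition(P = 4, Ac = 2))
  exact <- decompose_peak(m, tolerance = 0)
  expect_equal(comp_keys(exact$matches), "P4H0Ac2Fa0U0")
})

test_that("enlarging the tolerance never removes a match", {
  set.seed(9)
  for (mz in runif(20, 300, 1800)) {
    small <- comp_keys(decompose_peak(mz, tolerance = 0.15)$matches)
    large <- comp_keys(decompose_peak(mz, tolerance = 0.45)$matches)
    expect_true(all(small %in% large))
  }
})

test_that("product prediction conserves mass exactly", {
  # X2Ac5 -> X2Ac4: sodium-adduct mass drops by one acetyl residue
  pr <- predict_products(glycan_composition(P = 2, Ac = 5), remove_ac = 1)
  expect_equal(pr$mass, 473.13, tolerance = 0.005)
  expect_equal(as.integer(pr$product), c(2L, 0L, 4L, 0L, 0L))
  # deferuloylation of the 1081.3 substrate
  pr2 <- predict_products(glycan_composition(P = 5, H = 1, Fa = 1, Ac = 1),
                          remove_fa = 1)
  expect_equal(pr2$mass, 1081.3220 - 176.0473, tolerance = 1e-4)
  # removing nothing is the identity
  pr0 <- predict_products(glycan_composition(P = 3, Ac = 2))
  expect_equal(pr0$mass, composition_mass(glycan_composition(P = 3, Ac = 2)))
  expect_error(predict_products(glycan_composition(P = 2, Ac = 1),
                                remove_ac = 2), "cannot remove")
  # conservation property over random compositions and removals
  set.seed(31)
  for (i in 1:100) {
    comp <- glycan_composition(P = sample(1:6, 1), H = sample(0:2, 1),
                               Ac = sample(0:5, 1), Fa = sample(0:3, 1))
    ka <- sample(0:comp[["Ac"]], 1); kf <- sample(0:comp[["Fa"]], 1)
    pr <- predict_products(comp, remove_ac = ka, remove_fa = kf)
    expect_equal(pr$mass,
                 composition_mass(comp) - ka * 42.0106 - kf * 176.0473,
                 tolerance = 1e-9)
  }
})

test_that("before/after comparison infers the released moieties", {
  # deferuloylation fixture: Fa released, Ac retained
  subs <- list(glycan_composition(P = 5, H = 1, Fa = 1, Ac = 1),
               glycan_composition(P = 5, Fa = 1, Ac = 1))
  sp <- generate_spectrum_pair(subs, remove_fa = "all", mz_jitter = 0.05,
                               seed = 4)
  cmp <- compare_spectra(sp$before, sp$after, tolerance = 0.3)
  expect_true(cmp$summary$feruloyl_released)
  expect_false(cmp$summary$acetyl_released)
  expect_false(cmp$summary$unchanged)
  # identical lists: no change
  same <- compare_spectra(c(515.14, 473.13), c(515.14, 473.13))
  expect_true(same$summary$unchanged)
  # deacetylation ladder: X2Ac5 converted to X2Ac4 and X2Ac3
  before <- composition_mass(glycan_composition(P = 2, Ac = 5))
  after <- c(composition_mass(glycan_composition(P = 2, Ac = 4)),
             composition_mass(glycan_composition(P = 2, Ac = 3)))
  ladder <- compare_spectra(before, after, tolerance = 0.3)
  expect_true(ladder$summary$acetyl_released)
  steps <- ladder$all_matches[ladder$all_matches$n_fa_removed == 0, ]
  expect_setequal(steps$n_ac_removed, c(1L, 2L))  # sequential deacetylation
})

test_that("peak lists round-trip through two-column text files", {
  d <- withr::local_tempdir()
  p <- file.path(d, "peaks.txt")
  peaks <- data.frame(mz = c(515.137, 473.127), intensity = c(0.8, 0.4))
  write_peaklist(peaks, p)
  back <- read_peaklist(p)
  expect_equal(back$mz, peaks$mz)
  expect_equal(back$intensity, peaks$intensity)
})
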