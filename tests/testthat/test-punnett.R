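test_that("selfing distributions match the closed-form monohybrid cases", {
  d <- self_distribution("fFFMm")
  cd <- class_distribution(d)
  expect_equal(unname(cd["Ef_Mp"]), 0.75)
  expect_equal(unname(cd["Ef_Mn"]), 0.25)
  expect_equal(self_distribution("aAAMM")$probs, c(aAAMM = 1))
})

test_that("hybrid selfing respects the enable flag and excludes aF-ova genotypes at v = 0", {
  off <- self_distribution("aAFMm")
  expect_true(is_empty_distribution(off))
  expect_equal(off$reason, "hybrid_selfing_disabled")

  on <- self_distribution("aAFMm", model_params(hybrid_selfing = TRUE))
  expect_false(is_empty_distribution(on))
  # with v = 0 no genotype with a maternal F allele (from an aF ovum) survives
  expect_true(all(substr(names(on$probs), 2, 2) == "A"))

  sterile <- self_distribution("fFAmM")
  expect_true(is_empty_distribution(sterile))
  expect_equal(sterile$reason, "sterile_mother")
})

test_that("single-role cross distributions reproduce the founder-pair squares", {
  d <- cross_distribution("aAAMM", "fFFmm",
                          model_params(selfing_rate = 0.5,
                                       ef_cross_success = 0))
  expect_equal(d$probs, c(aAAMM = 0.5, aAFMm = 0.5))

  d2 <- cross_distribution("fFFmm", "aAAMM",
                           model_params(selfing_rate = 0.5,
                                        ef_cross_success = 1))
  expect_equal(d2$probs, c(fFAmM = 0.5, fFFmm = 0.5))

  d3 <- cross_distribution("aAFMm", "aAAMM",
                           model_params(selfing_rate = 0))
  cd3 <- class_distribution(d3)
  expect_equal(sum(cd3[grepl("_Mp$", names(cd3))]), 1)
})

test_that("distributions agree with the brute-force enumeration oracle", {
  configs <- list(
    list(mother = "aAAMM", father = "fFFmm", sigma = 0.5, h = 0, v = 0),
    list(mother = "aAAMM", father = "fFFmm", sigma = 0.3, h = 0.2, v = 0),
    list(mother = "fFFmm", father = "aAAMM", sigma = 0.5, h = 1, v = 0),
    list(mother = "fFFmm", father = "aAFMm", sigma = 0.7, h = 0.1, v = 0),
    list(mother = "aAFMm", father = "aAAMM", sigma = 0.5, h = 0.1, v = 0),
    list(mother = "aAFMm", father = "fFFmm", sigma = 0.4, h = 0.3, v = 0.25),
    list(mother = "fFFMm", father = "fFFmm", sigma = 0.5, h = 0.1, v = 0),
    list(mother = "aAFmM", father = "aAAmm", sigma = 0.2, h = 0.5, v = 0.5)
  )
  for (cf in configs) {
    params <- model_params(selfing_rate = cf$sigma, ef_cross_success = cf$h,
                           aF_ovum_viability = cf$v)
    got <- cross_distribution(cf$mother, cf$father, params)
    want <- oracle_brood(cf$mother, cf$father, cf$sigma, cf$h, cf$v)
    expect_equal(got$probs, want, tolerance = 1e-12)
  }
  # pure selfing against the oracle, including the hybrid-selfing mode
  expect_equal(self_distribution("fFFMm")$probs,
               oracle_brood("fFFMm"), tolerance = 1e-12)
  expect_equal(
    self_distribution("aAFMm", model_params(hybrid_selfing = TRUE,
                                            aF_ovum_viability = 0.5))$probs,
    oracle_brood("aAFMm", v = 0.5, hybrid_selfing = TRUE), tolerance = 1e-12)
})

test_that("nonempty distributions are normalized to machine precision", {
  gts <- all_genotypes()
  set.seed(11)
  for (k in 1:40) {
    params <- model_params(selfing_rate = runif(1), ef_cross_success = runif(1),
                           aF_ovum_viability = runif(1),
                           hybrid_selfing = sample(c(TRUE, FALSE), 1))
    mo <- sample(gts, 1)
    fa <- sample(gts, 1)
    for (d in list(cross_distribution(mo, fa, params),
                   pair_distribution(mo, fa, params),
                   self_distribution(mo, params))) {
      if (!is_empty_distribution(d)) {
        expect_equal(sum(d$probs), 1, tolerance = 1e-12)
        expect_true(all(d$probs > 0))
      }
    }
  }
})

test_that("Ef-ova hybrid mass is zero at h = 0 and nondecreasing in h", {
  masses <- vapply(seq(0, 1, by = 0.1), function(h) {
    cd <- class_distribution(
      pair_distribution("aAAMM", "fFFmm",
                        model_params(ef_cross_success = h)))
    sum(cd[grepl("^hybrid_Ef", names(cd))])
  }, 0)
  expect_equal(masses[1], 0)
  expect_true(all(diff(masses) >= -1e-12))
})

test_that("the hybrid x Ef pair has exactly the six admissible offspring genotypes", {
  d <- pair_distribution("aAFMm", "fFFmm", model_params())
  expect_setequal(names(d$probs),
                  c("aAFMm", "aAFmm", "fFFmm", "fFFmM", "fFAmM", "fFAmm"))
})

test_that("class marginalization relabels and preserves mass", {
  d <- offspring_distribution(c(aAAMM = 0.5, aAFMm = 0.5), normalization = 1)
  expect_equal(class_distribution(d),
               c(Ea_Mp = 0.5, hybrid_Ea_derived_Mp = 0.5))
  expect_length(class_distribution(offspring_distribution(reason = "x")), 0)
  expect_true(is_empty_distribution(
    pair_distribution("aAFMm", "fFAmM", model_params())))
})
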