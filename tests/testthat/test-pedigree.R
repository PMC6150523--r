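test_that("founder-pair broods contain only the three admissible classes at h = 0", {
  off <- simulate_pair("aAAMM", "fFFmm", n = 1000,
                       params = model_params(ef_cross_success = 0), seed = 7)
  lab <- paste(genotype_class(record_genotype(off)), off$m_status, sep = "_")
  expect_setequal(unique(lab), c("Ea_Mp", "Ef_Mn", "hybrid_Ea_derived_Mp"))
})

test_that("hybrid pairs produce cocoons but no hatchlings", {
  off <- simulate_pair("aAFMm", "fFAmM", n = 100, seed = 3)
  expect_equal(nrow(off), 0L)
})

test_that("a selfing fFFMm culture segregates one quarter M-negative", {
  n <- 40000
  off <- simulate_pair("fFFMm", "fFFMm", n = n, seed = 19)
  p <- mean(off$m_status == "Mn")
  se <- sqrt(0.25 * 0.75 / n)
  expect_lt(abs(p - 0.25), 3 * se)
})

test_that("a seed is mandatory and identical seeds give byte-identical tables", {
  expect_error(simulate_pair("aAAMM", "fFFmm", n = 5), "seed")
  expect_error(simulate_design(study_mating_design(5, 5, 5)), "seed")
  t1 <- simulate_design(study_mating_design(20, 15, 15), seed = 101)
  t2 <- simulate_design(study_mating_design(20, 15, 15), seed = 101)
  expect_identical(t1, t2)
  f1 <- tempfile(fileext = ".tsv")
  f2 <- tempfile(fileext = ".tsv")
  write_specimens(t1, f1)
  write_specimens(t2, f2)
  expect_identical(readLines(f1), readLines(f2))
  t3 <- simulate_design(study_mating_design(20, 15, 15), seed = 102)
  expect_false(identical(t1, t3))
})

test_that("specimen tables round-trip through TSV", {
  tab <- simulate_design(study_mating_design(10, 8, 8), seed = 5)
  path <- tempfile(fileext = ".tsv")
  write_specimens(tab, path)
  back <- read_specimens(path)
  expect_equal(back$id, tab$id)
  expect_equal(back$coi, tab$coi)
  expect_equal(back$weight_g, tab$weight_g, tolerance = 1e-10)
})

test_that("COI is conserved through the maternal line", {
  tab <- simulate_design(study_mating_design(40, 30, 30),
                         params = model_params(ef_cross_success = 0.3),
                         seed = 23)
  kids <- tab[!is.na(tab$mother_id), ]
  mother_coi <- tab$coi[match(kids$mother_id, tab$id)]
  expect_equal(kids$coi, mother_coi)
})

test_that("the study design never yields M-negative pure Ea specimens", {
  # aAFmm hybrids are theoretically reachable (hybrid x Ef cross), but with
  # MM founders and hybrid selfing off, an aAAmm worm cannot arise
  tab <- simulate_design(study_mating_design(80, 60, 60), seed = 31)
  counts <- tabulate_classes(tab)
  expect_equal(unname(counts["Ea_Mn"]), 0L)
})

test_that("h = 0 forbids Ef-derived hybrids throughout the design", {
  tab <- simulate_design(study_mating_design(80, 60, 60),
                         params = model_params(ef_cross_success = 0),
                         seed = 13)
  counts <- tabulate_classes(tab)
  expect_equal(sum(counts[grepl("^hybrid_Ef", names(counts))]), 0L)
})

test_that("empty designs return founders only, sterile crosses zero rows", {
  tab <- simulate_design(list(founders = list(
    list(id = "x", genotype = "aAAMM")), crosses = list()), seed = 1)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$generation, 0L)

  des <- list(founders = list(list(id = "h1", genotype = "fFAmM"),
                              list(id = "h2", genotype = "aAFMm")),
              crosses = list(list(mother = "h1", father = "h2", n = 50)))
  tab2 <- simulate_design(des, seed = 1)
  expect_equal(nrow(tab2), 2L)  # founders only; the hybrid pair is sterile
})

test_that("symbiont transmission follows the cocoon rules", {
  params <- model_params(symbiont_vertical_p = 1, symbiont_sexual_p = 1)
  set.seed(1)
  expect_true(transmit_symbiont(TRUE, FALSE, params))
  expect_false(transmit_symbiont(FALSE, FALSE, params))
  expect_true(transmit_symbiont(FALSE, TRUE, params))
  # under the symbiont mechanism, a fully-vertical infected mother has no
  # M-negative offspring: the property that discriminates the mechanisms
  off <- simulate_pair("fFFMm", "fFFmm", n = 300,
                       params = model_params(mechanism = "symbiont",
                                             symbiont_vertical_p = 1,
                                             symbiont_sexual_p = 1),
                       seed = 9, mother_infected = TRUE,
                       father_infected = TRUE)
  expect_true(all(off$m_status == "Mp"))
  expect_true(all(off$infected))
})

test_that("design selectors resolve ids, fresh founders, and class patterns", {
  des <- study_mating_design(30, 10, 10)
  tab <- simulate_design(des, seed = 77)
  # crosses 2 and 3 must use generation-1 Ea-derived hybrid mothers
  f2 <- tab[tab$generation == 2L, ]
  mothers <- unique(f2$mother_id)
  mother_rows <- tab[match(mothers, tab$id), ]
  hyb_mothers <- mother_rows[genotype_class(record_genotype(mother_rows)) ==
                               "hybrid_Ea_derived", ]
  expect_gte(nrow(hyb_mothers), 2L)
  expect_true(all(hyb_mothers$generation == 1L))
  expect_error(
    simulate_design(list(founders = list(),
                         crosses = list(list(mother = "nope",
                                             father = "aAAMM", n = 1))),
                    seed = 1),
    "no specimen with id")
})

test_that("body weights are positive draws from the truncated normal", {
  set.seed(4)
  w <- draw_weights(5000, model_params())
  expect_true(all(w > 0))
  expect_lt(abs(mean(w) - 0.77), 3 * 0.18 / sqrt(5000))
  expect_lt(abs(sd(w) - 0.18), 0.02)
})
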