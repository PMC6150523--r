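test_that("marker-based classification matches the class mapping", {
  expect_equal(classify_specimen("f", "F", "A", "Mn"),
               list(class_label = "hybrid_Ef_derived", m_status = "Mn"))
  expect_equal(classify_specimen("f", "F", "F", "Mp"),
               list(class_label = "Ef", m_status = "Mp"))
  expect_equal(classify_specimen("a", "A", "A", "Mp"),
               list(class_label = "Ea", m_status = "Mp"))
  expect_error(classify_specimen("x", "A", "A", "Mp"), "COI haplotype")
  expect_error(classify_specimen("a", "A", "q", "Mp"), "paternal 28S")
})

test_that("marker classification of simulated specimens agrees with their genotypes", {
  tab <- simulate_design(study_mating_design(40, 30, 30),
                         params = model_params(ef_cross_success = 0.3),
                         seed = 15)
  gt <- record_genotype(tab)
  for (i in seq_len(nrow(tab))) {
    got <- classify_specimen(tab$coi[i], tab$nuc_mat[i], tab$nuc_pat[i],
                             tab$m_status[i])
    expect_equal(got$class_label, genotype_class(gt[i]))
    expect_equal(got$m_status, m_status_of(gt[i]))
  }
})

test_that("tabulation counts every class/status cell and the total", {
  counts <- tabulate_classes(load_study_fixture())
  expect_equal(attr(counts, "total"), 46L)
  empty <- tabulate_classes(load_study_fixture()[0, ])
  expect_true(all(empty == 0L))
  expect_equal(attr(empty, "total"), 0L)
})

test_that("M-genotype inference narrows offspring of an Mm x mm mating to Mm", {
  records <- data.frame(
    id = c("mo", "fa", "kid"),
    generation = c(0L, 0L, 1L),
    mother_id = c(NA, NA, "mo"),
    father_id = c(NA, NA, "fa"),
    coi = "f", nuc_mat = "F", nuc_pat = "F",
    m_status = c("Mp", "Mn", "Mp"),
    stringsAsFactors = FALSE)
  sets <- infer_m_genotypes(records)
  expect_equal(sets[["kid"]], "Mm")      # paternal allele must be m
  expect_setequal(sets[["mo"]], c("MM", "Mm", "mM"))
  expect_equal(sets[["fa"]], "mm")
  expect_equal(nrow(attr(sets, "inconsistencies")), 0L)
})

test_that("founder ambiguity is kept unless the Ea-MM assumption is switched on", {
  rec <- data.frame(id = "solo", generation = 0L,
                    mother_id = NA_character_, father_id = NA_character_,
                    coi = "a", nuc_mat = "A", nuc_pat = "A", m_status = "Mp",
                    stringsAsFactors = FALSE)
  expect_setequal(infer_m_genotypes(rec)[["solo"]], c("MM", "Mm", "mM"))
  expect_equal(infer_m_genotypes(rec, assume_ea_founders_MM = TRUE)[["solo"]],
               "MM")
})

test_that("impossible transmissions are flagged as inconsistencies", {
  records <- data.frame(
    id = c("mo", "kid"),
    generation = c(0L, 1L),
    mother_id = c(NA, "mo"),
    father_id = c(NA, "mo"),
    coi = "a", nuc_mat = "A", nuc_pat = "A",
    m_status = c("Mp", "Mn"),
    stringsAsFactors = FALSE)
  sets <- infer_m_genotypes(records, assume_ea_founders_MM = TRUE)
  expect_length(sets[["kid"]], 0L)
  expect_equal(attr(sets, "inconsistencies")$id, "kid")
})

test_that("inference never removes the true diplotype on simulated pedigrees", {
  tab <- simulate_design(study_mating_design(30, 20, 20),
                         params = model_params(ef_cross_success = 0.3),
                         seed = 44)
  truth <- paste0(tab$m_mat, tab$m_pat)
  sets <- infer_m_genotypes(tab)
  for (i in seq_len(nrow(tab))) {
    expect_true(truth[i] %in% sets[[tab$id[i]]])
  }
})

test_that("likelihood fitting hits the boundary when Ef hybrids are unobserved", {
  counts <- c(Ea_Mp = 30, hybrid_Ea_derived_Mp = 30, Ef_Mn = 40)
  fit <- estimate_params(counts, grid_n = 21)
  expect_equal(fit$h_hat, 0)
  expect_false(fit$flat)
})

test_that("a design with a single reachable class gives a flat flagged surface", {
  fit <- estimate_params(c(Ea_Mp = 12),
                         design = list(list(mother = "aAAMM",
                                            father = "aAAMM", n = 1)),
                         grid_n = 11)
  expect_true(fit$flat)
})

test_that("observed classes that the design cannot produce raise a structured report", {
  expect_error(
    estimate_params(c(Ea_Mp = 5, Ef_Mp = 3), grid_n = 11),
    class = "eis_impossible_class")
})

test_that("family log-likelihoods match the assignment-enumeration oracle", {
  params <- model_params()
  # selfing family
  d <- self_distribution("fFFMm", params)
  for (n_mn in 0:3) {
    fam <- list(mother = "fFFMm", father = NULL, n = 4, n_mn = n_mn)
    expect_equal(mechanism_loglik(fam, "mendelian", params),
                 oracle_family_loglik(d$probs, 4, n_mn), tolerance = 1e-10)
  }
  # pair family
  dp <- pair_distribution("fFFMm", "fFFmm", params)
  fam <- list(mother = "fFFMm", father = "fFFmm", n = 5, n_mn = 2)
  expect_equal(mechanism_loglik(fam, "mendelian", params),
               oracle_family_loglik(dp$probs, 5, 2), tolerance = 1e-10)
})

test_that("symbiont likelihood follows the infection rules", {
  fam <- list(mother = "fFFMm", father = NULL, n = 7, n_mn = 2,
              mother_infected = TRUE)
  expect_equal(mechanism_loglik(fam, "symbiont",
                                model_params(symbiont_vertical_p = 1)), -Inf)
  # vertical_p = 0.75 makes the symbiont binomial coincide with the
  # Mendelian 1/4 segregation
  expect_equal(mechanism_loglik(fam, "symbiont",
                                model_params(symbiont_vertical_p = 0.75)),
               mechanism_loglik(fam, "mendelian"))
  none <- list(mother = "fFFmm", father = NULL, n = 3, n_mn = 3,
               mother_infected = FALSE, father_infected = FALSE)
  expect_equal(mechanism_loglik(none, "symbiont"), 0)
})
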