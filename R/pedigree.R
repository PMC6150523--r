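# Forward simulation of mating designs. Specimen tables are plain data
# frames with a fixed column set so they round-trip through TSV byte-for-byte.

SPECIMEN_COLS <- c("id", "generation", "mother_id", "father_id", "coi",
                   "nuc_mat", "nuc_pat", "m_mat", "m_pat", "m_status",
                   "infected", "weight_g")

empty_specimens <- function() {
  data.frame(id = character(0), generation = integer(0),
             mother_id = character(0), father_id = character(0),
             coi = character(0), nuc_mat = character(0),
             nuc_pat = character(0), m_mat = character(0),
             m_pat = character(0), m_status = character(0),
             infected = logical(0), weight_g = numeric(0),
             stringsAsFactors = FALSE)
}

#' Genotype codes of specimen records
#'
#' Reassembles the five-character genotype code from the marker columns of a
#' specimen table. Records with unknown M-locus alleles give `NA`.
#'
#' @param records A specimen data frame (see [simulate_design()]).
#' @return Character vector of genotype codes (or `NA`).
#' @export
record_genotype <- function(records) {
  code <- paste0(records$coi, records$nuc_mat, records$nuc_pat,
                 records$m_mat, records$m_pat)
  code[is.na(records$m_mat) | is.na(records$m_pat)] <- NA_character_
  code
}

#' Draw adult body weights
#'
#' Normal weights truncated at zero by rejection, with the study-calibrated
#' default mean 0.77 g and SD 0.18 g.
#'
#' @param n Number of draws.
#' @param params An [model_params()] object (fields `weight_mean_g`,
#'   `weight_sd_g`).
#' @return Numeric vector of positive weights in grams. Uses the current RNG
#'   stream; seed via the calling simulation.
#' @export
draw_weights <- function(n, params = model_params()) {
  params <- as_model_params(params)
  w <- stats::rnorm(n, params$weight_mean_g, params$weight_sd_g)
  while (any(bad <- w <= 0)) {
    w[bad] <- stats::rnorm(sum(bad), params$weight_mean_g, params$weight_sd_g)
  }
  w
}

#' Symbiont transmission to one offspring
#'
#' The alternative, non-Mendelian mechanism: a nephridial symbiont is
#' vertically transmitted via the cocoon with probability
#' `symbiont_vertical_p` when the mother is infected. An uninfected mother
#' paired with an infected partner has her cocoon infected with probability
#' `symbiont_sexual_p` (sperm-borne transfer at copulation), after which the
#' vertical rule applies. Under this mechanism a specimen is M-positive iff
#' infected.
#'
#' @param mother_infected,father_infected Logical flags.
#' @param params An [model_params()] object.
#' @return Logical: is the offspring infected? Uses the current RNG stream.
#' @export
transmit_symbiont <- function(mother_infected, father_infected,
                              params = model_params()) {
  params <- as_model_params(params)
  stopifnot(is.logical(mother_infected), is.logical(father_infected),
            length(mother_infected) == 1L, length(father_infected) == 1L)
  cocoon <- isTRUE(mother_infected) ||
    (isTRUE(father_infected) &&
       stats::runif(1) < params$symbiont_sexual_p)
  cocoon && stats::runif(1) < params$symbiont_vertical_p
}

# core brood sampler; assumes the RNG is already seeded by the caller.
# mother/father are genotype codes; infected flags are cocoon inputs.
sim_brood <- function(mother_gt, father_gt, n, params,
                      mother_inf = NA, father_inf = NA,
                      generation = 1L, cross_index = 1L,
                      mother_id = NA_character_, father_id = NA_character_) {
  if (n == 0L) return(empty_specimens())
  roles <- list()
  rt1 <- role_terms(mother_gt, father_gt, params)
  if (!is.null(rt1)) {
    roles[[length(roles) + 1L]] <- c(rt1, list(mo = mother_id,
                                               fa = father_id,
                                               mo_inf = mother_inf,
                                               fa_inf = father_inf))
  }
  rt2 <- role_terms(father_gt, mother_gt, params)
  if (!is.null(rt2)) {
    roles[[length(roles) + 1L]] <- c(rt2, list(mo = father_id,
                                               fa = mother_id,
                                               mo_inf = father_inf,
                                               fa_inf = mother_inf))
  }
  if (!length(roles)) return(empty_specimens())

  # one cocoon-level sexual-transmission draw per mother role
  cocoon <- vapply(roles, function(r) {
    if (is.na(r$mo_inf)) return(NA)
    isTRUE(r$mo_inf) ||
      (isTRUE(r$fa_inf) && stats::runif(1) < params$symbiont_sexual_p)
  }, NA)

  role_idx <- if (length(roles) == 1L) rep(1L, n) else
    sample.int(length(roles), n, replace = TRUE)
  genotype <- character(n)
  infected <- rep(NA, n)
  mo_ids <- character(n)
  fa_ids <- character(n)
  for (k in seq_along(roles)) {
    sel <- role_idx == k
    nk <- sum(sel)
    if (!nk) next
    r <- roles[[k]]
    # sample at the (ovum, sperm source) term level so that selfed offspring
    # record the mother as both parents
    term <- sample.int(nrow(r$terms), nk, replace = TRUE, prob = r$w)
    genotype[sel] <- r$terms$genotype[term]
    mo_ids[sel] <- r$mo
    fa_ids[sel] <- ifelse(r$terms$source[term] == "self", r$mo, r$fa)
    if (!is.na(cocoon[k])) {
      infected[sel] <- cocoon[k] &
        stats::runif(nk) < params$symbiont_vertical_p
    }
  }
  m_status <- if (params$mechanism == "symbiont") {
    ifelse(is.na(infected), "unknown", ifelse(infected, "Mp", "Mn"))
  } else {
    m_status_of(genotype)
  }
  parts <- genotype_components(genotype)
  data.frame(id = sprintf("%d_%d_%d", generation, cross_index, seq_len(n)),
             generation = as.integer(generation),
             mother_id = mo_ids,
             father_id = fa_ids,
             coi = parts$mito, nuc_mat = parts$nuc_mat,
             nuc_pat = parts$nuc_pat, m_mat = parts$m_mat,
             m_pat = parts$m_pat, m_status = m_status,
             infected = infected, weight_g = draw_weights(n, params),
             stringsAsFactors = FALSE)
}

#' Simulate the brood of one pair
#'
#' Draws `n` independent offspring from the pair's exact offspring
#' distribution (both mother roles, see [pair_distribution()]), assigning
#' pedigree links, the M phenotype under the configured mechanism, symbiont
#' infection flags, and truncated-normal body weights. Infertile pairings
#' (two hybrids, or all roles sterile) return an empty table: plenty of
#' cocoons, no hatchlings.
#'
#' @param mother,father Genotype codes, or single-row specimen records with
#'   known M-locus alleles.
#' @param n Number of offspring.
#' @param params An [model_params()] object.
#' @param seed Integer seed; mandatory (reproducibility contract).
#' @param mother_infected,father_infected Symbiont infection of the parents;
#'   default for genotype-code parents is infection iff the a-mito lineage
#'   (the symbiont is *E. andrei*-specific in the model).
#' @return A specimen data frame with columns
#'   `r paste(SPECIMEN_COLS, collapse = ", ")`.
#' @examples
#' f1 <- simulate_pair("aAAMM", "fFFmm", n = 20, seed = 1)
#' table(f1$m_status)
#' @export
simulate_pair <- function(mother, father, n, params = model_params(),
                          seed, mother_infected = NULL,
                          father_infected = NULL) {
  if (missing(seed) || is.null(seed)) {
    stop("'seed' is required: simulations must be reproducible",
         call. = FALSE)
  }
  params <- as_model_params(params)
  stopifnot(is.numeric(n), length(n) == 1L, n >= 0)
  unpack <- function(x, default_id) {
    if (is.data.frame(x)) {
      stopifnot(nrow(x) == 1L)
      gt <- record_genotype(x)
      if (is.na(gt)) stop("parent record has unknown M-locus alleles",
                          call. = FALSE)
      list(gt = gt, id = x$id, inf = x$infected)
    } else {
      validate_genotype(x)
      list(gt = x, id = default_id, inf = substr(x, 1L, 1L) == "a")
    }
  }
  mo <- unpack(mother, "mother")
  fa <- unpack(father, "father")
  if (!is.null(mother_infected)) mo$inf <- mother_infected
  if (!is.null(father_infected)) fa$inf <- father_infected
  set.seed(as.integer(seed))
  sim_brood(mo$gt, fa$gt, as.integer(n), params,
            mother_inf = mo$inf, father_inf = fa$inf,
            generation = 1L, cross_index = 1L,
            mother_id = mo$id, father_id = fa$id)
}

#' Mating designs
#'
#' A mating design is a list with `founders` (each a list with `id`,
#' `genotype`, and optionally `infected`) and `crosses` (each a list with
#' `mother` and `father` selectors and an offspring count `n`). A selector is
#' either a list `list(id = ...)` naming an existing specimen, a list
#' `list(genotype = ...)` creating a fresh founder of that genotype, or a
#' list `list(class = ..., m_status = ..., generation = ..., index = ...)`
#' picking the `index`-th matching specimen in table order. Plain strings are
#' accepted: a valid genotype code means a fresh founder, anything else an
#' id.
#'
#' `study_mating_design()` builds the study's combined mating scheme: an
#' Ea x Ef founder pair producing F1, then the first two Ea-derived F1
#' hybrids test-crossed against a fresh Ea and a fresh Ef partner.
#'
#' @param n_f1 Offspring count of the founder cross.
#' @param n_f2_ea,n_f2_ef Offspring counts of the two hybrid test-crosses.
#' @return A design list suitable for [simulate_design()].
#' @export
study_mating_design <- function(n_f1 = 60, n_f2_ea = 49, n_f2_ef = 49) {
  list(
    founders = list(
      list(id = "Ea_P0", genotype = "aAAMM", infected = TRUE),
      list(id = "Ef_P0", genotype = "fFFmm", infected = FALSE)
    ),
    crosses = list(
      list(mother = list(id = "Ea_P0"), father = list(id = "Ef_P0"),
           n = n_f1),
      list(mother = list(class = "hybrid_Ea_derived", generation = 1,
                         index = 1),
           father = list(genotype = "aAAMM"), n = n_f2_ea),
      list(mother = list(class = "hybrid_Ea_derived", generation = 1,
                         index = 2),
           father = list(genotype = "fFFmm"), n = n_f2_ef)
    )
  )
}

normalize_selector <- function(sel) {
  if (is.character(sel) && length(sel) == 1L) {
    if (grepl(GENOTYPE_PATTERN, sel)) return(list(genotype = sel))
    return(list(id = sel))
  }
  if (!is.list(sel)) stop("selector must be a string or a list", call. = FALSE)
  sel
}

validate_design <- function(design) {
  if (!is.list(design)) stop("design must be a list", call. = FALSE)
  founders <- design$founders
  if (is.null(founders)) founders <- list()
  for (i in seq_along(founders)) {
    f <- founders[[i]]
    if (is.null(f$id) || is.null(f$genotype)) {
      stop(sprintf("founder %d needs 'id' and 'genotype'", i), call. = FALSE)
    }
    validate_genotype(f$genotype)
  }
  ids <- vapply(founders, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate founder ids", call. = FALSE)
  crosses <- design$crosses
  if (is.null(crosses)) crosses <- list()
  for (i in seq_along(crosses)) {
    cr <- crosses[[i]]
    if (is.null(cr$mother) || is.null(cr$father) || is.null(cr$n)) {
      stop(sprintf("cross %d needs 'mother', 'father' and 'n'", i),
           call. = FALSE)
    }
    if (!is.numeric(cr$n) || cr$n < 0) {
      stop(sprintf("cross %d: 'n' must be a nonnegative count", i),
           call. = FALSE)
    }
  }
  list(founders = founders, crosses = crosses)
}

founder_row <- function(id, genotype, infected, params) {
  parts <- genotype_components(genotype)
  data.frame(id = id, generation = 0L,
             mother_id = NA_character_, father_id = NA_character_,
             coi = parts$mito, nuc_mat = parts$nuc_mat,
             nuc_pat = parts$nuc_pat, m_mat = parts$m_mat,
             m_pat = parts$m_pat,
             m_status = m_status_of(genotype),
             infected = infected, weight_g = draw_weights(1L, params),
             stringsAsFactors = FALSE)
}

# run a validated design against an already-seeded RNG stream
run_design <- function(design, params) {
  specimens <- empty_specimens()
  n_founder <- 0L
  add_founder <- function(id, genotype, infected) {
    if (is.null(infected)) infected <- substr(genotype, 1L, 1L) == "a"
    specimens <<- rbind(specimens,
                        founder_row(id, genotype, infected, params))
  }
  for (f in design$founders) add_founder(f$id, f$genotype, f$infected)

  resolve <- function(sel, cross_idx, role) {
    sel <- normalize_selector(sel)
    if (!is.null(sel$id)) {
      hit <- which(specimens$id == sel$id)
      if (!length(hit)) {
        stop(sprintf("cross %d (%s): no specimen with id '%s'",
                     cross_idx, role, sel$id), call. = FALSE)
      }
      return(specimens[hit[1L], , drop = FALSE])
    }
    if (!is.null(sel$genotype)) {
      validate_genotype(sel$genotype)
      n_founder <<- n_founder + 1L
      id <- sprintf("founder_%d", n_founder)
      add_founder(id, sel$genotype, sel$infected)
      return(specimens[specimens$id == id, , drop = FALSE])
    }
    keep <- rep(TRUE, nrow(specimens))
    if (!is.null(sel$generation)) {
      keep <- keep & specimens$generation == sel$generation
    }
    if (!is.null(sel$class)) {
      gt <- record_genotype(specimens)
      cls <- rep(NA_character_, length(gt))
      cls[!is.na(gt)] <- genotype_class(gt[!is.na(gt)])
      keep <- keep & !is.na(cls) & cls == sel$class
    }
    if (!is.null(sel$m_status)) keep <- keep & specimens$m_status == sel$m_status
    idx <- if (is.null(sel$index)) 1L else as.integer(sel$index)
    hit <- which(keep)
    if (length(hit) < idx) {
      stop(sprintf("cross %d (%s): selector matched %d specimen(s), need %d",
                   cross_idx, role, length(hit), idx), call. = FALSE)
    }
    specimens[hit[idx], , drop = FALSE]
  }

  for (i in seq_along(design$crosses)) {
    cr <- design$crosses[[i]]
    cr_params <- if (is.null(cr$params)) params else
      as_model_params(utils::modifyList(unclass(params), cr$params))
    mo <- resolve(cr$mother, i, "mother")
    fa <- resolve(cr$father, i, "father")
    gen <- max(mo$generation, fa$generation) + 1L
    brood <- sim_brood(record_genotype(mo), record_genotype(fa),
                       as.integer(cr$n), cr_params,
                       mother_inf = mo$infected, father_inf = fa$infected,
                       generation = gen, cross_index = i,
                       mother_id = mo$id, father_id = fa$id)
    specimens <- rbind(specimens, brood)
  }
  rownames(specimens) <- NULL
  specimens
}

#' Simulate a multi-generation mating design
#'
#' Executes the crosses of a design in order, appending each brood to the
#' specimen table (founders are generation 0). A sterile pairing yields zero
#' offspring for that cross, not an error. Identical `design`, `params`, and
#' `seed` give a byte-identical table.
#'
#' @param design A design list, see [study_mating_design()].
#' @param params An [model_params()] object; per-cross `params` entries in
#'   the design override fields for that cross only.
#' @param seed Integer seed; mandatory.
#' @return A specimen data frame.
#' @examples
#' tab <- simulate_design(study_mating_design(10, 8, 8), seed = 42)
#' table(tab$generation)
#' @export
simulate_design <- function(design, params = model_params(), seed) {
  if (missing(seed) || is.null(seed)) {
    stop("'seed' is required: simulations must be reproducible",
         call. = FALSE)
  }
  params <- as_model_params(params)
  design <- validate_design(design)
  set.seed(as.integer(seed))
  run_design(design, params)
}

#' Read and write specimen tables
#'
#' Tab-separated text with the fixed header
#' `id, generation, mother_id, father_id, coi, nuc_mat, nuc_pat, m_mat,
#' m_pat, m_status, infected, weight_g`. Missing values are written as `NA`.
#'
#' @param path File path.
#' @param records A specimen data frame.
#' @return `read_specimens()`: a specimen data frame; `write_specimens()`:
#'   `path`, invisibly.
#' @export
read_specimens <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character",
                          stringsAsFactors = FALSE, na.strings = "NA")
  missing_cols <- setdiff(SPECIMEN_COLS, names(df))
  if (length(missing_cols)) {
    stop("specimen table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[SPECIMEN_COLS]
  df$generation <- as.integer(df$generation)
  df$infected <- as.logical(df$infected)
  df$weight_g <- as.numeric(df$weight_g)
  df
}

#' @rdname read_specimens
#' @export
write_specimens <- function(records, path) {
  stopifnot(all(SPECIMEN_COLS %in% names(records)))
  utils::write.table(records[SPECIMEN_COLS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}
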