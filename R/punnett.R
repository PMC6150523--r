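# Exact offspring distributions. Every distribution is built from a term
# table: one row per (ovum, sperm source, sperm) combination, carrying the
# base Mendelian probability and flags saying which model weights (selfing
# mixture, Ef-ova cross success h, aF-ovum viability v) multiply it. The
# same terms back cross_distribution() and the grid search in
# estimate_params(), so the exact and fitted paths cannot diverge.

#' Offspring genotype distribution
#'
#' Container for the exact probability map over viable offspring genotypes of
#' a mating configuration. `normalization` records the total weight before
#' renormalization (diagnostic: how much probability mass the viability and
#' asymmetry weights removed relative to the unweighted enumeration). An
#' empty distribution carries a `reason` code instead of probabilities.
#'
#' @param probs Named numeric vector of probabilities over genotype codes.
#' @param normalization Total pre-renormalization mass.
#' @param reason `NULL`, or a string explaining an empty support (e.g.
#'   `"sterile_mother"`, `"hybrid_pair"`).
#' @return An object of class `offspring_distribution`.
#' @export
offspring_distribution <- function(probs = numeric(0), normalization = 0,
                                   reason = NULL) {
  if (length(probs)) {
    stopifnot(!is.null(names(probs)), all(probs >= 0))
    probs <- probs[order(names(probs))]
  }
  structure(list(probs = probs, normalization = normalization,
                 reason = reason),
            class = "offspring_distribution")
}

#' @rdname offspring_distribution
#' @param d An `offspring_distribution`.
#' @export
is_empty_distribution <- function(d) {
  stopifnot(inherits(d, "offspring_distribution"))
  length(d$probs) == 0L
}

#' @export
print.offspring_distribution <- function(x, ...) {
  if (is_empty_distribution(x)) {
    cat("Empty offspring distribution (", x$reason, ")\n", sep = "")
    return(invisible(x))
  }
  cat("Offspring distribution over", length(x$probs), "genotypes",
      sprintf("(pre-normalization mass %.4g)\n", x$normalization))
  for (g in names(x$probs)) {
    cat(sprintf("  %s  %.6g\n", g, x$probs[[g]]))
  }
  invisible(x)
}

# Enumerate the raw terms of a brood: mother's ova crossed with the mother's
# own sperm ("self" source) and, when a father is given, the father's sperm
# ("cross" source). Flags, not params, so the table is parameter-free.
cross_terms <- function(mother, father = NULL) {
  ova <- make_gametes(mother, "ovum")
  one_source <- function(sperm, source) {
    grid <- expand.grid(ovum = names(ova), sperm = names(sperm),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid$base <- ova[grid$ovum] * sperm[grid$sperm]
    grid$source <- source
    grid
  }
  terms <- one_source(make_gametes(mother, "sperm"), "self")
  if (!is.null(father)) {
    terms <- rbind(terms, one_source(make_gametes(father, "sperm"), "cross"))
  }
  terms$genotype <- mapply(fertilize, terms$ovum, terms$sperm,
                           USE.NAMES = FALSE)
  terms$needs_v <- substr(terms$ovum, 1L, 1L) == "a" &
    substr(terms$ovum, 2L, 2L) == "F"
  terms$needs_h <- terms$source == "cross" &
    substr(terms$ovum, 1L, 1L) == "f" &
    substr(terms$sperm, 1L, 1L) == "A"
  terms
}

# term table + weights of one mother role, NULL when the role is sterile;
# shared by cross_distribution() and the forward simulator so that sampled
# broods and exact distributions cannot diverge
role_terms <- function(mother, father, params) {
  if (is_hybrid(mother) && is_hybrid(father)) return(NULL)
  if (is_ef_hybrid(mother)) return(NULL)
  terms <- cross_terms(mother, father)
  self_w <- if (is_hybrid(mother) && !params$hybrid_selfing) 0 else
    params$selfing_rate
  cross_w <- if (can_sire(father, params)) 1 - params$selfing_rate else 0
  w <- eval_terms(terms, self_w = self_w, cross_w = cross_w, params)
  if (sum(w) <= 0) return(NULL)
  list(terms = terms, w = w)
}

# weight vector for a term table under given mixture weights and params
eval_terms <- function(terms, self_w, cross_w, params) {
  w <- terms$base * ifelse(terms$source == "self", self_w, cross_w)
  w <- w * ifelse(terms$needs_h, params$ef_cross_success, 1)
  w * ifelse(terms$needs_v, params$aF_ovum_viability, 1)
}

build_distribution <- function(terms, w, empty_reason) {
  total <- sum(w)
  if (total <= 0) {
    return(offspring_distribution(reason = empty_reason))
  }
  agg <- tapply(w, terms$genotype, sum)
  probs <- as.numeric(agg) / total
  names(probs) <- names(agg)
  offspring_distribution(probs[probs > 0], normalization = total)
}

#' Offspring distribution under pure self-fertilization
#'
#' Enumerates all own-ovum x own-sperm combinations of a single hermaphrodite,
#' weights each ovum by its mito-nuclear viability, and renormalizes.
#' Ef-derived hybrids are sterile mothers; Ea-derived hybrids self only when
#' `params$hybrid_selfing` is enabled. In those cases an empty distribution
#' with a reason code is returned.
#'
#' @param g Genotype code of the selfing individual.
#' @param params An [model_params()] object.
#' @return An [offspring_distribution()].
#' @examples
#' self_distribution("fFFMm")  # 3:1 Mp:Mn, the classic monohybrid ratio
#' @export
self_distribution <- function(g, params = model_params()) {
  params <- as_model_params(params)
  validate_genotype(g)
  if (is_ef_hybrid(g)) {
    return(offspring_distribution(reason = "sterile_mother"))
  }
  if (is_hybrid(g) && !params$hybrid_selfing) {
    return(offspring_distribution(reason = "hybrid_selfing_disabled"))
  }
  terms <- cross_terms(g)
  w <- eval_terms(terms, self_w = 1, cross_w = 0, params)
  build_distribution(terms, w, "no_viable_offspring")
}

#' Offspring distribution of one mother role in a pair
#'
#' Each ovum of the mother is fertilized by the mother's own sperm with
#' probability `selfing_rate` and by the father's sperm with probability
#' `1 - selfing_rate`. Cross-fertilizations of f-mito ova by A-bearing sperm
#' carry the additional asymmetry weight `h`; aF ova carry the viability
#' weight `v`; the result is renormalized (weights shift brood composition,
#' not brood size). Hybrid mothers contribute no selfed offspring unless
#' `hybrid_selfing` is enabled, and a father that cannot sire (a sterile fFA
#' hybrid by default) contributes no cross offspring.
#'
#' `pair_distribution()` models a pair of hermaphrodites as the equal mixture
#' of the two mother roles, dropping a sterile role.
#'
#' @param mother,father Genotype codes; in `cross_distribution()` the mother
#'   is the ovum donor.
#' @param g1,g2 The two partners of a pair.
#' @param params An [model_params()] object.
#' @return An [offspring_distribution()].
#' @examples
#' cross_distribution("aAAMM", "fFFmm")  # selfed Ea plus aAFMm hybrids
#' pair_distribution("aAAMM", "fFFmm")
#' @export
cross_distribution <- function(mother, father, params = model_params()) {
  params <- as_model_params(params)
  validate_genotype(c(mother, father))
  if (is_hybrid(mother) && is_hybrid(father)) {
    return(offspring_distribution(reason = "hybrid_pair"))
  }
  if (is_ef_hybrid(mother)) {
    return(offspring_distribution(reason = "sterile_mother"))
  }
  terms <- cross_terms(mother, father)
  self_w <- if (is_hybrid(mother) && !params$hybrid_selfing) 0 else
    params$selfing_rate
  cross_w <- if (can_sire(father, params)) 1 - params$selfing_rate else 0
  w <- eval_terms(terms, self_w = self_w, cross_w = cross_w, params)
  build_distribution(terms, w, "no_viable_offspring")
}

#' @rdname cross_distribution
#' @export
pair_distribution <- function(g1, g2, params = model_params()) {
  params <- as_model_params(params)
  d1 <- cross_distribution(g1, g2, params)
  d2 <- cross_distribution(g2, g1, params)
  roles <- Filter(Negate(is_empty_distribution), list(d1, d2))
  if (!length(roles)) {
    return(offspring_distribution(reason = "pair_sterile"))
  }
  probs <- numeric(0)
  for (d in roles) {
    add <- d$probs / length(roles)
    for (g in names(add)) {
      probs[g] <- (if (g %in% names(probs)) probs[[g]] else 0) + add[[g]]
    }
  }
  offspring_distribution(probs,
                         normalization = mean(vapply(roles, `[[`, 0,
                                                     "normalization")))
}

#' Marginalize an offspring distribution to class x phenotype
#'
#' Pushes an offspring distribution forward through [phenotype()], giving the
#' probability of each reporting class x M-status combination. Keys are
#' `"<class>_<status>"` (e.g. `"hybrid_Ea_derived_Mp"`).
#'
#' @param d An [offspring_distribution()].
#' @return Named numeric vector over the nonzero class/status keys, sorted by
#'   key; an empty vector for an empty distribution.
#' @examples
#' class_distribution(self_distribution("fFFMm"))
#' @export
class_distribution <- function(d) {
  stopifnot(inherits(d, "offspring_distribution"))
  if (is_empty_distribution(d)) return(stats::setNames(numeric(0), NULL))
  keys <- paste(genotype_class(names(d$probs)), m_status_of(names(d$probs)),
                sep = "_")
  agg <- tapply(d$probs, keys, sum)
  out <- as.numeric(agg)
  names(out) <- names(agg)
  out[order(names(out))]
}
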