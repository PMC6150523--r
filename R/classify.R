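# Classification of observed/simulated specimens into the study's reporting
# classes, pedigree-constrained M-genotype inference, likelihood estimation
# of the mating parameters, and Mendelian-vs-symbiont model comparison.

#' Classify one specimen from its markers
#'
#' Maps the maternal COI haplotype and the ordered 28S diplotype to the
#' reporting class (see [genotype_class()]) and carries the M phenotype
#' through unchanged. Unknown allele symbols are rejected with the offending
#' position named.
#'
#' @param coi `"a"` or `"f"`.
#' @param nuc_mat,nuc_pat Maternal and paternal 28S alleles, `"A"` or `"F"`.
#' @param m_status `"Mp"`, `"Mn"`, or `"unknown"`.
#' @return A list with `class_label` and `m_status`.
#' @examples
#' classify_specimen("f", "F", "A", "Mn")  # the atypical Mn fFA hybrid
#' @export
classify_specimen <- function(coi, nuc_mat, nuc_pat, m_status = "unknown") {
  check_sym <- function(x, ok, what) {
    if (!is.character(x) || length(x) != 1L || !(x %in% ok)) {
      stop(sprintf("invalid %s symbol '%s' (expected one of: %s)",
                   what, as.character(x), paste(ok, collapse = ", ")),
           call. = FALSE)
    }
  }
  check_sym(coi, c("a", "f"), "COI haplotype")
  check_sym(nuc_mat, c("A", "F"), "maternal 28S allele")
  check_sym(nuc_pat, c("A", "F"), "paternal 28S allele")
  check_sym(m_status, c("Mp", "Mn", "unknown"), "M phenotype")
  pure <- nuc_mat == nuc_pat &&
    ((coi == "a" && nuc_mat == "A") || (coi == "f" && nuc_mat == "F"))
  cls <- if (pure) {
    if (coi == "a") "Ea" else "Ef"
  } else if (coi == "a") "hybrid_Ea_derived" else "hybrid_Ef_derived"
  list(class_label = cls, m_status = m_status)
}

# vectorized class labels for a specimen table
record_class <- function(records) {
  mapply(function(a, b, c) classify_specimen(a, b, c)$class_label,
         records$coi, records$nuc_mat, records$nuc_pat, USE.NAMES = FALSE)
}

#' Tabulate class x phenotype counts
#'
#' Exact counts of specimens per reporting class and M phenotype, over all
#' eight class/status combinations (zeros included). The total is attached as
#' an attribute.
#'
#' @param records A specimen data frame with columns `coi`, `nuc_mat`,
#'   `nuc_pat`, `m_status`; every `m_status` must be `Mp` or `Mn`.
#' @return Named integer vector keyed `"<class>_<status>"`, with attribute
#'   `total`.
#' @examples
#' tabulate_classes(load_study_fixture())
#' @export
tabulate_classes <- function(records) {
  keys <- class_status_keys()
  if (nrow(records) == 0L) {
    out <- stats::setNames(integer(length(keys)), keys)
    attr(out, "total") <- 0L
    return(out)
  }
  if (any(!records$m_status %in% STATUS_LEVELS)) {
    stop("every record needs an observed M phenotype (Mp or Mn)",
         call. = FALSE)
  }
  lab <- paste(record_class(records), records$m_status, sep = "_")
  out <- stats::setNames(integer(length(keys)), keys)
  tab <- table(lab)
  out[names(tab)] <- as.integer(tab)
  attr(out, "total") <- sum(out)
  out
}

# ---- M-genotype constraint propagation -------------------------------------

M_DIPLOTYPES <- c("MM", "Mm", "mM", "mm")

alleles_of_set <- function(dips) unique(unlist(strsplit(dips, "")))

#' Infer M-locus genotypes through a pedigree
#'
#' For each specimen, computes the set of ordered M-locus diplotypes
#' (maternal-first; `Mm` and `mM` are distinct) jointly consistent with its
#' phenotype, its parents' compatible sets, and Mendelian transmission, by
#' fixpoint constraint propagation (arc consistency): a diplotype survives
#' iff each of its alleles is transmissible by the corresponding parent's
#' surviving set, and a parent diplotype survives iff it can transmit the
#' required allele to every child. M-positive specimens start from
#' `{MM, Mm, mM}`, M-negative from `{mm}`, unknown from all four.
#'
#' Arc consistency never removes a truth: on simulated pedigrees each
#' specimen's true diplotype is always in its compatible set. A specimen
#' whose set empties is reported as an inconsistency (attribute
#' `inconsistencies`), not an error.
#'
#' @param records A specimen data frame with pedigree columns `mother_id`,
#'   `father_id` (selfing: both equal to the parent's id).
#' @param assume_ea_founders_MM Fix pedigree founders of class `Ea` with an
#'   Mp phenotype to `{MM}` (the founder assumption of the hybridization
#'   scheme). Default `FALSE`: founders keep their full phenotype-compatible
#'   set.
#' @return Named list (by specimen id) of character vectors of compatible
#'   ordered diplotypes; attribute `inconsistencies` is a data frame with
#'   columns `id` and `constraint`.
#' @export
infer_m_genotypes <- function(records, assume_ea_founders_MM = FALSE) {
  n <- nrow(records)
  ids <- records$id
  if (anyDuplicated(ids)) stop("duplicate specimen ids", call. = FALSE)
  sets <- vector("list", n)
  names(sets) <- ids
  for (i in seq_len(n)) {
    sets[[i]] <- switch(records$m_status[i],
                        Mp = c("MM", "Mm", "mM"),
                        Mn = "mm",
                        M_DIPLOTYPES)
  }
  is_founder <- is.na(records$mother_id) & is.na(records$father_id)
  if (assume_ea_founders_MM) {
    fix <- is_founder & record_class(records) == "Ea" &
      records$m_status == "Mp"
    for (i in which(fix)) sets[[i]] <- "MM"
  }
  idx_of <- stats::setNames(seq_len(n), ids)
  mo <- idx_of[records$mother_id]
  fa <- idx_of[records$father_id]

  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      # child pruning: each allele must be transmissible by its parent
      if (!is.na(mo[i])) {
        ok <- substr(sets[[i]], 1L, 1L) %in% alleles_of_set(sets[[mo[i]]])
        if (!all(ok)) { sets[[i]] <- sets[[i]][ok]; changed <- TRUE }
      }
      if (!is.na(fa[i])) {
        ok <- substr(sets[[i]], 2L, 2L) %in% alleles_of_set(sets[[fa[i]]])
        if (!all(ok)) { sets[[i]] <- sets[[i]][ok]; changed <- TRUE }
      }
    }
    for (i in seq_len(n)) {
      # parent pruning: a parent diplotype must serve every child
      prune_parent <- function(p, pos) {
        child_alleles <- substr(sets[[i]], pos, pos)
        ok <- vapply(sets[[p]], function(d) {
          length(child_alleles) == 0L ||
            any(child_alleles %in% strsplit(d, "")[[1]])
        }, NA)
        if (!all(ok)) { sets[[p]] <<- sets[[p]][ok]; changed <<- TRUE }
      }
      if (!is.na(mo[i])) prune_parent(mo[i], 1L)
      if (!is.na(fa[i])) prune_parent(fa[i], 2L)
    }
    if (!changed) break
  }
  empty <- vapply(sets, length, 0L) == 0L
  inconsistencies <- data.frame(
    id = ids[empty],
    constraint = rep("no M-locus diplotype consistent with phenotype and parents",
                     sum(empty)),
    stringsAsFactors = FALSE)
  attr(sets, "inconsistencies") <- inconsistencies
  sets
}

# ---- (sigma, h) estimation --------------------------------------------------

# Precompute, for each mother role of each cross in a design, the term table
# reduced to class keys, so class probabilities at any (sigma, h) are a few
# vector ops. `design` is a list of crosses: list(mother=, father=, n=).
design_class_terms <- function(design, params) {
  roles <- list()
  total_n <- sum(vapply(design, function(cr) cr$n, 0))
  for (cr in design) {
    for (role in list(c(cr$mother, cr$father), c(cr$father, cr$mother))) {
      mother <- role[[1]]; father <- role[[2]]
      if (is_hybrid(mother) && is_hybrid(father)) next
      if (is_ef_hybrid(mother)) next
      terms <- cross_terms(mother, father)
      terms$class_key <- paste(genotype_class(terms$genotype),
                               m_status_of(terms$genotype), sep = "_")
      drop_self <- is_hybrid(mother) && !params$hybrid_selfing
      drop_cross <- !can_sire(father, params)
      roles[[length(roles) + 1L]] <-
        list(terms = terms, drop_self = drop_self, drop_cross = drop_cross,
             weight = cr$n / total_n / 2)  # two roles per cross
    }
  }
  roles
}

eval_design_class_probs <- function(roles, sigma, h, params) {
  keys <- class_status_keys()
  p <- stats::setNames(numeric(length(keys)), keys)
  used_weight <- 0
  for (r in roles) {
    t <- r$terms
    w <- t$base *
      ifelse(t$source == "self", if (r$drop_self) 0 else sigma,
             if (r$drop_cross) 0 else 1 - sigma) *
      ifelse(t$needs_h, h, 1) *
      ifelse(t$needs_v, params$aF_ovum_viability, 1)
    tot <- sum(w)
    if (tot <= 0) next
    agg <- tapply(w, t$class_key, sum) / tot
    p[names(agg)] <- p[names(agg)] + r$weight * as.numeric(agg)
    used_weight <- used_weight + r$weight
  }
  if (used_weight > 0) p <- p / used_weight
  p
}

#' Estimate selfing and hybridization rates from class counts
#'
#' Grid search of the multinomial log-likelihood of observed class x
#' phenotype counts under the exact class probabilities of a mating design,
#' over (sigma, h) in \[0, 1\]^2. The full likelihood surface is returned:
#' the surface can be flat or boundary-maximized and the grid is honest about
#' that. Ties break toward the smallest sigma, then smallest h.
#'
#' @param counts Named counts keyed `"<class>_<status>"` (as from
#'   [tabulate_classes()]); absent keys count 0.
#' @param design A list of crosses, each `list(mother = <genotype>,
#'   father = <genotype>, n = <weight>)`; class probabilities are the
#'   `n`-weighted mixture of the pairs' distributions. Defaults to the single
#'   founder pair Ea x Ef.
#' @param params An [model_params()] object; `aF_ovum_viability` and the
#'   fertility switches are held fixed at their configured values.
#' @param grid_n Number of grid points per axis (default 101, step 0.01).
#' @return A list of class `param_fit`: `sigma_hat`, `h_hat`, `loglik`
#'   (matrix, sigma in rows), `sigma_grid`, `h_grid`, `max_loglik`, `flat`.
#' @examples
#' counts <- c(Ea_Mp = 25, hybrid_Ea_derived_Mp = 25, Ef_Mn = 45,
#'             hybrid_Ef_derived_Mp = 5)
#' fit <- estimate_params(counts, grid_n = 21)
#' c(fit$sigma_hat, fit$h_hat)
#' @export
estimate_params <- function(counts,
                            design = list(list(mother = "aAAMM",
                                               father = "fFFmm", n = 1)),
                            params = model_params(), grid_n = 101) {
  params <- as_model_params(params)
  keys <- class_status_keys()
  x <- stats::setNames(numeric(length(keys)), keys)
  if (is.null(names(counts)) || any(!names(counts) %in% keys)) {
    stop("counts must be named with '<class>_<status>' keys", call. = FALSE)
  }
  x[names(counts)] <- as.numeric(counts)
  stopifnot(all(x >= 0), sum(x) > 0)
  roles <- design_class_terms(design, params)
  sigma_grid <- seq(0, 1, length.out = grid_n)
  h_grid <- seq(0, 1, length.out = grid_n)
  const <- lgamma(sum(x) + 1) - sum(lgamma(x + 1))
  ll <- matrix(-Inf, grid_n, grid_n, dimnames = list(NULL, NULL))
  obs <- x > 0
  possible <- rep(FALSE, length(keys))
  for (i in seq_len(grid_n)) {
    for (j in seq_len(grid_n)) {
      p <- eval_design_class_probs(roles, sigma_grid[i], h_grid[j], params)
      possible <- possible | p > 0
      ll[i, j] <- if (any(obs & p == 0)) -Inf else
        const + sum(x[obs] * log(p[obs]))
    }
  }
  impossible <- keys[obs & !possible]
  if (length(impossible)) {
    stop(structure(class = c("eis_impossible_class", "error", "condition"),
                   list(message = paste0(
                          "observed class(es) with zero probability over the whole grid: ",
                          paste(impossible, collapse = ", ")),
                        call = NULL, classes = impossible)))
  }
  best <- which(ll == max(ll), arr.ind = TRUE)
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
  finite <- ll[is.finite(ll)]
  structure(list(sigma_hat = sigma_grid[best[1]], h_hat = h_grid[best[2]],
                 loglik = ll, sigma_grid = sigma_grid, h_grid = h_grid,
                 max_loglik = max(ll),
                 flat = diff(range(finite)) < 1e-8),
            class = "param_fit")
}

#' @export
print.param_fit <- function(x, ...) {
  cat(sprintf("Grid MLE: sigma = %g, h = %g (loglik %.4f%s)\n",
              x$sigma_hat, x$h_hat, x$max_loglik,
              if (x$flat) "; surface is flat" else ""))
  invisible(x)
}

# ---- mechanism comparison ---------------------------------------------------

#' Family log-likelihood under the Mendelian or symbiont mechanism
#'
#' Binomial likelihood of the observed number of M-negative offspring in one
#' family. Under the Mendelian mechanism the Mn probability is the Mn mass of
#' the parent(s)' offspring distribution ([self_distribution()] for a selfing
#' mother, [pair_distribution()] for a pair). Under the symbiont mechanism an
#' infected mother transmits with probability `symbiont_vertical_p`, so
#' P(Mn) = 1 - vertical_p per offspring; an uninfected mother with an
#' infected partner is a cocoon-level mixture (infected with probability
#' `symbiont_sexual_p`); with neither parent infected every offspring is Mn.
#' Zero-probability observations return `-Inf`.
#'
#' @param family A list with `mother` (genotype code), optional `father`
#'   (genotype code or `NULL` for selfing), `n` (offspring count), `n_mn`
#'   (observed M-negative count), and logical `mother_infected`,
#'   `father_infected` (defaults `TRUE`, `FALSE`).
#' @param mechanism `"mendelian"` or `"symbiont"`.
#' @param params An [model_params()] object.
#' @return The log-likelihood (may be `-Inf`).
#' @examples
#' fam <- list(mother = "fFFMm", father = NULL, n = 7, n_mn = 2)
#' mechanism_loglik(fam, "mendelian")   # log choose(7,2) 0.25^2 0.75^5
#' mechanism_loglik(fam, "symbiont")    # -Inf under pure vertical transmission
#' @export
mechanism_loglik <- function(family, mechanism = c("mendelian", "symbiont"),
                             params = model_params()) {
  mechanism <- match.arg(mechanism)
  params <- as_model_params(params)
  n <- family$n
  n_mn <- family$n_mn
  stopifnot(is.numeric(n), n >= 0, is.numeric(n_mn), n_mn >= 0, n_mn <= n)
  if (mechanism == "mendelian") {
    d <- if (is.null(family$father)) {
      self_distribution(family$mother, params)
    } else {
      pair_distribution(family$mother, family$father, params)
    }
    if (is_empty_distribution(d)) return(if (n > 0) -Inf else 0)
    cd <- class_distribution(d)
    p_mn <- sum(cd[grepl("_Mn$", names(cd))])
    return(stats::dbinom(n_mn, n, p_mn, log = TRUE))
  }
  mo_inf <- if (is.null(family$mother_infected)) TRUE else
    isTRUE(family$mother_infected)
  fa_inf <- isTRUE(family$father_infected)
  vp <- params$symbiont_vertical_p
  sp <- params$symbiont_sexual_p
  if (mo_inf) {
    stats::dbinom(n_mn, n, 1 - vp, log = TRUE)
  } else if (fa_inf) {
    # cocoon either infected (prob sp) or not; uninfected cocoon -> all Mn
    log(sp * stats::dbinom(n_mn, n, 1 - vp) + (1 - sp) * as.numeric(n_mn == n))
  } else {
    if (n_mn == n) 0 else -Inf
  }
}

#' Compare the Mendelian and symbiont hypotheses on one family
#'
#' @inheritParams mechanism_loglik
#' @return A list with both log-likelihoods, their difference
#'   (`loglik_ratio`, Mendelian minus symbiont), and the `favored` mechanism
#'   (`"tie"` on exact equality).
#' @examples
#' compare_mechanisms(list(mother = "fFFMm", father = NULL, n = 7, n_mn = 2))
#' @export
compare_mechanisms <- function(family, params = model_params()) {
  m <- mechanism_loglik(family, "mendelian", params)
  s <- mechanism_loglik(family, "symbiont", params)
  lr <- m - s
  favored <- if (is.nan(lr) || lr == 0) "tie" else
    if (lr > 0) "mendelian" else "symbiont"
  list(mendelian = m, symbiont = s, loglik_ratio = lr, favored = favored)
}
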