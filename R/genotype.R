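# Genotype string grammar: [af][AF][AF][Mm][Mm], maternal-first within each
# locus pair. Position 1: mitochondrial COI haplotype (a = E. andrei lineage,
# f = E. fetida); positions 2-3: nuclear 28S diplotype (maternal, paternal);
# positions 4-5: M-locus diplotype (maternal, paternal).

GENOTYPE_PATTERN <- "^[af][AF][AF][Mm][Mm]$"
OVUM_PATTERN <- "^[af][AF][Mm]$"
SPERM_PATTERN <- "^[AF][Mm]$"

#' Validate cytonuclear genotype codes
#'
#' A genotype code is a five-character string `[af][AF][AF][Mm][Mm]`: the
#' maternal mitochondrial haplotype, the ordered (maternal, paternal) 28S
#' diplotype, and the ordered (maternal, paternal) M-locus diplotype, e.g.
#' `"aAFMm"`. Codes are case-sensitive; anything else is rejected.
#'
#' @param code Character vector of genotype codes.
#' @return `code`, invisibly, if every element is valid; otherwise an error.
#' @examples
#' validate_genotype(c("aAAMM", "fFAmM"))
#' @export
validate_genotype <- function(code) {
  if (!is.character(code) || length(code) == 0L) {
    stop("genotype codes must be a non-empty character vector", call. = FALSE)
  }
  bad <- is.na(code) | !grepl(GENOTYPE_PATTERN, code)
  if (any(bad)) {
    stop("invalid genotype code(s): ",
         paste(unique(code[bad]), collapse = ", "),
         " (expected [af][AF][AF][Mm][Mm], maternal-first)", call. = FALSE)
  }
  invisible(code)
}

#' Split genotype codes into components
#'
#' @param code Character vector of genotype codes.
#' @return A data frame with columns `mito`, `nuc_mat`, `nuc_pat`, `m_mat`,
#'   `m_pat`.
#' @examples
#' genotype_components("aAFMm")
#' @export
genotype_components <- function(code) {
  validate_genotype(code)
  data.frame(mito = substr(code, 1L, 1L),
             nuc_mat = substr(code, 2L, 2L),
             nuc_pat = substr(code, 3L, 3L),
             m_mat = substr(code, 4L, 4L),
             m_pat = substr(code, 5L, 5L),
             stringsAsFactors = FALSE)
}

#' Genotype class and M phenotype
#'
#' `genotype_class()` maps a genotype to the reporting class: `Ea` (a-mito,
#' AA), `Ef` (f-mito, FF), else `hybrid_Ea_derived` (a-mito) or
#' `hybrid_Ef_derived` (f-mito). `m_status_of()` applies the dominance rule:
#' `Mp` iff the M-locus diplotype carries at least one `M`. `phenotype()`
#' returns both for a single genotype.
#'
#' @param code Character vector of genotype codes (`phenotype()` takes one).
#' @return `genotype_class()` / `m_status_of()`: character vectors;
#'   `phenotype()`: a list with `m_status` and `class_label`.
#' @examples
#' genotype_class(c("aAAMM", "fFAmM"))
#' phenotype("fFFMm")
#' @export
genotype_class <- function(code) {
  parts <- genotype_components(code)
  pure <- parts$nuc_mat == parts$nuc_pat &
    ((parts$mito == "a" & parts$nuc_mat == "A") |
     (parts$mito == "f" & parts$nuc_mat == "F"))
  ifelse(pure,
         ifelse(parts$mito == "a", "Ea", "Ef"),
         ifelse(parts$mito == "a", "hybrid_Ea_derived", "hybrid_Ef_derived"))
}

#' @rdname genotype_class
#' @export
m_status_of <- function(code) {
  parts <- genotype_components(code)
  ifelse(parts$m_mat == "M" | parts$m_pat == "M", "Mp", "Mn")
}

#' @rdname genotype_class
#' @export
phenotype <- function(code) {
  stopifnot(length(code) == 1L)
  list(m_status = m_status_of(code), class_label = genotype_class(code))
}

#' Is a genotype an interspecific hybrid?
#'
#' A hybrid carries a 28S diplotype discordant with a pure species (any
#' genotype whose class is one of the two hybrid classes). `is_ef_hybrid()`
#' selects the Ef-derived (fFA-type) hybrids, which are sterile as mothers.
#'
#' @param code Character vector of genotype codes.
#' @return Logical vector.
#' @examples
#' is_hybrid(c("aAAMM", "aAFMm", "fFAmM"))
#' @export
is_hybrid <- function(code) {
  grepl("^hybrid", genotype_class(code))
}

#' @rdname is_hybrid
#' @export
is_ef_hybrid <- function(code) {
  genotype_class(code) == "hybrid_Ef_derived"
}

#' Gamete distribution of a genotype
#'
#' Enumerates the exact gamete distribution of a parent. Each nuclear locus
#' contributes its maternal or paternal allele with probability 1/2,
#' independently across the two loci; ova additionally carry the parent's
#' mitochondrial haplotype (sperm never do). Identical gametes are merged, so
#' the support size is 1, 2, or 4.
#'
#' Ovum codes are `[af][AF][Mm]` (e.g. `"aAM"`); sperm codes `[AF][Mm]`
#' (e.g. `"Fm"`).
#'
#' @param g A single genotype code.
#' @param kind `"ovum"` or `"sperm"`.
#' @return Named numeric vector of probabilities over gamete codes, sorted by
#'   code, summing to 1.
#' @examples
#' make_gametes("aAFMm", "ovum")   # four oocyte types, 1/4 each
#' make_gametes("fFFmm", "sperm")  # only Fm
#' @export
make_gametes <- function(g, kind = c("ovum", "sperm")) {
  kind <- match.arg(kind)
  stopifnot(length(g) == 1L)
  validate_genotype(g)
  nuc <- c(substr(g, 2L, 2L), substr(g, 3L, 3L))
  m <- c(substr(g, 4L, 4L), substr(g, 5L, 5L))
  combos <- expand.grid(nuc = nuc, m = m,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  codes <- if (kind == "ovum") {
    paste0(substr(g, 1L, 1L), combos$nuc, combos$m)
  } else {
    paste0(combos$nuc, combos$m)
  }
  agg <- tapply(rep(0.25, nrow(combos)), codes, sum)
  out <- as.numeric(agg)
  names(out) <- names(agg)
  out[order(names(out))]
}

#' Fuse an ovum and a sperm into a zygote genotype
#'
#' The zygote inherits the ovum's mitochondrial haplotype, and each nuclear
#' locus pair is written maternal-first: (ovum allele, sperm allele).
#'
#' @param ovum Ovum code `[af][AF][Mm]`.
#' @param sperm Sperm code `[AF][Mm]`.
#' @return A genotype code.
#' @examples
#' fertilize("aAM", "Fm")  # aAFMm, the Ea-derived hybrid
#' @export
fertilize <- function(ovum, sperm) {
  stopifnot(length(ovum) == 1L, length(sperm) == 1L)
  if (!is.character(ovum) || !grepl(OVUM_PATTERN, ovum)) {
    stop("'ovum' must be an ovum code [af][AF][Mm], got: ", ovum,
         call. = FALSE)
  }
  if (!is.character(sperm) || !grepl(SPERM_PATTERN, sperm)) {
    stop("'sperm' must be a sperm code [AF][Mm], got: ", sperm, call. = FALSE)
  }
  paste0(substr(ovum, 1L, 1L),
         substr(ovum, 2L, 2L), substr(sperm, 1L, 1L),
         substr(ovum, 3L, 3L), substr(sperm, 2L, 2L))
}

#' Viability weight of an ovum under mito-nuclear incompatibility
#'
#' Ova that combine the `a` mitochondrial haplotype with the foreign nuclear
#' `F` allele are weighted by `params$aF_ovum_viability` (default 0, a hard
#' exclusion); all other ova have weight 1.
#'
#' @param ovum Ovum code `[af][AF][Mm]`.
#' @param params An [model_params()] object.
#' @return A weight in \[0, 1\].
#' @examples
#' ovum_viability("aFM", model_params())                         # 0
#' ovum_viability("aFm", model_params(aF_ovum_viability = 0.5))  # 0.5
#' @export
ovum_viability <- function(ovum, params = model_params()) {
  stopifnot(length(ovum) == 1L)
  if (!grepl(OVUM_PATTERN, ovum)) {
    stop("'ovum' must be an ovum code [af][AF][Mm], got: ", ovum,
         call. = FALSE)
  }
  params <- as_model_params(params)
  if (substr(ovum, 1L, 1L) == "a" && substr(ovum, 2L, 2L) == "F") {
    params$aF_ovum_viability
  } else {
    1
  }
}

#' Can a mother/father pairing produce offspring?
#'
#' Pairing-level fertility: hybrid x hybrid pairings are infertile (they
#' produce cocoons but no hatchlings), and Ef-derived (fFA-type) hybrids are
#' sterile as mothers — their ova yield nothing. All other pairings are
#' fertile. Whether an fFA individual can still sire offspring is controlled
#' separately by `params$fFA_paternal_fertile` and affects the offspring
#' distribution, not this pairing-level flag.
#'
#' @param mother,father Genotype codes of the two partners, mother first.
#' @param params An [model_params()] object.
#' @return `TRUE` or `FALSE`.
#' @examples
#' is_fertile_pairing("aAFMm", "fFAmM")  # FALSE: two hybrids
#' is_fertile_pairing("aAFMm", "aAAMM")  # TRUE
#' @export
is_fertile_pairing <- function(mother, father, params = model_params()) {
  validate_genotype(c(mother, father))
  if (is_hybrid(mother) && is_hybrid(father)) return(FALSE)
  if (is_ef_hybrid(mother)) return(FALSE)
  TRUE
}

# can this genotype contribute sperm to a brood?
can_sire <- function(g, params) {
  !is_ef_hybrid(g) || params$fFA_paternal_fertile
}

# can this genotype self-fertilize (pure selfing, no partner)?
can_self <- function(g, params) {
  if (is_ef_hybrid(g)) return(FALSE)
  if (is_hybrid(g)) return(params$hybrid_selfing)
  TRUE
}
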