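#' Model parameters for the cytonuclear inheritance model
#'
#' Bundles every tunable probability of the inheritance model. All
#' probabilities must lie in \[0, 1\].
#'
#' @param selfing_rate Per-ovum probability that an ovum is fertilized by the
#'   mother's own sperm rather than the partner's (mixed-mating weight sigma).
#' @param ef_cross_success Relative success `h` of cross-fertilization of an
#'   f-mito ovum by A-bearing partner sperm. `h = 0` forbids Ef-ova hybrids
#'   (fFA), reproducing fully asymmetrical hybridization; `h = 1` removes the
#'   asymmetry. a-mito ova cross with weight 1.
#' @param aF_ovum_viability Viability weight `v` of ova combining the `a`
#'   mitochondrial haplotype with the foreign nuclear `F` allele
#'   (mito-nuclear incompatibility). The default 0 excludes such ova outright.
#' @param hybrid_selfing Logical; whether Ea-derived hybrids may
#'   self-fertilize. Default `FALSE`.
#' @param fFA_paternal_fertile Logical; whether sterile Ef-derived hybrids can
#'   still sire offspring as sperm donors. Default `FALSE` (sterile in both
#'   roles).
#' @param symbiont_vertical_p Probability that an infected mother's cocoon
#'   transmits the symbiont to an offspring (vertical transmission).
#' @param symbiont_sexual_p Probability that an infected partner's sperm
#'   infects the mother's cocoon during copulation (sexual transmission),
#'   resolved once per pairing.
#' @param mechanism Which mechanism determines the recorded M phenotype in
#'   simulations: `"mendelian"` (dominant M allele) or `"symbiont"`
#'   (phenotype follows infection status).
#' @param weight_mean_g,weight_sd_g Mean and standard deviation (grams) of the
#'   truncated-normal adult body-weight model.
#'
#' @return An object of class `eis_params` (a named list).
#' @examples
#' p <- model_params(ef_cross_success = 0)
#' p$ef_cross_success
#' @export
model_params <- function(selfing_rate = 0.5,
                         ef_cross_success = 0.1,
                         aF_ovum_viability = 0,
                         hybrid_selfing = FALSE,
                         fFA_paternal_fertile = FALSE,
                         symbiont_vertical_p = 1,
                         symbiont_sexual_p = 0.5,
                         mechanism = c("mendelian", "symbiont"),
                         weight_mean_g = 0.77,
                         weight_sd_g = 0.18) {
  mechanism <- match.arg(mechanism)
  probs <- c(selfing_rate = selfing_rate,
             ef_cross_success = ef_cross_success,
             aF_ovum_viability = aF_ovum_viability,
             symbiont_vertical_p = symbiont_vertical_p,
             symbiont_sexual_p = symbiont_sexual_p)
  bad <- !is.finite(probs) | probs < 0 | probs > 1
  if (any(bad)) {
    stop("probabilities must lie in [0, 1]: ",
         paste(names(probs)[bad], collapse = ", "), call. = FALSE)
  }
  if (!is.logical(hybrid_selfing) || length(hybrid_selfing) != 1L ||
      is.na(hybrid_selfing)) {
    stop("'hybrid_selfing' must be TRUE or FALSE", call. = FALSE)
  }
  if (!is.logical(fFA_paternal_fertile) || length(fFA_paternal_fertile) != 1L ||
      is.na(fFA_paternal_fertile)) {
    stop("'fFA_paternal_fertile' must be TRUE or FALSE", call. = FALSE)
  }
  if (!is.numeric(weight_mean_g) || weight_mean_g <= 0 ||
      !is.numeric(weight_sd_g) || weight_sd_g < 0) {
    stop("weight model needs a positive mean and nonnegative SD", call. = FALSE)
  }
  structure(list(selfing_rate = selfing_rate,
                 ef_cross_success = ef_cross_success,
                 aF_ovum_viability = aF_ovum_viability,
                 hybrid_selfing = hybrid_selfing,
                 fFA_paternal_fertile = fFA_paternal_fertile,
                 symbiont_vertical_p = symbiont_vertical_p,
                 symbiont_sexual_p = symbiont_sexual_p,
                 mechanism = mechanism,
                 weight_mean_g = weight_mean_g,
                 weight_sd_g = weight_sd_g),
            class = "eis_params")
}

#' @export
print.eis_params <- function(x, ...) {
  cat("Cytonuclear model parameters\n")
  cat(sprintf("  selfing rate (sigma)        : %g\n", x$selfing_rate))
  cat(sprintf("  Ef-ova cross success (h)    : %g\n", x$ef_cross_success))
  cat(sprintf("  aF ovum viability (v)       : %g\n", x$aF_ovum_viability))
  cat(sprintf("  hybrid selfing enabled      : %s\n", x$hybrid_selfing))
  cat(sprintf("  fFA paternal fertility      : %s\n", x$fFA_paternal_fertile))
  cat(sprintf("  symbiont vertical / sexual p: %g / %g\n",
              x$symbiont_vertical_p, x$symbiont_sexual_p))
  cat(sprintf("  phenotype mechanism         : %s\n", x$mechanism))
  cat(sprintf("  body weight mean / SD (g)   : %g / %g\n",
              x$weight_mean_g, x$weight_sd_g))
  invisible(x)
}

as_model_params <- function(x) {
  if (inherits(x, "eis_params")) return(x)
  if (is.null(x)) return(model_params())
  if (!is.list(x)) stop("params must be a list or an 'eis_params' object",
                        call. = FALSE)
  known <- names(formals(model_params))
  extra <- setdiff(names(x), known)
  if (length(extra)) {
    stop("unknown parameter field(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  do.call(model_params, x)
}
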