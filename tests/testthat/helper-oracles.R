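# Independent brute-force oracles. These enumerate gametes and zygotes with
# explicit character indexing and nested loops, sharing no code with the
# package's term-table machinery.

# gamete distribution by direct enumeration of the four (nuclear, M) picks
oracle_gametes <- function(g, kind) {
  ch <- strsplit(g, "")[[1]]
  codes <- character(0)
  for (i in 2:3) {
    for (j in 4:5) {
      codes <- c(codes,
                 if (kind == "ovum") paste0(ch[1], ch[i], ch[j])
                 else paste0(ch[i], ch[j]))
    }
  }
  tab <- table(codes) / 4
  out <- as.numeric(tab)
  names(out) <- names(tab)
  out[order(names(out))]
}

oracle_is_hybrid <- function(g) {
  ch <- strsplit(g, "")[[1]]
  !(ch[2] == ch[3] &&
      ((ch[1] == "a" && ch[2] == "A") || (ch[1] == "f" && ch[2] == "F")))
}

oracle_is_ef_hybrid <- function(g) {
  substr(g, 1, 1) == "f" && oracle_is_hybrid(g)
}

# Offspring distribution of one mother role by quadruple loop over allele
# picks. father = NULL means pure selfing (self weight 1). Returns a sorted
# named probability vector, or NULL when the configuration is sterile.
oracle_brood <- function(mother, father = NULL, sigma = 0.5, h = 0.1, v = 0,
                         hybrid_selfing = FALSE, ffa_paternal = FALSE) {
  mch <- strsplit(mother, "")[[1]]
  if (oracle_is_ef_hybrid(mother)) return(NULL)
  pure_selfing <- is.null(father)
  self_ok <- !oracle_is_hybrid(mother) || hybrid_selfing
  if (pure_selfing && !self_ok) return(NULL)
  if (!pure_selfing && oracle_is_hybrid(mother) && oracle_is_hybrid(father)) {
    return(NULL)
  }
  probs <- numeric(0)
  add <- function(code, w) {
    probs[code] <<- (if (code %in% names(probs)) probs[[code]] else 0) + w
  }
  sperm_sources <- list(list(ch = mch, kind = "self"))
  if (!pure_selfing) {
    fch <- strsplit(father, "")[[1]]
    father_ok <- !oracle_is_ef_hybrid(father) || ffa_paternal
    if (father_ok) {
      sperm_sources <- c(sperm_sources, list(list(ch = fch, kind = "cross")))
    }
  }
  for (oi in 2:3) for (oj in 4:5) {
    ovum_nuc <- mch[oi]
    ovum_m <- mch[oj]
    viab <- if (mch[1] == "a" && ovum_nuc == "F") v else 1
    for (src in sperm_sources) {
      mix <- if (pure_selfing) 1
        else if (src$kind == "self") (if (self_ok) sigma else 0)
        else 1 - sigma
      for (si in 2:3) for (sj in 4:5) {
        sperm_nuc <- src$ch[si]
        sperm_m <- src$ch[sj]
        w <- (1 / 16) * mix * viab
        if (src$kind == "cross" && mch[1] == "f" && sperm_nuc == "A") {
          w <- w * h
        }
        if (w > 0) {
          add(paste0(mch[1], ovum_nuc, sperm_nuc, ovum_m, sperm_m), w)
        }
      }
    }
  }
  if (!length(probs) || sum(probs) <= 0) return(NULL)
  probs <- probs / sum(probs)
  probs[order(names(probs))]
}

# Log-likelihood of observing n_mn M-negative offspring among n, by summing
# the probability of every genotype assignment in support^n with a matching
# Mn count. Phenotype read directly off the code (no M in positions 4-5).
oracle_family_loglik <- function(dist_probs, n, n_mn) {
  support <- names(dist_probs)
  is_mn <- !grepl("M", substr(support, 4, 5))
  grid <- expand.grid(rep(list(seq_along(support)), n))
  total <- 0
  for (r in seq_len(nrow(grid))) {
    idx <- as.integer(grid[r, ])
    if (sum(is_mn[idx]) == n_mn) {
      total <- total + prod(dist_probs[idx])
    }
  }
  log(total)
}

# every genotype in the grammar, for property sweeps
all_genotypes <- function() {
  g <- expand.grid(mito = c("a", "f"), n1 = c("A", "F"), n2 = c("A", "F"),
                   m1 = c("M", "m"), m2 = c("M", "m"),
                   stringsAsFactors = FALSE)
  paste0(g$mito, g$n1, g$n2, g$m1, g$m2)
}
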