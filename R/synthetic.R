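# Packaged study fixture and configurable synthetic cohorts, so every stage
# is testable offline.

#' Founder genotypes of the hybridization experiment
#'
#' The assumed founder genotypes: M-positive *E. andrei* `aAAMM` and
#' M-negative *E. fetida* `fFFmm`. That Ea founders are `MM` rather than `Mm`
#' is an assumption of the scheme (phenotype alone cannot separate them), not
#' an observation.
#'
#' @return Named character vector with elements `Ea` and `Ef`.
#' @export
founder_genotypes <- function() {
  c(Ea = "aAAMM", Ef = "fFFmm")
}

pad_specimens <- function(df) {
  out <- empty_specimens()[seq_len(nrow(df)), ]
  for (col in names(df)) out[[col]] <- df[[col]]
  rownames(out) <- NULL
  out
}

#' The packaged 46-specimen study table
#'
#' The class x phenotype composition of the 46 genotyped descendants of the
#' Ea + Ef pairings: 10 `Ea` and 19 `hybrid_Ea_derived` specimens, all
#' M-positive; 12 M-negative and 1 M-positive `Ef`; 3 M-positive and 1
#' M-negative `hybrid_Ef_derived`. Specimen codes named in the study text
#' (e.g. `aAA41`, `fFF_158/190`, `fFA_149/194`) are kept; the remaining ids
#' are synthetic placeholders (prefix `syn`), since the published material
#' does not list every tip code. Pedigree links and M-locus alleles of these
#' observed worms are unknown and left `NA`.
#'
#' `load_poc_family()` returns the proof-of-concept family: a selfing
#' M-positive *E. fetida* mother (`fFFMm` culture) with 7 sampled offspring,
#' 5 M-positive and 2 M-negative.
#'
#' @return A specimen data frame (see [read_specimens()] for the columns).
#' @examples
#' tabulate_classes(load_study_fixture())
#' @export
load_study_fixture <- function() {
  path <- system.file("extdata", "study_specimens.tsv",
                      package = "eiseniahyb", mustWork = TRUE)
  df <- utils::read.delim(path, sep = "\t", colClasses = "character",
                          na.strings = "NA")
  pad_specimens(df)
}

#' @rdname load_study_fixture
#' @export
load_poc_family <- function() {
  path <- system.file("extdata", "poc_family.tsv",
                      package = "eiseniahyb", mustWork = TRUE)
  df <- utils::read.delim(path, sep = "\t", colClasses = "character",
                          na.strings = "NA")
  df$generation <- as.integer(df$generation)
  pad_specimens(df)
}

#' Cohort configuration
#'
#' Configuration of a fully synthetic cohort: a mating design, model
#' parameters, and the spectral noise level used when attaching per-specimen
#' fluorescence scans.
#'
#' @param design A mating design (see [study_mating_design()]).
#' @param params An [model_params()] object or a parameter list.
#' @param spectra_noise_sd Additive noise SD of the synthetic scans (a.u.).
#' @param spectrum A [spectrum_params()] object.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(design = study_mating_design(),
                          params = model_params(),
                          spectra_noise_sd = 0,
                          spectrum = spectrum_params()) {
  config <- list(design = design, params = params,
                 spectra_noise_sd = spectra_noise_sd, spectrum = spectrum)
  validate_cohort_config(config)
}

validate_cohort_config <- function(config) {
  if (!is.list(config)) stop("config must be a list", call. = FALSE)
  extra <- setdiff(names(config),
                   c("design", "params", "spectra_noise_sd", "spectrum"))
  if (length(extra)) {
    stop("unknown config field(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(config$design)) stop("config field 'design' is required",
                                   call. = FALSE)
  config$design <- validate_design(config$design)
  config$params <- as_model_params(config$params)
  if (is.null(config$spectra_noise_sd)) config$spectra_noise_sd <- 0
  if (!is.numeric(config$spectra_noise_sd) || config$spectra_noise_sd < 0) {
    stop("config field 'spectra_noise_sd' must be a nonnegative number",
         call. = FALSE)
  }
  if (is.null(config$spectrum)) config$spectrum <- spectrum_params()
  if (!inherits(config$spectrum, "spectrum_params")) {
    config$spectrum <- do.call(spectrum_params, config$spectrum)
  }
  structure(config, class = "cohort_config")
}

#' Generate a synthetic study-like cohort
#'
#' Simulates the configured mating design and attaches, to every specimen, a
#' synthetic emission and excitation scan matching its true M phenotype at
#' the configured noise level (plus the truncated-normal body weights drawn
#' during simulation). Fully reproducible from `(config, seed)`.
#'
#' @param config A [cohort_config()] (or a plain list validated as one).
#' @param seed Integer seed; mandatory.
#' @return A list of class `eis_cohort` with `specimens` (data frame) and
#'   `spectra` (named list per specimen id, each with `emission` and
#'   `excitation`).
#' @examples
#' ch <- generate_cohort(cohort_config(study_mating_design(8, 6, 6)), seed = 3)
#' nrow(ch$specimens)
#' @export
generate_cohort <- function(config = cohort_config(), seed) {
  if (missing(seed) || is.null(seed)) {
    stop("'seed' is required: simulations must be reproducible",
         call. = FALSE)
  }
  config <- validate_cohort_config(config)
  set.seed(as.integer(seed))
  specimens <- run_design(config$design, config$params)
  spectra <- lapply(seq_len(nrow(specimens)), function(i) {
    st <- specimens$m_status[i]
    if (!st %in% STATUS_LEVELS) st <- "Mn"
    list(emission = generate_spectrum(st, "emission",
                                      noise_sd = config$spectra_noise_sd,
                                      params = config$spectrum),
         excitation = generate_spectrum(st, "excitation",
                                        noise_sd = config$spectra_noise_sd,
                                        params = config$spectrum))
  })
  names(spectra) <- specimens$id
  structure(list(specimens = specimens, spectra = spectra),
            class = "eis_cohort")
}

#' Classify a cohort's scans back to phenotypes
#'
#' Runs [classify_spectrum()] on every specimen's attached scan pair.
#'
#' @param cohort An `eis_cohort` from [generate_cohort()].
#' @param prominence_threshold Passed to [classify_spectrum()].
#' @return Named character vector of called phenotypes, by specimen id.
#' @export
classify_cohort_spectra <- function(cohort, prominence_threshold = 2) {
  stopifnot(inherits(cohort, "eis_cohort"))
  vapply(cohort$spectra, function(sp) {
    classify_spectrum(sp$emission, sp$excitation,
                      prominence_threshold)$m_status
  }, "")
}

#' Write a cohort to a directory
#'
#' Writes `specimens.tsv` plus per-specimen `spectra/<id>_emission.csv` and
#' `spectra/<id>_excitation.csv` (ids sanitized for the filesystem).
#'
#' @param cohort An `eis_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "eis_cohort"))
  dir.create(file.path(dir, "spectra"), recursive = TRUE,
             showWarnings = FALSE)
  write_specimens(cohort$specimens, file.path(dir, "specimens.tsv"))
  for (id in names(cohort$spectra)) {
    safe <- gsub("[^A-Za-z0-9_.-]", "-", id)
    write_spectrum(cohort$spectra[[id]]$emission,
                   file.path(dir, "spectra", paste0(safe, "_emission.csv")))
    write_spectrum(cohort$spectra[[id]]$excitation,
                   file.path(dir, "spectra", paste0(safe, "_excitation.csv")))
  }
  invisible(dir)
}
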