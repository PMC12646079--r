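#' Simulate regional brain volumes for a 72-region atlas
#'
#' Draws log-normal volumes for every subject, region and timepoint. Each
#' region has a fixed population mean (spread over a realistic mouse range
#' of roughly 0.3-25 mm^3); the generating coefficient of variation is
#' `cfg$volume_cv` exactly (the log-normal sigma is chosen so that the
#' distribution's mean equals the regional mean and its CV equals
#' `volume_cv`). Males carry a multiplicative `volume_sex_effect` excess
#' in adolescence only, mirroring sex differences that wash out by
#' adulthood, and all regions grow by `volume_growth` into adulthood.
#'
#' @param cfg A [sim_config()].
#' @param cohort Cohort table from [make_cohort()].
#' @return Long-format data frame: `subject_id`, `genotype`, `sex`,
#'   `timepoint`, `region`, `value`, `value_kind = "absolute_mm3"`.
#' @export
simulate_regional_volumes <- function(cfg, cohort) {
  nreg <- cfg$volume_region_count
  regions <- sprintf("region_%02d", seq_len(nreg))
  region_mean <- exp(seq(log(0.3), log(25), length.out = nreg))
  cv <- cfg$volume_cv
  sigma <- if (cv > 0) sqrt(log(1 + cv^2)) else 0
  with_seed(cfg$seed + 1L, {
    rows <- lapply(seq_len(nrow(cohort)), function(k) {
      rec <- cohort[k, ]
      mu <- region_mean
      if (rec$timepoint == "adulthood") mu <- mu * (1 + cfg$volume_growth)
      if (rec$sex == "M" && rec$timepoint == "adolescence") {
        mu <- mu * (1 + cfg$volume_sex_effect)
      }
      noise <- if (sigma > 0) exp(rnorm(nreg, -sigma^2 / 2, sigma)) else rep(1, nreg)
      data.frame(
        subject_id = rec$subject_id, genotype = rec$genotype, sex = rec$sex,
        timepoint = rec$timepoint, region = regions, value = mu * noise,
        value_kind = "absolute_mm3"
      )
    })
    do.call(rbind, rows)
  })
}

#' Simulate paired white-matter fractional anisotropy medians
#'
#' Adolescent FA per subject and region is the regional mean plus a
#' subject-level deviation (`fa_subject_sd`). Adult FA is the subject's
#' own adolescent value plus the developmental increment
#' `developmental_delta_fa` plus residual noise (`fa_noise_sd`). The
#' olfactory tract receives a zero increment, reflecting the early
#' maturation of the olfactory system relative to other tracts. Values
#' are clamped to the FA range `[0, 1]`.
#'
#' @param cfg A [sim_config()].
#' @param cohort Cohort table from [make_cohort()].
#' @return Long-format data frame: `subject_id`, `genotype`, `sex`,
#'   `timepoint`, `region`, `value`, `value_kind = "fa_median"`.
#' @export
simulate_fa_table <- function(cfg, cohort) {
  regions <- cfg$fa_regions
  nreg <- length(regions)
  base <- seq(0.30, 0.45, length.out = nreg)
  names(base) <- regions
  delta <- rep(cfg$developmental_delta_fa, nreg)
  names(delta) <- regions
  if ("olfactory_tract" %in% regions) delta["olfactory_tract"] <- 0
  subjects <- cohort_subjects(cohort)
  with_seed(cfg$seed + 2L, {
    rows <- lapply(seq_len(nrow(subjects)), function(k) {
      rec <- subjects[k, ]
      adol <- base + rnorm(nreg, 0, cfg$fa_subject_sd)
      adult <- adol + delta + rnorm(nreg, 0, cfg$fa_noise_sd)
      data.frame(
        subject_id = rec$subject_id, genotype = rec$genotype, sex = rec$sex,
        timepoint = rep(c("adolescence", "adulthood"), each = nreg),
        region = c(regions, regions),
        value = pmin(pmax(c(adol, adult), 0), 1),
        value_kind = "fa_median"
      )
    })
    do.call(rbind, rows)
  })
}
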