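#' Post-mortem tissue donor demographics
#'
#' The bundled donor table for the worked example: 5 neurologically normal
#' controls and 13 ALS cases with age at death, sex, post-mortem delay (h),
#' sporadic/familial status and site of symptom onset.
#'
#' @return data.frame with columns `case`, `group`, `age_y`, `sex`, `pmd_h`,
#'   `als_type`, `onset_site`.
#' @export
donor_table <- function() {
  read.csv(system.file("extdata", "donor_demographics.csv",
                       package = "cordleak"),
           stringsAsFactors = FALSE)
}

#' Per-cohort summary of the donor table
#'
#' Mean and SD of age and post-mortem delay, and the F/M split, per group.
#'
#' @param donors a donor table (default [donor_table()]).
#' @return data.frame with one row per group.
#' @export
donor_summary <- function(donors = donor_table()) {
  out <- lapply(split(donors, donors$group), function(d) {
    data.frame(
      group = d$group[1], n = nrow(d),
      age_mean = mean(d$age_y), age_sd = sd(d$age_y),
      pmd_mean = mean(d$pmd_h), pmd_sd = sd(d$pmd_h),
      n_female = sum(d$sex == "F"), n_male = sum(d$sex == "M")
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$group != "control"), ]
}
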