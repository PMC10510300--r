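#' Reference variance components used as simulation truths
#'
#' Published posterior-mean estimates for the sow thermotolerance indicator
#' traits (additive genetic variance, heritability and, for repeated-record
#' traits, repeatability). The package uses these magnitudes as the true
#' parameters of its recovery simulations; they are not re-estimated from any
#' raw data.
#'
#' @return data frame: \code{trait}, \code{sigma_a}, \code{h2}, \code{re}
#'   (NA for single-record traits), \code{repeated}.
#' @export
reference_variance_components <- function() {
  df <- read.csv(text = "trait,sigma_a,h2,re
T_ES,0.0313,0.04,0.10
T_SS,0.0446,0.06,0.21
T_RS,0.0290,0.06,0.22
T_TS,0.0298,0.05,0.18
T_Vall,0.0620,0.15,0.37
T_V4days,0.0619,0.22,0.57
T_V8h,0.0633,0.23,0.59
T_V12h,0.0767,0.24,0.56
T_V16h,0.0699,0.19,0.52
T_V20h,0.0631,0.20,0.54
T_V8hS,0.0686,0.25,NA
T_V12hS,0.0934,0.29,NA
T_V16hS,0.0771,0.22,NA
T_V20hS,0.0778,0.22,NA
RR,33.590,0.06,0.19
PS,0.0106,0.05,0.16
R_eff,0.0001,0.03,NA
BCS_Cal,3.7127,0.29,NA
BCS_Vis,0.0710,0.25,NA
HD,0.0577,0.25,NA
BS,0.1156,0.33,NA
EA,1151.7,0.40,NA
EL,2.4413,0.32,NA", stringsAsFactors = FALSE)
  df$repeated <- !is.na(df$re)
  df
}

#' Variance components for one reference trait
#'
#' Convenience lookup combining [reference_variance_components()] and
#' [trait_variances()].
#'
#' @param trait trait name as in [reference_variance_components()].
#' @return list with \code{sigma_a}, \code{sigma_pe}, \code{sigma_e} and the
#'   implied \code{h2} / \code{re}.
#' @export
reference_truth <- function(trait) {
  tab <- reference_variance_components()
  row <- tab[tab$trait == trait, ]
  if (nrow(row) != 1) stop("reference_truth: unknown trait ", trait)
  v <- trait_variances(row$sigma_a, row$h2,
                       if (row$repeated) row$re else row$h2)
  c(v, list(h2 = row$h2, re = if (row$repeated) row$re else row$h2,
            repeated = row$repeated))
}
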