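# Synthetic cohort generator. Emulates the study population shape: 18
# patients, 4 fused, two graft-material groups, six clinical instruments
# scored at baseline and 12 months, and per-patient summed SUVtotal /
# cSUVtotal. Score draws are independent uniforms inside the observed
# min-max ranges (no correlation structure is claimed by the data source
# being emulated), clipped to instrument bounds.

# observed pooled [min, max] per variable: baseline level and 12m-minus-
# baseline change, plus instrument bounds used for clipping
COHORT_RANGES <- list(
  age   = list(bs = c(60, 78)),
  bmi   = list(bs = c(21.8, 35)),
  wlk_d = list(bs = c(15, 1000), change = c(0, 985), bounds = c(0, Inf)),
  vas_b = list(bs = c(0, 9.6), change = c(-8.5, 0.1), bounds = c(0, 10)),
  vas_l = list(bs = c(1.1, 9.3), change = c(-9.1, 0.8), bounds = c(0, 10)),
  tan   = list(bs = c(0, 30), change = c(0, 30), bounds = c(0, 30)),
  odi   = list(bs = c(16, 62), change = c(-54, -4), bounds = c(0, 100)),
  eq5d  = list(bs = c(0.32, 0.82), change = c(0, 0.67), bounds = c(-0.6, 1))
)

#' Cohort simulation parameters
#'
#' @param n Number of patients (default 18).
#' @param p_fused Fusion probability (default 4/18).
#' @param effect_suv_total Additive shift of fused patients' summed SUVtotal
#'   relative to unfused (SUV.mL; default 0, no association).
#' @param uptake_range Min-max of the unfused summed SUVtotal draw
#'   (default c(474, 1766)).
#' @param p_ifactor Probability of the iFactor graft-material group.
#' @param uptake_change_assoc Rank-level association in `[0, 1]` between the
#'   uptake draw and every score-change draw (0 = independent, default; 1 =
#'   comonotone). Used to simulate cohorts where uptake predicts clinical
#'   change.
#' @param missing_rate Per-score probability that a baseline or 12-month
#'   value is missing (default 0).
#' @param seed Integer RNG seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n = 18L, p_fused = 4 / 18, effect_suv_total = 0,
                        uptake_range = c(474, 1766), p_ifactor = 8 / 18,
                        uptake_change_assoc = 0, missing_rate = 0, seed = 1L) {
  if (p_fused < 0 || p_fused > 1)
    stop_gq("p_fused must be in [0, 1]", class = "gq_argument_error")
  if (uptake_change_assoc < 0 || uptake_change_assoc > 1)
    stop_gq("uptake_change_assoc must be in [0, 1]", class = "gq_argument_error")
  structure(list(n = as.integer(n), p_fused = p_fused,
                 effect_suv_total = effect_suv_total,
                 uptake_range = uptake_range, p_ifactor = p_ifactor,
                 uptake_change_assoc = uptake_change_assoc,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic patient cohort
#'
#' Draws fused status from a binomial with the spec's fusion probability,
#' clinical scores uniformly inside the observed ranges (12-month score =
#' baseline + a change draw, clipped to instrument bounds: VAS 0-10, TAN
#' 0-30, ODI 0-100, EQ-5D <= 1, walking distance >= 0), and summed uptake
#' totals with the stated fused/unfused effect. Fully reproducible from the
#' seed.
#'
#' @param spec A [cohort_spec()].
#' @return A data frame of patient records, one row per patient, with
#'   baseline (`_bs`) and 12-month (`_12m`) score columns, `fused`, `group`,
#'   `suv_total` and `c_suv_total`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n
  rng <- COHORT_RANGES
  draw <- function(r) runif(n, r[1L], r[2L])
  clip <- function(x, b) pmin(pmax(x, b[1L]), b[2L])
  fused <- rbinom(n, 1L, spec$p_fused) == 1L
  u_uptake <- runif(n)  # shared rank driver for the uptake/change coupling
  a <- spec$uptake_change_assoc
  out <- data.frame(
    id = sprintf("P%02d", seq_len(n)),
    group = ifelse(runif(n) < spec$p_ifactor, "iFactor", "allograft"),
    fused = fused,
    age = draw(rng$age$bs),
    bmi = draw(rng$bmi$bs))
  for (v in c("wlk_d", "vas_b", "vas_l", "tan", "odi", "eq5d")) {
    bs <- draw(rng[[v]]$bs)
    cu <- a * u_uptake + (1 - a) * runif(n)
    chg <- rng[[v]]$change[1L] + cu * diff(rng[[v]]$change)
    m12 <- clip(bs + chg, rng[[v]]$bounds)
    out[[paste0(v, "_bs")]] <- bs
    out[[paste0(v, "_12m")]] <- m12
  }
  out$suv_total <- spec$uptake_range[1L] +
    u_uptake * diff(spec$uptake_range) +
    ifelse(fused, spec$effect_suv_total, 0)
  out$suv_total <- pmax(out$suv_total, 1)
  out$c_suv_total <- out$suv_total * runif(n, 1.0, 1.1)
  if (spec$missing_rate > 0) {
    score_cols <- grep("_(bs|12m)$", names(out), value = TRUE)
    for (cl in score_cols) {
      miss <- runif(n) < spec$missing_rate
      out[[cl]][miss] <- NA_real_
    }
  }
  out
}
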