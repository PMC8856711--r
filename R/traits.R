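#' Sample latent responder traits and planted ground truth
#'
#' Each participant carries one latent scalar trait per non-neutral
#' emotion, drawn from a zero-mean normal distribution. The trait loads
#' simultaneously onto that emotion's event-related component amplitudes
#' (P300 and LPP), its phasic skin-conductance driver, and its signed
#' effect on log reaction time. The intended group label of a participant
#' in an emotion condition is the sign of the planted RT effect:
#' `facilitated` for a negative effect (faster than neutral), `impeded`
#' for a positive one. When every loading and shift is zero the planted RT
#' effects are exactly zero and the label is `undefined`.
#'
#' This is the minimal latent structure under which physiological features
#' referenced to the neutral condition are informative about the direction
#' of the attentional effect, so that the downstream classifier has a
#' recoverable signal.
#'
#' @param config A [cohort_config()].
#' @return A tibble of class `cohort_truth` with one row per participant
#'   and condition: `participant`, `condition`, `trait`, `p300_amp_uv`,
#'   `lpp_amp_uv`, `scr_driver`, `rt_effect`, `intended_label`.
#' @export
#' @examples
#' truth <- sample_traits(cohort_config(n_participants = 3, seed = 2))
#' dplyr::count(truth, intended_label)
sample_traits <- function(config) {
  validate_cohort_config(config)
  tp <- config$trait_params
  cp <- config$component_params
  sp <- config$scr_params
  if (!is.finite(tp$load_erp_uv) || !is.finite(tp$load_scr) || !is.finite(tp$load_rt)) {
    abort("Trait loadings must be finite.")
  }
  with_seed(derive_seed(config$seed, 0L, 2L), {
    grid <- tidyr::expand_grid(
      participant = seq_len(config$n_participants),
      condition = config$conditions
    )
    z <- rnorm(nrow(grid), 0, tp$trait_sd)
    z[grid$condition == "neutral"] <- 0
    shift <- ifelse(grid$condition == "neutral", 0,
                    unname(tp$rt_shift[grid$condition]))
    rt_effect <- ifelse(grid$condition == "neutral", 0,
                        shift + tp$load_rt * z)
    out <- tibble(
      participant = grid$participant,
      condition = grid$condition,
      trait = z,
      p300_amp_uv = unname(cp$p300_amp_uv[grid$condition]) + tp$load_erp_uv * z,
      lpp_amp_uv = unname(cp$lpp_amp_uv[grid$condition]) + tp$load_erp_uv * z,
      scr_driver = pmax(0, unname(sp$driver[grid$condition]) + tp$load_scr * z),
      rt_effect = rt_effect,
      intended_label = dplyr::case_when(
        condition == "neutral" ~ NA_character_,
        rt_effect < 0 ~ "facilitated",
        rt_effect > 0 ~ "impeded",
        TRUE ~ "undefined"
      )
    )
    if (any(out$intended_label == "undefined", na.rm = TRUE)) {
      warn("Some planted RT effects are exactly zero; their intended labels are `undefined`.")
    }
    class(out) <- c("cohort_truth", class(out))
    out
  })
}
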