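#' Default PRIAS-like population parameters
#'
#' A hand-specified, realistic parameter set emulating a PRIAS-like active
#' surveillance population, used as the simulation truth and as the oracle
#' parameters of the scheduling experiments. The trajectory rises slowly on
#' the log2-PSA scale (entry level about log2(6), population velocity 0.04
#' per year), with subject-level heterogeneity calibrated so that the
#' quartiles of the fitted PSA velocities are close to (-0.06, 0.14) — the
#' interval over which the hazard of reclassification roughly doubles at the
#' default velocity association `log(2.05)/0.2`. Age effects are mild. The
#' nominal baseline hazard is the intermediate-progression Weibull(3, 5);
#' simulation replaces it subgroup by subgroup and prediction replaces it by
#' the subgroup-mixture marginal ([marginalBaseline()]).
#'
#' @param psa_scale outcome scale; the simulation default is `"log2psa"`.
#' @return a [modelParameters()] bundle.
#' @export
priasParams <- function(psa_scale = c("log2psa", "log2psa1")) {
  psa_scale <- match.arg(psa_scale)
  sd_b <- c(0.7, 1.15, 1.15)
  corr <- rbind(c(1, -0.1, 0), c(-0.1, 1, 0.2), c(0, 0.2, 1))
  D <- diag(sd_b) %*% corr %*% diag(sd_b)
  long <- longitudinalSpec(
    beta = c(2.59, 0.01, -5e-4, 0.0613, 0.1513, 0.2465, 0.2756),
    D = D, sigma = 0.25, residual_df = 3, psa_scale = psa_scale)
  risk <- riskSpec(gamma = c(0.03, 0), alpha_value = 0.05,
                   alpha_velocity = log(2.05) / 0.2,
                   baseline = weibullHazard(3, 5))
  modelParameters(long, risk)
}
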