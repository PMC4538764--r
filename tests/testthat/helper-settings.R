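# Worked-example settings shared across tests: continuous outcome with
# effect -0.3785 and SD 1.55, binary with baseline probability 0.26 and
# odds ratio 0.56, count with baseline rate 1.5 and rate ratio 0.8;
# K = 20 per cluster-period, J = 6 times (baseline + 5 crossovers).
worked <- list(
  theta = -0.3785, sd_y = 1.55,
  p0 = 0.26, or = 0.56,
  lambda0 = 1.5, rr = 0.8,
  n_times = 6L, cluster_size = 20L)

continuous_model <- function(icc, mode = "within",
                             time = time_effect("none"), ...) {
  outcome_model("normal", baseline = 0.3, effect = worked$theta,
                vc = variance_components(icc, worked$sd_y^2, mode, ...),
                time = time)
}
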