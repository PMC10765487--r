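#' Sampled tone-burst waveform and duty cycle
#'
#' Builds one repetition period of the burst drive: a sinusoid lasting
#' `n_cycles / carrier_frequency` seconds followed by silence until the
#' repetition period. The duty cycle is the active fraction in percent.
#'
#' @param burst a [burst_spec()]
#' @param sample_rate sampling rate in Hz; must be at least 10x the
#'   carrier frequency
#' @return a list with `t` (s), `s` (dimensionless waveform, unit
#'   amplitude) and `duty_cycle` (percent)
#' @examples
#' w <- burst_waveform(burst_spec(500, 20e-3, 250e3), sample_rate = 5e6)
#' w$duty_cycle   # 10
#' @export
burst_waveform <- function(burst, sample_rate) {
  stopifnot(inherits(burst, "burst_spec"))
  check_num(sample_rate, "sample_rate", positive = TRUE)
  if (sample_rate < 10 * burst$carrier_frequency)
    stopf("sample_rate must be >= 10x the carrier frequency")
  active <- burst$n_cycles / burst$carrier_frequency
  t <- seq(0, burst$repetition_period, by = 1 / sample_rate)
  s <- ifelse(t < active, sin(2 * pi * burst$carrier_frequency * t), 0)
  duty <- 100 * active / burst$repetition_period
  list(t = t, s = s, duty_cycle = duty)
}
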