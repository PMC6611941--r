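#' Pulsatile arterial pressure source
#'
#' The driving pressure of the circuit: two sinusoids at the cardiac
#' fundamental and its first harmonic, subtracted and offset, giving a
#' waveform with the characteristic dicrotic shape of arterial blood
#' pressure,
#' `P(t) = a1 sin(2 pi f1 t + phi1) - a2 sin(2 pi f2 t) + offset`.
#' With default parameters the waveform has period 1 s and mean 16000 Pa.
#'
#' @param t Time in seconds (vectorised).
#' @param params A `csf_params` object.
#' @return Source pressure in Pa, same length as `t`.
#' @examples
#' arterial_source(0.25)  # both sine terms vanish: 16000
#' arterial_source(0)     # 15983
#' @export
arterial_source <- function(t, params = model_parameters()) {
  params$src_amp1 * sin(2 * pi * params$src_f1 * t + params$src_phase1) -
    params$src_amp2 * sin(2 * pi * params$src_f2 * t) +
    params$src_offset
}

#' Shunt resistance at a given time
#'
#' Evaluates the shunt resistance of a [shunt_spec()]: the constant value
#' for a constant shunt, or `tv_amp * exp(-tv_decay * t) * (tv_offset +
#' sin(t))` for the time-varying malfunction model (the sine argument is
#' time in seconds, i.e. an angular frequency of 1 rad/s). Querying an
#' absent shunt is a programming error and is signalled as such.
#'
#' @param t Time in seconds (vectorised).
#' @param spec A `csf_shunt` object with `kind != "absent"`.
#' @return Resistance in ohm, same length as `t`.
#' @examples
#' shunt_resistance_at(0, shunt_time_varying())   # 15 * 1.2 = 18
#' shunt_resistance_at(3, shunt_constant(1.25))   # 1.25
#' @export
shunt_resistance_at <- function(t, spec) {
  stopifnot(inherits(spec, "csf_shunt"))
  switch(spec$kind,
    absent = stop("shunt is absent; its resistance is undefined",
                  call. = FALSE),
    constant = rep_len(spec$Rshunt, length(t)),
    time_varying =
      spec$tv_amp * exp(-spec$tv_decay * t) * (spec$tv_offset + sin(t)))
}
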