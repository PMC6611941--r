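#' Model parameters for the CSF circuit
#'
#' Constructs the full parameter set of the electrical-analog CSF model: the
#' five blood-path resistances, the CSF outflow resistance, the three
#' compliances, the constants of the pulsatile arterial pressure source, the
#' drainage-branch reference pressure and the unit-conversion constants.
#' Defaults are the published element values of the equivalent circuit
#' (resistances in ohm-analog, compliances in farad-analog, pressures in Pa).
#'
#' The electrical-hydraulic analogy maps voltage to pressure (1 V = 1 Pa),
#' current to volumetric flow, resistance to hydraulic resistance
#' (1 ohm-analog is approximately 8 mmHg/ml/min of CSF outflow resistance)
#' and capacitance to compliance.
#'
#' @param R1 Source series ("tuning") resistance, ohm. Cerebral blood flow is
#'   the current through this element.
#' @param R2 Arterial resistance, ohm.
#' @param R3 Capillary resistance, ohm.
#' @param R4 Venous resistance, ohm.
#' @param Rf Resistance of the CSF formation path from capillary blood to the
#'   choroid plexus, ohm.
#' @param Ro Resistance to CSF outflow through the arachnoid villi, ohm.
#'   1 for a healthy subject; 5 and 10 model moderate and severe
#'   (communicating) hydrocephalus.
#' @param Cai Compliance between the arterial and intracranial compartments,
#'   farad-analog.
#' @param Cvi Compliance between the venous and intracranial compartments,
#'   farad-analog.
#' @param Ctiss Compliance of the brain tissue, farad-analog.
#' @param src_amp1,src_amp2 Amplitudes of the 1 Hz and 2 Hz components of the
#'   arterial pressure source, Pa.
#' @param src_offset Mean (DC offset) of the arterial source, Pa.
#' @param src_f1,src_f2 Frequencies of the two sinusoidal components, Hz.
#' @param src_phase1 Phase of the first sinusoidal component, radians.
#' @param P_vs Pressure at the far end of the drainage branch (arachnoid
#'   villi to sagittal sinus), Pa, relative to the circuit reference. The
#'   drainage and shunt branches terminate at this pressure.
#' @param ohm_to_hydraulic Conversion constant from ohm-analog to hydraulic
#'   resistance, (mmHg/ml/min) per ohm.
#' @param pa_per_mmhg Pascals per mmHg.
#'
#' @return An object of class `csf_params` (a named list).
#' @examples
#' p <- model_parameters()
#' p$Ro
#' model_parameters(Ro = 10)$Ro
#' @export
model_parameters <- function(R1 = 6, R2 = 2.5, R3 = 3.25, R4 = 3,
                             Rf = 5, Ro = 1,
                             Cai = 0.1, Cvi = 0.1, Ctiss = 0.1,
                             src_amp1 = 17, src_amp2 = 12.5,
                             src_offset = 16000,
                             src_f1 = 1, src_f2 = 2,
                             src_phase1 = -pi / 2,
                             P_vs = 0,
                             ohm_to_hydraulic = 8,
                             pa_per_mmhg = 133.322) {
  p <- list(R1 = R1, R2 = R2, R3 = R3, R4 = R4, Rf = Rf, Ro = Ro,
            Cai = Cai, Cvi = Cvi, Ctiss = Ctiss,
            src_amp1 = src_amp1, src_amp2 = src_amp2,
            src_offset = src_offset,
            src_f1 = src_f1, src_f2 = src_f2, src_phase1 = src_phase1,
            P_vs = P_vs,
            ohm_to_hydraulic = ohm_to_hydraulic,
            pa_per_mmhg = pa_per_mmhg)
  validate_params(p)
  structure(p, class = "csf_params")
}

validate_params <- function(p) {
  res <- c("R1", "R2", "R3", "R4", "Rf", "Ro")
  comp <- c("Cai", "Cvi", "Ctiss")
  for (nm in c(res, comp, "src_f1", "src_f2", "ohm_to_hydraulic",
               "pa_per_mmhg")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("'%s' must be a single positive finite number", nm),
           call. = FALSE)
    }
  }
  invisible(p)
}

#' @export
print.csf_params <- function(x, ...) {
  cat("CSF circuit parameters\n")
  cat(sprintf("  resistances (ohm): R1=%g R2=%g R3=%g R4=%g Rf=%g Ro=%g\n",
              x$R1, x$R2, x$R3, x$R4, x$Rf, x$Ro))
  cat(sprintf("  compliances (F):   Cai=%g Cvi=%g Ctiss=%g\n",
              x$Cai, x$Cvi, x$Ctiss))
  cat(sprintf("  source: %g + %g sin(2pi %g t %+g) - %g sin(2pi %g t) Pa\n",
              x$src_offset, x$src_amp1, x$src_f1, x$src_phase1,
              x$src_amp2, x$src_f2))
  cat(sprintf("  P_vs=%g Pa; 1 ohm = %g mmHg/ml/min; %g Pa/mmHg\n",
              x$P_vs, x$ohm_to_hydraulic, x$pa_per_mmhg))
  invisible(x)
}

#' Shunt specification
#'
#' Describes the hydrocephalus shunt branch: absent, a constant hydraulic
#' resistance, or a time-varying resistance modelling valve malfunction and
#' progressive tube occlusion, `R(t) = tv_amp * exp(-tv_decay * t) *
#' (tv_offset + sin(t))`. In every case the physical shunt is a catheter in
#' series with a one-way valve, so flow is unidirectional (ventricles to
#' drainage site).
#'
#' @param kind One of `"absent"`, `"constant"`, `"time_varying"`.
#' @param Rshunt Constant shunt resistance, ohm (used when
#'   `kind = "constant"`).
#' @param tv_amp Amplitude of the time-varying resistance, ohm.
#' @param tv_decay Exponential decay rate, 1/s.
#' @param tv_offset Dimensionless offset; must exceed 1 so the resistance
#'   stays positive at finite time.
#' @param has_valve Whether the one-way valve (series diode) is present.
#' @return An object of class `csf_shunt`.
#' @examples
#' shunt_constant(1.25)
#' shunt_time_varying()
#' shunt_absent()
#' @export
shunt_spec <- function(kind = c("absent", "constant", "time_varying"),
                       Rshunt = 1.11111,
                       tv_amp = 15, tv_decay = 0.3, tv_offset = 1.2,
                       has_valve = TRUE) {
  kind <- match.arg(kind)
  if (kind == "constant" &&
      (!is.numeric(Rshunt) || length(Rshunt) != 1L || !is.finite(Rshunt) ||
       Rshunt <= 0)) {
    stop("constant shunt requires a single positive 'Rshunt'", call. = FALSE)
  }
  if (kind == "time_varying") {
    if (!is.numeric(tv_amp) || tv_amp <= 0) {
      stop("'tv_amp' must be positive", call. = FALSE)
    }
    if (!is.numeric(tv_offset) || tv_offset <= 1) {
      stop("'tv_offset' must exceed 1 so the resistance never reaches zero",
           call. = FALSE)
    }
  }
  structure(list(kind = kind, Rshunt = Rshunt,
                 tv_amp = tv_amp, tv_decay = tv_decay, tv_offset = tv_offset,
                 has_valve = isTRUE(has_valve)),
            class = "csf_shunt")
}

#' @rdname shunt_spec
#' @export
shunt_absent <- function() shunt_spec("absent")

#' @rdname shunt_spec
#' @export
shunt_constant <- function(Rshunt, has_valve = TRUE) {
  shunt_spec("constant", Rshunt = Rshunt, has_valve = has_valve)
}

#' @rdname shunt_spec
#' @param ... Passed on to [shunt_spec()].
#' @export
shunt_time_varying <- function(tv_amp = 15, tv_decay = 0.3, tv_offset = 1.2,
                               ...) {
  shunt_spec("time_varying", tv_amp = tv_amp, tv_decay = tv_decay,
             tv_offset = tv_offset, ...)
}

#' @export
print.csf_shunt <- function(x, ...) {
  desc <- switch(x$kind,
    absent = "absent",
    constant = sprintf("constant, Rshunt = %g ohm", x$Rshunt),
    time_varying = sprintf("time-varying, %g exp(-%g t) (%g + sin t) ohm",
                           x$tv_amp, x$tv_decay, x$tv_offset))
  cat("Hydrocephalus shunt:", desc,
      if (x$has_valve) "(one-way valve)" else "(no valve)", "\n")
  invisible(x)
}

#' Read model parameters from a flat key-value config file
#'
#' Reads a YAML file of flat `key: value` pairs, where keys are the argument
#' names of [model_parameters()], and overrides the corresponding defaults
#' (or the values of `base`). Unknown keys are an error, so typos in a
#' config file do not silently leave a default in place.
#'
#' @param path Path to the config file.
#' @param base A `csf_params` object supplying values for keys absent from
#'   the file.
#' @return A `csf_params` object.
#' @export
read_params_config <- function(path, base = model_parameters()) {
  stopifnot(inherits(base, "csf_params"))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) return(base)
  if (!is.list(cfg) || is.null(names(cfg)) || any(names(cfg) == "")) {
    stop("config must be a flat mapping of named scalar values",
         call. = FALSE)
  }
  unknown <- setdiff(names(cfg), names(base))
  if (length(unknown) > 0L) {
    stop("unknown parameter key(s) in config: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  merged <- unclass(base)
  merged[names(cfg)] <- lapply(cfg, as.numeric)
  do.call(model_parameters, merged)
}

#' Unit conversions
#'
#' `ohm_to_hydraulic_resistance()` maps an ohm-analog resistance to hydraulic
#' units: 1 ohm in the circuit corresponds to about 8 mmHg/ml/min of
#' resistance to CSF outflow (so the healthy `Ro = 1` ohm sits inside the
#' normal clinical 6-10 mmHg/ml/min range). `pa_to_mmhg()` and
#' `mmhg_to_pa()` convert pressures.
#'
#' @param R Resistance in ohm-analog; must be non-negative.
#' @param params A `csf_params` object supplying the conversion constants.
#' @return Hydraulic resistance in mmHg/ml/min.
#' @examples
#' ohm_to_hydraulic_resistance(1)  # 8
#' pa_to_mmhg(2496)                # 18.72
#' @export
ohm_to_hydraulic_resistance <- function(R, params = model_parameters()) {
  if (any(!is.finite(R)) || any(R < 0)) {
    stop("'R' must be non-negative", call. = FALSE)
  }
  R * params$ohm_to_hydraulic
}

#' @rdname ohm_to_hydraulic_resistance
#' @param p Pressure in Pa (`pa_to_mmhg`) or mmHg (`mmhg_to_pa`).
#' @export
pa_to_mmhg <- function(p, params = model_parameters()) {
  p / params$pa_per_mmhg
}

#' @rdname ohm_to_hydraulic_resistance
#' @export
mmhg_to_pa <- function(p, params = model_parameters()) {
  p * params$pa_per_mmhg
}
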