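#' Model parameters for the HB+Ih thermoreceptor neuron
#'
#' Constructs the full parameter set of the HB+Ih conductance-based model: a
#' Huber & Braun type cold-thermoreceptor neuron with a fast spike-generating
#' pair (persistent sodium-like depolarizing current \eqn{I_d} and delayed
#' rectifier \eqn{I_r}), a slow oscillator pair (slow depolarizing \eqn{I_{sd}}
#' and calcium-activated potassium-like \eqn{I_{sr}}), a
#' hyperpolarization-activated cation current \eqn{I_h} and a leak. Defaults are
#' the model's published reference values; any subset can be overridden.
#'
#' Units: conductance densities in mS/cm^2, voltages in mV, time constants in
#' ms, capacitance in uF/cm^2, `eta` in cm^2/uA; `kappa`, `K_sr` are
#' dimensionless; temperature `temperature` in degrees Celsius. `K_sr` is the
#' saturation constant of the \eqn{I_{sr}} calcium-binding term
#' \eqn{a_{sr}^2/(a_{sr}^2 + K_{sr})}; its default 0.16 = 0.4^2 puts the
#' half-activation of the gate at \eqn{a_{sr} = 0.4}.
#'
#' @param ... named overrides of any parameter; unknown names are an error.
#' @param temperature temperature in degrees C (default 36, near-physiological).
#'
#' @return An object of class `hb_params`: a named list of all parameters.
#' @examples
#' p <- hb_params(g_h = 0.2, temperature = 36)
#' p$g_sd
#' @export
hb_params <- function(..., temperature = 36) {
  p <- hb_default_params()
  p$temperature <- temperature
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop("all parameter overrides must be named", call. = FALSE)
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "), call. = FALSE)
    p[names(dots)] <- dots
  }
  validate_hb_params(p)
}

hb_default_params <- function() {
  list(
    C_m   = 1.0,
    g_d   = 2.5,  g_r   = 2.8,  g_sd = 0.21, g_sr = 0.28,
    g_l   = 0.06, g_h   = 0.4,
    V0_d  = -25,  V0_r  = -25,  V0_sd = -40, V0_h = -85,
    s_d   = 0.25, s_r   = 0.25, s_sd  = 0.11, s_h = -0.14,
    tau_r = 2,    tau_sd = 10,  tau_sr = 35,  tau_h = 125,
    E_d   = 50,   E_sd  = 50,   E_r   = -90,  E_sr = -90,
    E_l   = -80,  E_h   = -30,
    kappa = 0.18, eta   = 0.014, K_sr = 0.16,
    temperature = 36, spike_threshold = -15
  )
}

validate_hb_params <- function(p) {
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x), logical(1))
  if (!all(num))
    stop("all parameters must be finite numeric scalars; offending: ",
         paste(names(p)[!num], collapse = ", "), call. = FALSE)
  if (p$C_m <= 0) stop("C_m must be positive", call. = FALSE)
  taus <- c("tau_r", "tau_sd", "tau_sr", "tau_h")
  if (any(unlist(p[taus]) <= 0)) stop("all time constants must be positive", call. = FALSE)
  gs <- c("g_d", "g_r", "g_sd", "g_sr", "g_l", "g_h")
  if (any(unlist(p[gs]) < 0)) stop("conductance densities must be non-negative", call. = FALSE)
  if (p$K_sr <= 0) stop("K_sr must be positive", call. = FALSE)
  structure(p, class = "hb_params")
}

#' @export
print.hb_params <- function(x, ...) {
  cat("<hb_params> HB+Ih model parameters\n")
  cat(sprintf("  T = %g degC  (rho = %.4f, phi = %.4f)\n",
              x$temperature,
              temperature_factors(x$temperature)["rho"],
              temperature_factors(x$temperature)["phi"]))
  cat(sprintf("  g: d=%g r=%g sd=%g sr=%g l=%g h=%g mS/cm^2\n",
              x$g_d, x$g_r, x$g_sd, x$g_sr, x$g_l, x$g_h))
  cat(sprintf("  tau: r=%g sd=%g sr=%g h=%g ms;  spike threshold %g mV\n",
              x$tau_r, x$tau_sd, x$tau_sr, x$tau_h, x$spike_threshold))
  invisible(x)
}

#' Temperature scale factors for conductances and kinetics
#'
#' The model scales all ionic currents by \eqn{\rho(T) = 1.3^{(T-25)/10}} and
#' all gating kinetics by \eqn{\phi(T) = 3^{(T-25)/10}}; both equal 1 at the
#' reference temperature 25 degC.
#'
#' @param temperature temperature in degrees Celsius.
#' @return Named numeric vector with elements `rho` and `phi`.
#' @examples
#' temperature_factors(25)  # c(rho = 1, phi = 1)
#' @export
temperature_factors <- function(temperature) {
  stopifnot(is.finite(temperature))
  c(rho = 1.3^((temperature - 25) / 10), phi = 3^((temperature - 25) / 10))
}

# Fixed-order numeric vector handed to the C++ kernels. rho/phi precomputed.
param_vector <- function(p) {
  tf <- temperature_factors(p$temperature)
  c(p$C_m, p$g_d, p$g_r, p$g_sd, p$g_sr, p$g_l, p$g_h,
    p$V0_d, p$V0_r, p$V0_sd, p$V0_h, p$s_d, p$s_r, p$s_sd, p$s_h,
    p$tau_r, p$tau_sd, p$tau_sr, p$tau_h,
    p$E_d, p$E_sd, p$E_r, p$E_sr, p$E_l, p$E_h,
    p$kappa, p$eta, p$K_sr, tf[["rho"]], tf[["phi"]])
}

#' Read and write parameter sets as JSON
#'
#' Parameter files carry exactly the field names of [hb_params()] (`g_sd`,
#' `tau_h`, ...). Unknown keys in a file are rejected; missing keys fall back
#' to the defaults. Writing and re-reading preserves values to full double
#' precision.
#'
#' @param params an `hb_params` object.
#' @param path file path.
#' @return `read_hb_params()` returns an `hb_params` object;
#'   `write_hb_params()` returns `path` invisibly.
#' @export
write_hb_params <- function(params, path) {
  stopifnot(inherits(params, "hb_params"))
  # I(17) = 17 *significant* digits, the shortest length guaranteed to
  # round-trip an IEEE double exactly (digits = NA drops the last ulp)
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname write_hb_params
#' @export
read_hb_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  # JSON has no integer/double distinction; whole numbers come back as
  # integers, but hb_params fields are doubles
  x <- lapply(x, function(v) if (is.numeric(v)) as.numeric(v) else v)
  known <- names(hb_params())
  unknown <- setdiff(names(x), known)
  if (length(unknown))
    stop("unknown parameter key(s) in ", path, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  do.call(hb_params, c(x[setdiff(names(x), "temperature")],
                       list(temperature = if (is.null(x$temperature)) 36 else x$temperature)))
}
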