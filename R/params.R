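#' Mean-field network parameters
#'
#' Constructs the full parameter set of one excitatory/inhibitory/adapting
#' mean-field network. Defaults are the reference operating point at which
#' an isolated network oscillates between a quiescent Down state and an
#' active Up state: membrane-scale time constants for the fast populations,
#' a much slower adaptation variable, threshold-linear response functions
#' with saturation, and a weak Gaussian noise current that triggers the
#' state transitions.
#'
#' `w_ee` is the recurrent excitatory-excitatory weight; when the network
#' is the efferent (driven) member of a coupled pair this weight is
#' conventionally called `W_INT`. `w_ext` scales the excitatory drive
#' received from an afferent network (`i_E(t) = w_ext * E_afferent(t)`)
#' and is 0 for an isolated network.
#'
#' @param tau_e,tau_i,tau_a time constants (ms) of the excitatory,
#'   inhibitory and adaptation variables; all positive.
#' @param g_e,g_i response gains (dimensionless, positive).
#' @param theta_e,theta_i response thresholds (dimensionless current).
#' @param w_ee,w_ei,w_ie,w_ii,w_ea,w_ae synaptic weights (dimensionless,
#'   non-negative). `w_XY` is the weight from population Y onto X;
#'   `w_ea` weights adaptation onto excitation, `w_ae` excitation onto
#'   adaptation.
#' @param sigma_noise SD of the zero-mean Gaussian noise current added
#'   inside the response-function argument of both populations.
#' @param w_ext afferent-to-efferent excitatory weight (0 = isolated).
#' @param shared_noise if `TRUE` the excitatory and inhibitory populations
#'   receive the same noise draw each step; the default uses independent
#'   draws.
#' @return an object of class `uds_params` (a named list).
#' @export
uds_params <- function(tau_e = 10, tau_i = 5, tau_a = 300,
                       g_e = 6, g_i = 30,
                       theta_e = 0.0517, theta_i = 0.2778,
                       w_ee = 1, w_ei = 0.166, w_ie = 1.66, w_ii = 0.083,
                       w_ea = 0.166, w_ae = 1.1,
                       sigma_noise = 0.03, w_ext = 0,
                       shared_noise = FALSE) {
  p <- list(tau_e = tau_e, tau_i = tau_i, tau_a = tau_a,
            g_e = g_e, g_i = g_i,
            theta_e = theta_e, theta_i = theta_i,
            w_ee = w_ee, w_ei = w_ei, w_ie = w_ie, w_ii = w_ii,
            w_ea = w_ea, w_ae = w_ae,
            sigma_noise = sigma_noise, w_ext = w_ext,
            shared_noise = isTRUE(shared_noise))
  validate_uds_params(p)
  class(p) <- "uds_params"
  p
}

#' Reference simulation parameter set
#'
#' [uds_params()] defaults carry the textbook constants used throughout
#' the fixed-point algebra. For time-stepping, the package's reference
#' operating point differs in one value: the inhibitory time constant is
#' 3.5 ms rather than 5 ms. At `tau_i = 5` the linearized fast subsystem
#' violates the determinant/trace stability requirement over the upper
#' part of the recurrent-excitation range used for fitting
#' (`tau_i * (g_e*w_ee + 1) < tau_e * (g_i*w_ii + 1)` fails already at
#' `w_ee = 1`), leaving the Up state so weakly damped that it collapses
#' through fast excitatory-inhibitory ringing regardless of recurrent
#' strength; 3.5 ms is the largest round value satisfying the stability
#' requirement across the whole fitted grid (`tau_i < 4.5` at
#' `w_ee = 1.12`), and restores the defining phenomenology: Up-state
#' lifetime and persistence grow with `w_ee`. All other constants equal
#' the [uds_params()] defaults. See the methods vignette.
#'
#' @param ... overrides passed to [uds_params()]
#' @return a `uds_params` object
#' @export
sim_params <- function(...) {
  args <- list(...)
  if (is.null(args$tau_i)) args$tau_i <- 3.5
  do.call(uds_params, args)
}

validate_uds_params <- function(p) {
  num <- p[setdiff(names(p), "shared_noise")]
  if (!all(vapply(num, function(x) is.numeric(x) && length(x) == 1 && is.finite(x), TRUE)))
    stop("all parameters must be finite scalars")
  if (any(unlist(p[c("tau_e", "tau_i", "tau_a")]) <= 0))
    stop("time constants must be positive")
  if (p$g_e <= 0 || p$g_i <= 0) stop("gains must be positive")
  if (p$sigma_noise < 0) stop("sigma_noise must be non-negative")
  w <- unlist(p[c("w_ee", "w_ei", "w_ie", "w_ii", "w_ea", "w_ae", "w_ext")])
  if (any(w < 0)) stop("weights must be non-negative")
  invisible(p)
}

#' @export
print.uds_params <- function(x, ...) {
  cat("Mean-field network parameters (uds_params)\n")
  cat(sprintf("  tau_E/I/A: %g / %g / %g ms   g_E/I: %g / %g\n",
              x$tau_e, x$tau_i, x$tau_a, x$g_e, x$g_i))
  cat(sprintf("  theta_E/I: %g / %g   sigma: %g\n",
              x$theta_e, x$theta_i, x$sigma_noise))
  cat(sprintf("  W_EE=%g W_EI=%g W_IE=%g W_II=%g W_EA=%g W_AE=%g W_EXT=%g\n",
              x$w_ee, x$w_ei, x$w_ie, x$w_ii, x$w_ea, x$w_ae, x$w_ext))
  invisible(x)
}

#' Modify a parameter set
#'
#' Convenience for grid sweeps: returns a copy of `p` with the named
#' fields replaced, re-validated.
#'
#' @param p a `uds_params` object
#' @param ... named fields to replace, e.g. `w_ee = 1.08`
#' @export
update_params <- function(p, ...) {
  stopifnot(inherits(p, "uds_params"))
  repl <- list(...)
  bad <- setdiff(names(repl), names(unclass(p)))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  p[names(repl)] <- repl
  validate_uds_params(p)
  class(p) <- "uds_params"
  p
}

# symbol names used in serialized parameter files
.param_symbols <- c(tau_e = "tau_E", tau_i = "tau_I", tau_a = "tau_A",
                    g_e = "g_E", g_i = "g_I",
                    theta_e = "theta_E", theta_i = "theta_I",
                    w_ee = "W_EE", w_ei = "W_EI", w_ie = "W_IE",
                    w_ii = "W_II", w_ea = "W_EA", w_ae = "W_AE",
                    sigma_noise = "sigma_noise", w_ext = "W_EXT",
                    shared_noise = "shared_noise")

#' Read/write parameters as flat JSON or YAML
#'
#' Parameters serialize to a flat mapping keyed by the conventional symbol
#' names (`tau_E`, `g_E`, `theta_E`, `W_EE`, ...), so a parameter file is
#' readable on its own and portable across implementations.
#'
#' @param p a `uds_params` object
#' @param path file path; format chosen by extension (`.json`, `.yaml`/`.yml`)
#' @return `read_params` returns a `uds_params`; `write_params` returns
#'   `path` invisibly.
#' @export
write_params <- function(p, path) {
  stopifnot(inherits(p, "uds_params"))
  flat <- stats::setNames(unclass(p), .param_symbols[names(unclass(p))])
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(flat, path)
  } else {
    jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  flat <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
          else jsonlite::read_json(path, simplifyVector = TRUE)
  inv <- stats::setNames(names(.param_symbols), .param_symbols)
  unknown <- setdiff(names(flat), names(inv))
  if (length(unknown)) stop("unknown parameter key(s): ",
                            paste(unknown, collapse = ", "))
  args <- stats::setNames(flat, inv[names(flat)])
  do.call(uds_params, args)
}
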