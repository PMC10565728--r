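#' Model parameters for the G-function
#'
#' Bundles the constants of the competition model: the Lotka-Volterra
#' growth/carrying-capacity terms, the widths of the two Gaussian kernels,
#' the linear cost of evolvability, the competition-kernel variant, and the
#' extinction threshold.  Defaults are the standard parameterisation used
#' throughout the package's scenarios.
#'
#' @param r Intrinsic growth rate (per unit time).
#' @param Km Maximum carrying capacity (density), attained when the focal
#'   strategy sits at the environmental optimum.
#' @param d Cost of evolvability: a fitness penalty `d * k` subtracted from
#'   the per-capita growth rate of a species with evolvability `k`.
#' @param sigma_k2 Environmental niche size: variance of the Gaussian
#'   carrying-capacity kernel (strategy units squared).
#' @param sigma_a2 Species niche width: variance of the Gaussian competition
#'   kernel (strategy units squared).
#' @param kernel Competition-kernel variant.  `"gaussian"` is the plain
#'   Gaussian kernel; `"bounded"` adds a baseline so competition never
#'   drops below `kernel_floor`, which prevents unlimited niche packing
#'   when `sigma_a2 < sigma_k2`.
#' @param kernel_floor Baseline of the bounded kernel (unitless, in `[0, 1)`).
#' @param extinction_threshold Density below which a species is declared
#'   extinct (the deterministic model never reaches zero on its own).
#'
#' @return An object of class `evodyn_params`.
#' @examples
#' p <- model_params()
#' carrying_capacity(0, gamma = 0, params = p)  # == Km
#' @export
model_params <- function(r = 0.25, Km = 100, d = 0.05,
                         sigma_k2 = 12.5, sigma_a2 = 100,
                         kernel = c("gaussian", "bounded"),
                         kernel_floor = 0.05,
                         extinction_threshold = 1) {
  kernel <- match.arg(kernel)
  stopifnot(
    "r must be a positive scalar" = is.numeric(r) && length(r) == 1 && r > 0,
    "Km must be a positive scalar" = is.numeric(Km) && length(Km) == 1 && Km > 0,
    "d must be a non-negative scalar" = is.numeric(d) && length(d) == 1 && d >= 0,
    "sigma_k2 must be positive" = is.numeric(sigma_k2) && length(sigma_k2) == 1 && sigma_k2 > 0,
    "sigma_a2 must be positive" = is.numeric(sigma_a2) && length(sigma_a2) == 1 && sigma_a2 > 0,
    "kernel_floor must lie in [0, 1)" =
      is.numeric(kernel_floor) && length(kernel_floor) == 1 &&
      kernel_floor >= 0 && kernel_floor < 1,
    "extinction_threshold must be positive" =
      is.numeric(extinction_threshold) && length(extinction_threshold) == 1 &&
      extinction_threshold > 0
  )
  structure(
    list(r = r, Km = Km, d = d, sigma_k2 = sigma_k2, sigma_a2 = sigma_a2,
         kernel = kernel, kernel_floor = kernel_floor,
         extinction_threshold = extinction_threshold),
    class = "evodyn_params"
  )
}

#' @export
print.evodyn_params <- function(x, ...) {
  cat("G-function model parameters\n")
  cat(sprintf("  r = %g, Km = %g, d = %g\n", x$r, x$Km, x$d))
  cat(sprintf("  sigma_k2 = %g, sigma_a2 = %g\n", x$sigma_k2, x$sigma_a2))
  cat(sprintf("  kernel = %s", x$kernel))
  if (x$kernel == "bounded") cat(sprintf(" (floor %g)", x$kernel_floor))
  cat(sprintf("\n  extinction threshold = %g\n", x$extinction_threshold))
  invisible(x)
}

is_params <- function(x) inherits(x, "evodyn_params")

check_params <- function(params) {
  if (!is_params(params)) stop("`params` must be created by model_params()", call. = FALSE)
  params
}
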