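#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fit result
#'
#' @param x A `cyto_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`,
#'   `std_error`, `unit` (and `boot_se` when bootstrapped).
#' @method tidy cyto_fit
#' @export
tidy.cyto_fit <- function(x, ...) {
  x$parameters
}

#' One-row summary of a fit result
#'
#' @param x A `cyto_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `model`, `n_points`, `residual_norm`,
#'   `rmse`, `converged`.
#' @method glance cyto_fit
#' @export
glance.cyto_fit <- function(x, ...) {
  tibble(
    model = x$model_kind,
    n_points = x$n_points,
    residual_norm = x$residual_norm,
    rmse = x$residual_norm / sqrt(x$n_points),
    converged = x$converged
  )
}

#' Tidy a tensegrity equilibrium solution
#'
#' @param x A `tenseg_solution`.
#' @param ... Unused.
#' @return The member table with axial forces (`force_uN`).
#' @method tidy tenseg_solution
#' @export
tidy.tenseg_solution <- function(x, ...) {
  as_tibble(x$members)
}

#' One-row summary of a tensegrity solution
#'
#' @param x A `tenseg_solution`.
#' @param ... Unused.
#' @return A one-row tibble: `converged`, `iterations`, `residual_norm`,
#'   force balance and slack-cable count.
#' @method glance tenseg_solution
#' @export
glance.tenseg_solution <- function(x, ...) {
  balance <- max(abs(vapply(1:3, function(ax) {
    sum(x$reactions$R_uN[x$reactions$axis == ax]) +
      sum(x$applied_loads$value_uN[x$applied_loads$axis == ax])
  }, numeric(1))))
  tibble(
    converged = x$converged,
    iterations = x$iterations,
    residual_norm_uN = x$residual_norm,
    force_balance_uN = balance,
    n_slack_cables = sum(x$members$kind == "cable" & x$members$force_uN <= 0)
  )
}
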