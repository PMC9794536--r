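# cyto_curve: a tibble of a time- or displacement-indexed experiment
# signal, with a free-form metadata list in attr "meta".

new_curve <- function(df, meta = list()) {
  out <- as_tibble(df)
  attr(out, "meta") <- meta
  class(out) <- c("cyto_curve", class(out))
  out
}

#' Metadata of a curve
#'
#' Curves produced by the simulation and synthesis functions carry a
#' metadata list (model variant, parameters, seed, ...) alongside their
#' columns.
#'
#' @param curve A `cyto_curve` tibble.
#' @return The metadata list.
#' @export
curve_meta <- function(curve) {
  attr(curve, "meta") %||% list()
}

#' @export
print.cyto_curve <- function(x, ...) {
  meta <- curve_meta(x)
  if (length(meta) > 0) {
    shown <- meta[vapply(meta, function(v) is.atomic(v) && length(v) == 1, logical(1))]
    cat(
      "<cyto_curve> ",
      paste(names(shown), unlist(shown), sep = "=", collapse = " | "),
      "\n",
      sep = ""
    )
  }
  NextMethod()
}

# internal: validate a curve used as fitting input
check_curve_columns <- function(curve, cols) {
  missing <- setdiff(cols, names(curve))
  if (length(missing) > 0) {
    abort(paste0("Curve is missing column(s): ", paste(missing, collapse = ", ")),
      class = "cytomech_input_error"
    )
  }
  invisible(TRUE)
}
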