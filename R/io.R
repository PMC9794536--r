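#' Write a curve to a delimited text file
#'
#' Tab-separated values with `#`-prefixed metadata header lines
#' (`# key=value`), the canonical exchange format of this package. Values
#' are written at 12 significant digits so a write-read round trip is
#' lossless at that precision.
#'
#' @param curve A `cyto_curve` (or plain data frame).
#' @param path Output path.
#' @param timestamp Include a `# written=` timestamp line (default
#'   `FALSE`, keeping re-runs byte-identical).
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path, timestamp = FALSE) {
  meta <- curve_meta(curve)
  meta <- meta[vapply(meta, function(v) is.atomic(v) && length(v) == 1 && !is.null(v), logical(1))]
  header <- sprintf("# %s=%s", names(meta), vapply(meta, format, character(1)))
  if (timestamp) header <- c(header, sprintf("# written=%s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
  df <- as_tibble(curve)
  body <- vapply(
    seq_len(nrow(df)),
    function(i) paste(vapply(df[i, ], format, character(1), digits = 12), collapse = "\t"),
    character(1)
  )
  writeLines(c(header, paste(names(df), collapse = "\t"), body), path)
  invisible(path)
}

#' Read a curve from a delimited text file
#'
#' Counterpart of [write_curve()]: `#` lines become metadata, the first
#' non-comment line is the column header. A `t_s` column must be strictly
#' increasing; a violation is reported with its file line number. Files
#' using a decimal comma are detected and rejected with a pointer to the
#' `decimal` argument.
#'
#' @param path Input path.
#' @param decimal Decimal separator, `"."` (default) or `","`.
#' @return A `cyto_curve` tibble.
#' @export
read_curve <- function(path, decimal = ".") {
  lines <- readLines(path)
  is_meta <- startsWith(trimws(lines), "#")
  data_start <- which(!is_meta & nzchar(trimws(lines)))[1]
  if (is.na(data_start)) {
    abort("No data lines found.", class = "cytomech_parse_error")
  }
  meta_lines <- lines[seq_len(data_start - 1)][is_meta[seq_len(data_start - 1)]]
  meta <- list()
  for (ln in meta_lines) {
    kv <- sub("^#\\s*", "", ln)
    if (grepl("=", kv, fixed = TRUE)) {
      key <- sub("=.*", "", kv)
      val <- sub("^[^=]*=", "", kv)
      num <- suppressWarnings(as.numeric(val))
      meta[[key]] <- if (!is.na(num)) num else val
    }
  }
  df <- read.delim(
    text = lines[data_start:length(lines)],
    sep = "\t", dec = decimal, check.names = FALSE
  )
  nonnum <- names(df)[!vapply(df, is.numeric, logical(1))]
  if (length(nonnum) > 0) {
    has_comma <- any(grepl(",", unlist(df[nonnum]), fixed = TRUE))
    if (has_comma && decimal == ".") {
      abort("Column(s) contain decimal commas; re-read with `decimal = \",\"`.",
        class = "cytomech_parse_error"
      )
    }
    abort(paste0("Non-numeric column(s): ", paste(nonnum, collapse = ", ")),
      class = "cytomech_parse_error"
    )
  }
  if ("t_s" %in% names(df) && is.unsorted(df$t_s, strictly = TRUE)) {
    bad <- which(diff(df$t_s) <= 0)[1] + 1L
    abort(
      sprintf(
        "Time column `t_s` is not strictly increasing at data row %d (file line %d).",
        bad, data_start + bad
      ),
      class = "cytomech_parse_error"
    )
  }
  new_curve(as_tibble(df), meta)
}

#' Read or write a material set as YAML
#'
#' Per-role blocks keyed by `E_MPa`, `nu` and optionally `C10_MPa`,
#' `D1_perMPa` (tabulated Neo-Hookean values) and `E_R_MPa`,
#' `tau_sigma_s`, `tau_epsilon_s` (the cytoplasm SLS triplet). Two files
#' mirroring the bundled cell types ship in `inst/extdata/`
#' (`celltype1.yaml`, `celltype2.yaml`).
#'
#' On reading, Neo-Hookean parameters are re-derived from `(E, nu)`; if
#' the file also lists `C10_MPa`/`D1_perMPa` they are checked against the
#' derivation (1% relative, matching 3-significant-figure tabulation) and
#' kept in the `printed` attribute.
#'
#' @param path YAML file path.
#' @param check Validate file-provided Neo-Hookean values against the
#'   `(E, nu)` derivation (default `TRUE`).
#' @return `read_materials()`: a `cell_materials` tibble.
#' @export
read_materials <- function(path, check = TRUE) {
  doc <- yaml::read_yaml(path)
  roles <- doc$materials %||% doc[setdiff(names(doc), "label")]
  df <- purrr::imap(roles, function(block, role) {
    tibble(
      role = role,
      E_MPa = block$E_MPa,
      nu = block$nu,
      E_R_MPa = block$E_R_MPa %||% NA_real_,
      tau_sigma_s = block$tau_sigma_s %||% NA_real_,
      tau_epsilon_s = block$tau_epsilon_s %||% NA_real_,
      C10_file_MPa = block$C10_MPa %||% NA_real_,
      D1_file_perMPa = block$D1_perMPa %||% NA_real_
    )
  }) |> list_rbind()
  printed <- df |> select(all_of(c("role", "C10_file_MPa", "D1_file_perMPa")))
  out <- cell_materials(
    df |> select(-all_of(c("C10_file_MPa", "D1_file_perMPa"))),
    label = doc$label %||% basename(path)
  )
  if (check && any(is.finite(printed$C10_file_MPa))) {
    cmp <- left_join(as_tibble(out), printed, by = "role") |>
      filter(is.finite(.data$C10_file_MPa))
    rel <- pmax(
      abs(cmp$C10_MPa / cmp$C10_file_MPa - 1),
      abs(cmp$D1_perMPa / cmp$D1_file_perMPa - 1)
    )
    if (any(rel > 0.01)) {
      abort(
        sprintf(
          "File Neo-Hookean values disagree with (E, nu) beyond 1%% (worst %.2f%%, role %s).",
          100 * max(rel), cmp$role[which.max(rel)]
        ),
        class = "cytomech_config_error"
      )
    }
  }
  attr(out, "printed") <- printed
  out
}

#' @rdname read_materials
#' @param materials A `cell_materials` tibble.
#' @param include_neohookean Also write the derived `C10_MPa`/`D1_perMPa`.
#' @return `write_materials()`: `path`, invisibly.
#' @export
write_materials <- function(materials, path, include_neohookean = TRUE) {
  stopifnot(inherits(materials, "cell_materials"))
  blocks <- lapply(seq_len(nrow(materials)), function(i) {
    row <- materials[i, ]
    b <- list(E_MPa = row$E_MPa, nu = row$nu)
    if (include_neohookean) {
      b$C10_MPa <- signif(row$C10_MPa, 6)
      b$D1_perMPa <- signif(row$D1_perMPa, 6)
    }
    if (is.finite(row$E_R_MPa)) {
      b$E_R_MPa <- row$E_R_MPa
      b$tau_sigma_s <- row$tau_sigma_s
      b$tau_epsilon_s <- row$tau_epsilon_s
    }
    b
  })
  names(blocks) <- materials$role
  yaml::write_yaml(
    list(label = attr(materials, "label"), materials = blocks),
    path
  )
  invisible(path)
}

#' Write a fit result as JSON
#'
#' @param fit A `cyto_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(
    list(
      model = fit$model_kind,
      parameters = fit$parameters,
      residual_norm = fit$residual_norm,
      n_points = fit$n_points,
      converged = fit$converged
    ),
    path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
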