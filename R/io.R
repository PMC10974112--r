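# File formats: CSV for measurements (rheometer-export friendly), JSON for
# parameter sets. Temperatures carry an explicit _C suffix to avoid Kelvin
# confusion; every writer embeds a reproducibility comment header.

#' Re-exported generics for model summaries
#'
#' See [generics::tidy()] and [generics::glance()].
#' @name rheomelt-generics
#' @importFrom generics tidy
#' @export
generics::tidy

#' @rdname rheomelt-generics
#' @importFrom generics glance
#' @export
generics::glance

repro_header <- function(what, seed = NULL, extra = NULL) {
  parts <- c(sprintf("# rheomelt %s", what),
             if (!is.null(seed)) sprintf("# seed: %s", seed),
             if (!is.null(extra)) paste0("# ", extra))
  paste(parts, collapse = "\n")
}

#' Read viscosity sweeps from CSV
#'
#' Expects a header row with at least `temperature_C`, `rate`,
#' `viscosity`; the full column set written by [write_curves()] also carries
#' `system`, `mode`, `drug_fraction`, `replicate`, `opaque_flag` (missing
#' optional columns are filled with defaults). Rows with non-positive rate
#' or viscosity are rejected with row-numbered messages. Rotational rows
#' above `rotational_cutoff` are flagged (`gap_artifact = TRUE`), not
#' dropped, since gap emptying invalidates those points.
#'
#' @param path Path to a CSV file (comment lines starting with `#` are
#'   skipped).
#' @param rotational_cutoff Maximum trustworthy rotational shear rate, 1/s.
#' @return A tibble of measurement rows.
#' @export
read_curves <- function(path, rotational_cutoff = 10) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  if (nrow(df) == 0) stop("empty curves file: ", path)
  need <- c("temperature_C", "rate", "viscosity")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("curves file missing required column(s): ",
         paste(miss, collapse = ", "))
  for (col in need)
    if (!is.numeric(df[[col]]))
      stop("column `", col, "` is not numeric")
  bad <- which(df$rate <= 0 | df$viscosity <= 0 |
                 !is.finite(df$rate) | !is.finite(df$viscosity))
  if (length(bad) > 0) {
    message("rejecting ", length(bad), " row(s) with non-positive or ",
            "non-finite rate/viscosity: data row(s) ",
            paste(utils::head(bad, 10), collapse = ", "),
            if (length(bad) > 10) ", ..." else "")
    df <- df[-bad, , drop = FALSE]
  }
  if (nrow(df) == 0) stop("no valid measurement rows left in ", path)
  if (!"system" %in% names(df)) df$system <- "unknown"
  if (!"mode" %in% names(df)) df$mode <- "oscillatory"
  if (!"drug_fraction" %in% names(df)) df$drug_fraction <- 0
  if (!"replicate" %in% names(df)) df$replicate <- 1L
  if (!"opaque_flag" %in% names(df)) df$opaque_flag <- FALSE
  df$gap_artifact <- df$mode == "rotational" & df$rate > rotational_cutoff
  tibble::as_tibble(df)
}

#' Write viscosity sweeps to CSV
#'
#' @param curves Tibble of measurement rows.
#' @param path Output path.
#' @param seed Optional seed recorded in the reproducibility header.
#' @return `path`, invisibly.
#' @export
write_curves <- function(curves, path, seed = NULL) {
  check_curve_df(curves)
  writeLines(repro_header("viscosity curves", seed), path)
  readr::write_csv(curves, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' Write a master curve to CSV
#'
#' Columns `reduced_rate`, `reduced_viscosity`, `source_temperature_C`,
#' `shift_factor`, with the reference temperature in the header.
#'
#' @param mc A `master_curve` object from [build_master_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_master_curve <- function(mc, path) {
  stopifnot(inherits(mc, "master_curve"))
  writeLines(repro_header("master curve",
                          extra = sprintf("tref_C: %g", attr(mc, "tref_C"))),
             path)
  cols <- c("reduced_rate", "reduced_viscosity", "source_temperature_C",
            "shift_factor")
  readr::write_csv(as.data.frame(mc)[cols], path, append = TRUE,
                   col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' Read a solubility curve from CSV
#'
#' Expects columns `temperature_C` and `ws_fraction`; validated by
#' [solubility_curve()].
#'
#' @param path Path to a CSV file.
#' @return A `solubility_curve` object.
#' @export
read_solubility_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  solubility_curve(df)
}

#' Write a solubility curve (or extracted solubility table) to CSV
#'
#' @param x Data frame with columns `temperature_C` and `ws_fraction` (or
#'   `w_s`, renamed on write).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_solubility_csv <- function(x, path) {
  stopifnot(is.data.frame(x))
  df <- as.data.frame(x)
  if ("w_s" %in% names(df) && !"ws_fraction" %in% names(df))
    names(df)[names(df) == "w_s"] <- "ws_fraction"
  need <- c("temperature_C", "ws_fraction")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("solubility table missing column(s): ", paste(miss, collapse = ", "))
  writeLines(repro_header("solubility curve"), path)
  readr::write_csv(df[need], path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

params_to_list <- function(p, d = NULL) {
  out <- list(eta0 = p$carreau$eta0, gamma_c = p$carreau$gamma_c,
              c = p$carreau$c, EA = p$arrhenius$EA,
              Tref_C = p$arrhenius$Tref_C)
  if (!is.null(d)) {
    out$s_plast <- d$s_plast
    out$s_filler <- d$s_filler
  }
  out
}

#' Write a parameter set to JSON
#'
#' Serializes a Carreau--Arrhenius parameter set (optionally with drug-shift
#' slopes) to a flat JSON document with fields `eta0`, `gamma_c`, `c`, `EA`,
#' `Tref_C` and, when given, `s_plast`, `s_filler`.
#'
#' @param p A [carreau_arrhenius_params()] object.
#' @param path Output path.
#' @param d Optional [drug_shift_params()] object.
#' @param seed Optional seed recorded in the metadata block.
#' @return `path`, invisibly.
#' @export
write_params_json <- function(p, path, d = NULL, seed = NULL) {
  stopifnot(inherits(p, "carreau_arrhenius_params"))
  if (!is.null(d)) stopifnot(inherits(d, "drug_shift_params"))
  doc <- params_to_list(p, d)
  doc$meta <- list(writer = "rheomelt",
                   seed = if (is.null(seed)) NA else seed)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a parameter set from JSON
#'
#' Validates field presence, types and finiteness before constructing the
#' parameter objects.
#'
#' @param path Path to a JSON document written by [write_params_json()].
#' @return A list with elements `params` ([carreau_arrhenius_params()]) and
#'   `drug` ([drug_shift_params()] or `NULL`).
#' @export
read_params_json <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("eta0", "gamma_c", "c", "EA", "Tref_C")
  miss <- setdiff(need, names(doc))
  if (length(miss) > 0)
    stop("parameter JSON missing field(s): ", paste(miss, collapse = ", "))
  for (f in need) {
    v <- doc[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter field `", f, "` must be a single finite number")
  }
  p <- carreau_arrhenius_params(doc$eta0, doc$gamma_c, doc$c, doc$EA,
                                doc$Tref_C)
  d <- NULL
  if (!is.null(doc$s_plast)) {
    if (!is.numeric(doc$s_plast) || !is.finite(doc$s_plast))
      stop("parameter field `s_plast` must be a finite number")
    d <- drug_shift_params(doc$s_plast,
                           if (is.null(doc$s_filler)) NA_real_
                           else doc$s_filler)
  }
  list(params = p, drug = d)
}
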