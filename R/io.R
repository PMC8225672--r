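#' Read decay traces from delimited text
#'
#' Reads one or many sensitized-emission decay traces from a CSV/TSV file
#' with columns `time_us` and `intensity`; multi-trace files are long-format
#' with an additional `label` column.
#'
#' @param path Path to the file.
#' @param sep Field separator (`","` or `"\t"`).
#' @return A tibble with columns `time_us`, `intensity` and, when present,
#'   `label`.
#' @export
read_decay_traces <- function(path, sep = ",") {
  df <- tibble::as_tibble(utils::read.table(path, header = TRUE, sep = sep,
                                            stringsAsFactors = FALSE))
  if (!all(c("time_us", "intensity") %in% names(df)))
    rlang::abort("Decay trace files need columns `time_us` and `intensity`.")
  df
}

#' Write decay traces to delimited text
#'
#' @param data A decay trace tibble (columns `time_us`, `intensity`,
#'   optionally `label`).
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_decay_traces <- function(data, path, sep = ",") {
  utils::write.table(data, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a Tr-FRET titration table
#'
#' @param path Path to a CSV/TSV with columns `x` (lipid load) and `ratio`
#'   (Tr-FRET ratio), optionally `lipid_label` and `replicate_id`.
#' @param sep Field separator.
#' @return A tibble.
#' @export
read_titration <- function(path, sep = ",") {
  df <- tibble::as_tibble(utils::read.table(path, header = TRUE, sep = sep,
                                            stringsAsFactors = FALSE))
  if (!all(c("x", "ratio") %in% names(df)))
    rlang::abort("Titration files need columns `x` and `ratio`.")
  df
}

#' Read a lipid-residue contact table
#'
#' Long-format export of a coarse-grained trajectory: one row per
#' (frame, lipid, residue), with either minimal distances or precomputed
#' boolean contacts.
#'
#' @param path Path to a CSV/TSV with columns `frame`, `lipid_id`,
#'   `residue_id` and `min_distance_nm` or `contact`; `species` and
#'   `leaflet` are carried through when present.
#' @param sep Field separator.
#' @return A tibble.
#' @export
read_contact_table <- function(path, sep = ",") {
  df <- tibble::as_tibble(utils::read.table(path, header = TRUE, sep = sep,
                                            stringsAsFactors = FALSE))
  check_contact_columns(df)
  df
}

#' Write a decay-fit report to JSON
#'
#' Serializes a [fit_decay()] result - components, molecular fractions under
#' both conventions, and residual diagnostics - to a JSON report that
#' [read_fit_report()] restores losslessly (to the precision of the decimal
#' representation).
#'
#' @param fit A `decay_fit` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "decay_fit"))
  report <- list(
    label = fit$label,
    n_obs = fit$n_obs,
    components = fit$components,
    baseline = fit$baseline,
    fractions_amplitude = molecular_fractions(fit, "amplitude"),
    fractions_lifetime = molecular_fractions(fit, "lifetime"),
    diagnostics = list(reduced_chi_square = fit$reduced_chi_square,
                       residual_runs_p = fit$residual_runs_p,
                       degenerate = fit$degenerate))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Read a decay-fit report written by [write_fit_report()]
#'
#' @param path Path to the JSON report.
#' @return A list mirroring the report structure, with `components` and the
#'   fraction tables as tibbles.
#' @export
read_fit_report <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  rep$components <- tibble::as_tibble(rep$components)
  rep$fractions_amplitude <- tibble::as_tibble(rep$fractions_amplitude)
  rep$fractions_lifetime <- tibble::as_tibble(rep$fractions_lifetime)
  rep
}
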