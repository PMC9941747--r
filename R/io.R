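# JSON / CSV spectrum formats.
#
# The JSON schema is defined by this package (open formats for Raman data
# name no standard schema): each acquisition is an object with keys
# "accumulations" (list of lists), "background" (list or null),
# "exposure_acq_s", "exposure_bg_s", "axis" (optional), "axis_kind",
# "metadata" (object). A bare spectrum is an object with "axis",
# "intensity", "axis_kind", "metadata". Files hold one object or an array.

spectrum_to_json_list <- function(x) {
  if (is_acquisition(x)) {
    list(
      type = "acquisition",
      accumulations = lapply(seq_len(nrow(x$accumulations)),
                             function(i) x$accumulations[i, ]),
      background = x$background,
      exposure_acq_s = x$exposure_acq,
      exposure_bg_s = x$exposure_bg,
      axis = x$axis,
      axis_kind = x$axis_kind,
      metadata = x$metadata
    )
  } else if (is_spectrum(x)) {
    list(
      type = "spectrum",
      axis = x$axis,
      intensity = x$intensity,
      axis_kind = x$axis_kind,
      metadata = x$metadata
    )
  } else {
    rp_value_error("can only serialize raman_spectrum or raman_acquisition")
  }
}

json_list_to_object <- function(obj) {
  require_field <- function(name) {
    if (is.null(obj[[name]]))
      rp_format_error(sprintf("malformed spectrum JSON: missing field '%s'", name))
    obj[[name]]
  }
  axis_kind <- if (is.null(obj$axis_kind)) "pixel" else obj$axis_kind
  metadata <- if (is.null(obj$metadata)) list() else as.list(obj$metadata)
  if (!is.null(obj$accumulations)) {
    acc <- obj$accumulations
    if (is.matrix(acc)) acc <- lapply(seq_len(nrow(acc)), function(i) acc[i, ])
    lens <- lengths(acc)
    if (length(unique(lens)) != 1L)
      rp_dim_error("ragged accumulation rows in JSON input")
    raw_acquisition(
      accumulations = acc,
      background = if (is.null(obj$background)) NULL else as.numeric(obj$background),
      exposure_acq = require_field("exposure_acq_s"),
      exposure_bg = require_field("exposure_bg_s"),
      axis = if (is.null(obj$axis)) NULL else as.numeric(obj$axis),
      axis_kind = axis_kind,
      metadata = metadata
    )
  } else if (!is.null(obj$intensity)) {
    spectrum(
      intensity = as.numeric(obj$intensity),
      axis = if (is.null(obj$axis)) NULL else as.numeric(obj$axis),
      axis_kind = axis_kind,
      metadata = metadata
    )
  } else {
    rp_format_error(
      "malformed spectrum JSON: missing field 'accumulations' or 'intensity'")
  }
}

#' Read spectra or raw acquisitions from disk
#'
#' JSON files follow the package's open acquisition schema (see
#' [write_spectra()]); CSV files are two-column (axis, intensity) with an
#' optional header naming the axis kind (`pixel` or `shift`).
#'
#' @param path Path to an existing file.
#' @param format `"json"` or `"csv"`. Defaults to the file extension.
#' @return A list of [raw_acquisition()] and/or [spectrum()] objects, in
#'   file order.
#' @export
read_spectra <- function(path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) rp_io_error(sprintf("file not found: %s", path))
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  if (format == "json") {
    parsed <- tryCatch(
      jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                         simplifyMatrix = FALSE),
      error = function(e) rp_format_error(sprintf("invalid JSON: %s", conditionMessage(e))))
    if (length(parsed) == 0L) return(list())
    # single object vs array of objects
    objs <- if (!is.null(names(parsed))) list(parsed) else parsed
    lapply(objs, json_list_to_object)
  } else {
    first <- readLines(path, n = 1L)
    has_header <- !grepl("^[-0-9.eE+, \t]+$", first)
    tab <- utils::read.csv(path, header = has_header)
    if (ncol(tab) < 2L)
      rp_format_error("CSV spectrum needs two columns (axis, intensity)")
    axis_kind <- "pixel"
    if (has_header && tolower(names(tab)[1]) %in% c("shift", "raman_shift", "wavenumber"))
      axis_kind <- "shift"
    list(spectrum(intensity = tab[[2]], axis = tab[[1]], axis_kind = axis_kind))
  }
}

#' Write spectra or raw acquisitions to disk
#'
#' Floats are serialized at full precision so `read_spectra(write_spectra(x))`
#' round-trips. JSON holds any mix of spectra and acquisitions; CSV holds a
#' single spectrum as two columns with a header naming the axis kind.
#'
#' @param objects A single object or list of [spectrum()] /
#'   [raw_acquisition()] objects.
#' @param path Output file path.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(objects, path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  if (is_spectrum(objects) || is_acquisition(objects)) objects <- list(objects)
  if (!dir.exists(dirname(path)))
    rp_io_error(sprintf("directory does not exist: %s", dirname(path)))
  if (format == "json") {
    payload <- lapply(objects, spectrum_to_json_list)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = FALSE)
  } else {
    if (length(objects) != 1L || !is_spectrum(objects[[1]]))
      rp_value_error("CSV output holds exactly one spectrum")
    s <- objects[[1]]
    tab <- data.frame(axis = s$axis, intensity = s$intensity)
    names(tab)[1] <- s$axis_kind
    utils::write.csv(format(tab, digits = 17, trim = TRUE, scientific = FALSE),
                     path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
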