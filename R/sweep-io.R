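#' Read a sweep set from a CSV/JSON file pair
#'
#' The on-disk format is a plain CSV of voltages (one `time_ms` column
#' plus one `I_<current>pA` column per sweep) with a JSON sidecar holding
#' the metadata (`cell_id`, `protocol`, `dt_ms`, `step_onset_ms`,
#' `step_offset_ms`, `currents_pA`, `holding_mV`).  `save_sweep_set()`
#' writes voltages with 17 significant digits so that a save/load
#' round-trip reproduces the numeric content exactly.
#'
#' @param path Path to the `.csv` file (or its basename without
#'   extension); the sidecar is the same path with extension `.json`.
#' @return A validated [sweep_set()].
#' @seealso [save_sweep_set()]
#' @export
load_sweep_set <- function(path) {
  csv <- if (grepl("\\.csv$", path)) path else paste0(path, ".csv")
  json <- sub("\\.csv$", ".json", csv)
  if (!file.exists(csv)) cp_stop(paste0("no such file: ", csv), "cp_io_error")
  if (!file.exists(json)) cp_stop(paste0("missing sidecar: ", json),
                                  "cp_io_error")
  meta <- jsonlite::read_json(json, simplifyVector = TRUE)
  need <- c("cell_id", "protocol", "dt_ms", "step_onset_ms",
            "step_offset_ms", "currents_pA", "holding_mV")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    cp_stop(paste0("sidecar missing metadata field(s): ",
                   paste(miss, collapse = ", ")), "cp_format_error")
  tab <- utils::read.csv(csv, check.names = FALSE,
                         colClasses = "numeric")
  if (anyNA(tab))
    cp_stop("ragged or non-numeric cells in sweep CSV", "cp_format_error")
  if (names(tab)[1L] != "time_ms")
    cp_stop("first CSV column must be 'time_ms'", "cp_format_error")
  tms <- tab[[1L]]
  if (length(tms) >= 2L) {
    dts <- diff(tms)
    if (any(dts <= 0) ||
        max(abs(dts - meta$dt_ms)) > 1e-6 * max(meta$dt_ms, 1))
      cp_stop("'time_ms' is not monotonic at the stated dt_ms",
              "cp_format_error")
  }
  cur <- as.numeric(meta$currents_pA)
  if (anyDuplicated(cur))
    cp_stop("duplicate entries in 'currents_pA'", "cp_format_error")
  cols <- paste0("I_", sweep_current_label(cur), "pA")
  miss <- setdiff(cols, names(tab))
  if (length(miss))
    cp_stop(paste0("CSV missing sweep column(s): ",
                   paste(miss, collapse = ", ")), "cp_format_error")
  sweeps <- lapply(seq_along(cur), function(j) {
    sweep_trace(tab[[cols[j]]], dt = meta$dt_ms, i_step = cur[j],
                step_onset = meta$step_onset_ms,
                step_offset = meta$step_offset_ms, t0 = tms[1L])
  })
  sweep_set(cell_id = meta$cell_id, protocol = meta$protocol,
            sweeps = sweeps, holding_v = meta$holding_mV)
}

#' Write a sweep set to a CSV/JSON file pair
#'
#' @param s A [sweep_set()].
#' @param path Destination path (`.csv` appended if absent); the JSON
#'   sidecar is written next to it.
#' @return Invisibly, the CSV path.
#' @export
save_sweep_set <- function(s, path) {
  if (!inherits(s, "cp_sweep_set"))
    cp_stop("'s' must be a cp_sweep_set", "cp_format_error")
  csv <- if (grepl("\\.csv$", path)) path else paste0(path, ".csv")
  json <- sub("\\.csv$", ".json", csv)
  cur <- sweep_currents(s)
  first <- s$sweeps[[1L]]
  meta <- list(cell_id = s$cell_id, protocol = s$protocol,
               dt_ms = first$dt, step_onset_ms = first$step_onset,
               step_offset_ms = first$step_offset,
               currents_pA = cur, holding_mV = s$holding_v)
  header <- paste(c("time_ms",
                    paste0("I_", sweep_current_label(cur), "pA")),
                  collapse = ",")
  num <- cbind(sweep_times(first),
               do.call(cbind, lapply(s$sweeps, `[[`, "v")))
  body <- do.call(paste, c(lapply(seq_len(ncol(num)), function(j)
    sprintf("%.17g", num[, j])), sep = ","))
  con <- tryCatch(file(csv, "w"), error = function(e)
    cp_stop(paste0("cannot write ", csv), "cp_io_error"))
  on.exit(close(con))
  writeLines(c(header, body), con)
  jsonlite::write_json(meta, json, auto_unbox = TRUE, digits = NA)
  invisible(csv)
}

# canonical label for a current value inside a CSV column name
sweep_current_label <- function(i) {
  vapply(i, function(x) {
    if (is.finite(x) && x == round(x)) sprintf("%d", as.integer(x))
    else sprintf("%.17g", x)
  }, character(1))
}
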