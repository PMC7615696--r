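# CSV serialization for simulated and reference traces, with an optional JSON
# metadata sidecar describing the condition and solver settings.

#' Write a hemoglobin trace to CSV
#'
#' Columns \code{t_ms, d_hbo, d_hbr, d_hbt}. If \code{sidecar = TRUE} a JSON
#' file \code{<path>.json} records the protocol and sampling metadata.
#'
#' @param trace a \code{hemo_trace}.
#' @param path output CSV path.
#' @param sidecar write the JSON metadata sidecar?
#' @return \code{path}, invisibly.
#' @export
write_trace <- function(trace, path, sidecar = TRUE) {
  utils::write.csv(as.data.frame(trace)[c("t_ms", "d_hbo", "d_hbr", "d_hbt")],
                   path, row.names = FALSE)
  proto <- attr(trace, "protocol")
  if (isTRUE(sidecar) && !is.null(proto)) {
    meta <- list(condition = proto$kind, lname = proto$lname,
                 t0_ms = proto$t0, duration_ms = proto$duration,
                 npy_width_factor = proto$npy_width_factor,
                 n_samples = nrow(trace),
                 dt_out_ms = if (nrow(trace) > 1) diff(trace$t_ms[1:2]) else NA,
                 solver = "lsoda", rtol = 1e-8, atol = 1e-10)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Read a hemoglobin trace from CSV
#'
#' @param path CSV written by \code{\link{write_trace}} (or any CSV with the
#'   same columns).
#' @return a \code{hemo_trace} data.frame (without the state matrix).
#' @export
read_trace <- function(path) {
  tr <- utils::read.csv(path)
  need <- c("t_ms", "d_hbo", "d_hbr", "d_hbt")
  if (!all(need %in% names(tr))) {
    stop_comparison_error(sprintf("'%s' lacks columns %s", path,
                                  paste(need, collapse = ", ")))
  }
  structure(tr[need], class = c("hemo_trace", "data.frame"))
}

#' Write a synthetic reference trace to CSV
#'
#' @param ref a \code{reference_trace}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_reference <- function(ref, path) {
  utils::write.csv(as.data.frame(ref), path, row.names = FALSE)
  invisible(path)
}

#' Read a reference trace from CSV
#'
#' @param path CSV written by \code{\link{write_reference}}.
#' @return a \code{reference_trace} data.frame.
#' @export
read_reference <- function(path) {
  ref <- utils::read.csv(path)
  need <- c("t_ms", "mean_d_hbo", "mean_d_hbr", "mean_d_hbt",
            "sd_d_hbo", "sd_d_hbr", "sd_d_hbt")
  if (!all(need %in% names(ref))) {
    stop_comparison_error(sprintf("'%s' lacks columns %s", path,
                                  paste(need, collapse = ", ")))
  }
  structure(ref[need], class = c("reference_trace", "data.frame"))
}
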