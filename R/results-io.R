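#' Write an analysis result to a structured JSON file
#'
#' Every result type in the pipeline (ACFs, memory kernels, spectral
#' densities, correlation-time spectra, AR fits, enhancement records,
#' paramagnetic-shift fits) serializes to the same JSON envelope:
#' the payload, the run-configuration echo carried by the object, the
#' package version, and an md5 checksum of the numeric payload so results
#' can be traced to their inputs. Writing the same object twice produces
#' byte-identical files (no timestamps).
#'
#' @param obj a finished result object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_result <- function(obj, path) {
  payload <- result_payload(obj)
  ok <- vapply(payload, is_serializable, logical(1))
  if (any(!ok)) {
    abort(sprintf("field(s) not serializable to JSON: %s",
                  paste(names(payload)[!ok], collapse = ", ")))
  }
  env <- list(
    type = class(obj)[1L],
    package = "odnptraj",
    version = as.character(packageVersion("odnptraj")),
    config = attr(obj, "config", exact = TRUE),
    checksum = payload_checksum(payload),
    payload = payload
  )
  jsonlite::write_json(env, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_result
#' @export
read_result <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

is_serializable <- function(x) {
  is.null(x) || is.atomic(x) || is.data.frame(x) ||
    (is.list(x) && all(vapply(x, is_serializable, logical(1))))
}

payload_checksum <- function(payload) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  jsonlite::write_json(payload, tmp, auto_unbox = TRUE, digits = NA, na = "null")
  unname(tools::md5sum(tmp))
}

result_payload <- function(obj) UseMethod("result_payload")

#' @export
result_payload.default <- function(obj) {
  if (is.data.frame(obj)) {
    out <- list(data = as.data.frame(obj))
    for (a in setdiff(names(attributes(obj)),
                      c("names", "row.names", "class", "config"))) {
      val <- attr(obj, a, exact = TRUE)
      if (is_serializable(val)) out[[a]] <- val
    }
    return(out)
  }
  if (is.list(obj)) return(unclass(obj))
  list(value = obj)
}
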