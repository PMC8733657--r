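#' Read a flat key=value configuration file
#'
#' Parses the plain-text parameter dialect used for all bundled model
#' inputs: one `key=value` pair per line, `#` starts a comment, blank
#' lines ignored.  Values are returned as character strings; use
#' [config_num()] for numeric retrieval with validation.
#'
#' @param path Path to the configuration file.
#' @return Named character vector of raw values.
#' @seealso [write_config()], [load_species_physiology()]
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    stop("configuration file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  bad <- !grepl("=", lines, fixed = TRUE)
  if (any(bad)) {
    stop("malformed configuration line (no '='): ", lines[which(bad)[1L]],
         call. = FALSE)
  }
  keys <- trimws(sub("=.*$", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  if (anyDuplicated(keys)) {
    stop("duplicated configuration key: ", keys[anyDuplicated(keys)],
         call. = FALSE)
  }
  stats::setNames(vals, keys)
}

#' Write a flat key=value configuration file
#'
#' @param config Named vector or list of scalar values.
#' @param path Output path.
#' @param header Optional comment line(s) written at the top.
#' @return Invisibly, `path`.
#' @export
write_config <- function(config, path, header = NULL) {
  config <- unlist(config)
  lines <- paste0(names(config), "=",
                  vapply(config, format_value, character(1)))
  if (!is.null(header)) lines <- c(paste0("# ", header), lines)
  writeLines(lines, path)
  invisible(path)
}

format_value <- function(x) {
  if (is.numeric(x)) format(x, digits = 15, scientific = FALSE) else as.character(x)
}

#' @rdname read_config
#' @param config Named character vector as returned by [read_config()].
#' @param key Key to retrieve.
#' @param positive Require the value to be strictly positive.
#' @export
config_num <- function(config, key, positive = FALSE) {
  if (!key %in% names(config)) {
    stop("missing configuration key: ", key, call. = FALSE)
  }
  x <- suppressWarnings(as.numeric(config[[key]]))
  if (is.na(x)) {
    stop("configuration key '", key, "' is not numeric: ", config[[key]],
         call. = FALSE)
  }
  if (positive && x <= 0) {
    stop("configuration key '", key, "' must be > 0, got ", x, call. = FALSE)
  }
  x
}

cefapbpk_extdata <- function(file) {
  path <- system.file("extdata", file, package = "cefapbpk")
  if (!nzchar(path)) stop("bundled file not found: ", file, call. = FALSE)
  path
}
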