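#' Packaged benchmark lifetime datasets
#'
#' Four classical positive-valued datasets shipped with the package as
#' plain-text fixtures:
#' \describe{
#'   \item{`milk`}{Total milk production proportions from the first birth
#'     of 107 cows of the SINDI race (n = 107).}
#'   \item{`bladder`}{Remission times in months of 128 bladder-cancer
#'     patients (n = 128).}
#'   \item{`fiber_x`}{Strengths of single carbon fibers tested under
#'     tension at 10 mm gauge length (n = 63); the strength sample of the
#'     stress-strength application.}
#'   \item{`fiber_y`}{Strengths of impregnated 1000-fiber tows at 20 mm
#'     gauge length (m = 69); the stress sample.}
#' }
#' Lengths are validated at load time; a mismatch indicates a packaging
#' bug, not user error.
#'
#' @param name One of `"milk"`, `"bladder"`, `"fiber_x"`, `"fiber_y"`.
#' @return A numeric vector with attributes `name` and `n`.
#' @examples
#' length(esg_dataset("milk"))
#' @export
esg_dataset <- function(name) {
  expected <- c(milk = 107L, bladder = 128L, fiber_x = 63L, fiber_y = 69L)
  if (!is.character(name) || length(name) != 1L || !name %in% names(expected)) {
    stop("unknown dataset; available: ",
         paste(names(expected), collapse = ", "), call. = FALSE)
  }
  path <- system.file("extdata", paste0(name, ".csv"), package = "esgfam",
                      mustWork = TRUE)
  v <- read_lifetimes(path)
  if (length(v) != expected[[name]]) {
    stop("packaging bug: dataset '", name, "' has ", length(v),
         " values, expected ", expected[[name]], call. = FALSE)
  }
  structure(v, name = name, n = length(v))
}

#' Read a univariate lifetime sample from a text file
#'
#' Accepts one value per line, a single-column CSV with an optional header
#' line, or comma-separated value lists; blank lines are skipped.
#'
#' @param path Path to the file.
#' @return Numeric vector of values.
#' @export
read_lifetimes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(numeric(0))
  tokens <- unlist(strsplit(lines, "[,;[:space:]]+"))
  tokens <- tokens[nzchar(tokens)]
  v <- suppressWarnings(as.numeric(tokens))
  if (is.na(v[1]) && length(v) > 1) {  # header token
    tokens <- tokens[-1]
    v <- suppressWarnings(as.numeric(tokens))
  }
  if (anyNA(v)) {
    bad <- which(is.na(v))[1]
    stop("could not parse value ", bad, " ('", tokens[bad], "') in ", path,
         call. = FALSE)
  }
  v
}
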