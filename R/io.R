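#' Read a univariate positive series from disk
#'
#' Accepts one-column CSV or whitespace-delimited text of positive
#' decimals. Blank lines are ignored; a single leading non-numeric line is
#' treated as a header. Non-numeric tokens and nonpositive values are
#' rejected with the offending line number.
#'
#' @param path path to a text file.
#' @return numeric vector of positive values.
#' @export
read_series <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  vals <- numeric(0)
  first_data_line <- TRUE
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    tokens <- strsplit(ln, "[,[:space:]]+")[[1]]
    tokens <- tokens[nzchar(tokens)]
    v <- suppressWarnings(as.numeric(tokens))
    if (anyNA(v)) {
      if (first_data_line) { # header line
        first_data_line <- FALSE
        next
      }
      stop(sprintf("non-numeric token on line %d of %s", i, path),
           call. = FALSE)
    }
    first_data_line <- FALSE
    if (any(v <= 0)) {
      stop(sprintf("nonpositive value on line %d of %s", i, path),
           call. = FALSE)
    }
    vals <- c(vals, v)
  }
  if (!length(vals)) {
    stop(sprintf("no numeric data found in %s", path), call. = FALSE)
  }
  vals
}

#' Bundled daily PM2.5 series
#'
#' The package ships two daily PM2.5 concentration series (micrograms per
#' cubic metre), recorded January 1 to June 30, 2023 by Thailand's
#' Pollution Control Department: `"maehongson"` (Mae Hong Son province) and
#' `"lampang"` (Lampang province), 181 values each. The Lampang series is
#' transcribed verbatim from the published record, including the adjacent
#' pair `16.91, 8.2` whose abrupt drop amid otherwise smooth values may be
#' a typesetting artifact in the source.
#'
#' @param name `"maehongson"` or `"lampang"`.
#' @return numeric vector of 181 positive values.
#' @examples
#' x <- bs_dataset("maehongson")
#' length(x)
#' @export
bs_dataset <- function(name = c("maehongson", "lampang")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"), package = "bsperc",
                      mustWork = TRUE)
  read_series(path)
}

#' Write results to CSV
#'
#' Converts an interval, simulation result or AIC table to a data frame and
#' writes it as CSV. Stochastic results carry their seed and draw counts in
#' the output so every run is reproducible from the file alone.
#'
#' @param x a `"bs_interval"`, `"bs_sim_result"`, `"bs_aic_table"` or plain
#'   data frame.
#' @param file output path.
#' @return the written data frame, invisibly.
#' @export
write_report <- function(x, file) {
  df <- if (inherits(x, "bs_interval")) as.data.frame(x) else
    as.data.frame(x)
  ok <- tryCatch({
    utils::write.csv(df, file, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop(sprintf("cannot write to %s", file), call. = FALSE)
  invisible(df)
}
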