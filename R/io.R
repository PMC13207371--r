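#' Read an experiment set from CSV
#'
#' Strictly typed reader for confluency time-series files. Required columns:
#' `cell_line`, `u0`, `time`, `confluency`, `replicate` (header mandatory,
#' comma separator, `.` decimal). Times are sorted within each
#' (cell line, u0, replicate) series; confluency must lie in `(0, 1.05]`,
#' values above 1 are clipped to 1 with a warning.
#'
#' @param path Path to a CSV file.
#' @return A data frame with the five required columns.
#' @export
read_timeseries_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("cell_line", "u0", "time", "confluency", "replicate")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  for (col in c("u0", "time", "confluency")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (any(is.na(v) & !is.na(df[[col]])) || any(is.na(v)))
      stop("non-numeric entries in column '", col, "'", call. = FALSE)
    df[[col]] <- v
  }
  if (nrow(df) == 0) stop("empty series", call. = FALSE)
  if (any(df$confluency <= 0) || any(df$confluency > 1.05))
    stop("confluency must lie in (0, 1.05]", call. = FALSE)
  over <- df$confluency > 1
  if (any(over)) {
    warning(sum(over), " confluency value(s) > 1 clipped to 1")
    df$confluency[over] <- 1
  }
  df <- df[order(df$cell_line, df$u0, df$replicate, df$time), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write an experiment set to CSV
#'
#' Companion writer to [read_timeseries_csv()]: numeric values are written as
#' decimal text with 12 significant digits, so a write-read round trip
#' preserves values.
#'
#' @param x Data frame with the experiment-set columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timeseries_csv <- function(x, path) {
  stopifnot(is.data.frame(x))
  y <- x
  for (col in names(y)) {
    if (is.numeric(y[[col]])) y[[col]] <- formatC(y[[col]], digits = 12,
                                                  format = "g")
  }
  utils::write.csv(y, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write fit results to JSON
#'
#' @param fits A single [fit_growth_law()] result or a list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_results_json <- function(fits, path) {
  if (inherits(fits, "fit_result")) fits <- list(fits)
  payload <- lapply(fits, function(f) {
    list(law = f$law,
         estimates = as.list(f$estimates),
         delta = f$delta,
         rss = f$rss, n_obs = f$n_obs, k = f$k,
         aic = as.numeric(f$aic), converged = f$converged)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a run configuration from YAML or JSON
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}
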