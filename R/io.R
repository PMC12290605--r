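#' Read a multivariate time series from TSV
#'
#' Expects a tab-separated file with a header row \code{time} followed
#' by node columns, or a headerless numeric matrix (then \code{TR} must
#' be supplied). Index locations are mapped onto \code{[0, 1]}.
#'
#' @param path file path.
#' @param TR repetition time in seconds; inferred from the \code{time}
#'   column when present.
#' @param normalize z-score columns on read (default FALSE).
#' @return a [TimeSeriesData-class].
#' @export
loadTimeSeries <- function(path, TR = NULL, normalize = FALSE) {
  first <- readLines(path, n = 1)
  has_header <- grepl("^time\t", first)
  df <- read.delim(path, header = has_header, sep = "\t",
                   check.names = FALSE)
  if (has_header) {
    tcol <- df[["time"]]
    if (!is.numeric(tcol)) stop("non-numeric 'time' column")
    if (any(diff(tcol) <= 0)) {
      bad <- which(diff(tcol) <= 0)[1] + 1
      stop("non-monotone time at row ", bad)
    }
    if (is.null(TR)) TR <- if (length(tcol) > 1) diff(tcol)[1] else 1
    Y <- as.matrix(df[, setdiff(names(df), "time"), drop = FALSE])
  } else {
    if (is.null(TR)) stop("TR must be supplied for headerless input")
    Y <- as.matrix(df)
  }
  if (!is.numeric(Y)) {
    bad <- which(!apply(Y, 1, function(r) all(!is.na(suppressWarnings(
      as.numeric(r))))))
    stop("non-numeric cell(s) at row(s) ",
         paste(head(bad, 5), collapse = ", "))
  }
  if (anyNA(Y)) stop("missing values in time series")
  dimnames(Y) <- NULL
  if (normalize) {
    Y <- scale(Y)
    attr(Y, "scaled:center") <- NULL
    attr(Y, "scaled:scale") <- NULL
  }
  newTimeSeriesData(Y, TR = TR)
}

#' Write a time series to TSV
#'
#' Header \code{time} plus \code{node_1..node_D}; one row per volume;
#' floats at 17 significant digits so a read round-trips bit-identically.
#'
#' @param data a [TimeSeriesData-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeTimeSeries <- function(data, path) {
  stopifnot(is(data, "TimeSeriesData"))
  Y <- observations(data)
  D <- ncol(Y)
  tm <- (seq_len(nrow(Y)) - 1) * repetitionTime(data)
  df <- data.frame(time = format(tm, digits = 17, trim = TRUE),
                   apply(Y, 2, function(col)
                     formatC(col, digits = 17, format = "g")))
  names(df) <- c("time", paste0("node_", seq_len(D)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a covariance trajectory as long-format TSV
#'
#' Columns \code{n, i, j, value}, one row per (time step, element),
#' upper triangle included for symmetry on read.
#'
#' @param traj a [CovTrajectory-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeTrajectory <- function(traj, path) {
  stopifnot(is(traj, "CovTrajectory"))
  D <- nNodes(traj); N <- nTimepoints(traj)
  idx <- expand.grid(i = seq_len(D), j = seq_len(D))
  rows <- do.call(rbind, lapply(seq_len(N), function(n)
    data.frame(n = n, i = idx$i, j = idx$j,
               value = formatC(traj@sigmas[cbind(idx$i, idx$j, n)],
                               digits = 17, format = "g"))))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a long-format trajectory TSV
#'
#' @param path file path (columns \code{n, i, j, value}).
#' @return a [CovTrajectory-class].
#' @export
readTrajectory <- function(path) {
  df <- read.delim(path, sep = "\t")
  stopifnot(all(c("n", "i", "j", "value") %in% names(df)))
  N <- max(df$n); D <- max(df$i)
  sig <- array(NA_real_, dim = c(D, D, N))
  sig[cbind(df$i, df$j, df$n)] <- df$value
  sig[is.na(sig)] <- 0
  newCovTrajectory(sig, validate = FALSE)
}

#' Write a JSON metadata sidecar
#'
#' Records the resolved configuration (kind, seed, snr, TR, ...) and the
#' package version next to any emitted output.
#'
#' @param meta named list.
#' @param path output path (conventionally \code{*.json}).
#' @return the path, invisibly.
#' @export
writeSidecar <- function(meta, path) {
  meta$package_version <- as.character(packageVersion("tvfc"))
  jsonlite::write_json(meta, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
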