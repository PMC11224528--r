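## TRC-style marker files and STO/MOT-style time-series files (tab
## separated, plain text).

#' Write a marker stream as a TRC-style file
#'
#' @param markers Marker stream (`time`, `rate`, `data`; optional `pulse`
#'   written as an extra single-coordinate column set).
#' @param path Output path.
#' @export
write_trc <- function(markers, path) {
  nm <- names(markers$data)
  n <- length(markers$time)
  rate <- markers$rate %||% 100
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("PathFileType\t4\t(X/Y/Z)\t", basename(path)),
    "DataRate\tCameraRate\tNumFrames\tNumMarkers\tUnits\tOrigDataRate\tOrigDataStartFrame\tOrigNumFrames",
    paste(rate, rate, n, length(nm), "m", rate, 1, n, sep = "\t"),
    paste0("Frame#\tTime\t", paste(nm, collapse = "\t\t\t")),
    paste0("\t\t", paste(unlist(lapply(seq_along(nm), function(i)
      paste0(c("X", "Y", "Z"), i))), collapse = "\t"))
  ), con)
  M <- do.call(cbind, markers$data)
  for (i in seq_len(n)) {
    writeLines(paste(c(i, format(markers$time[i], nsmall = 5),
                       format(M[i, ], digits = 10)), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a TRC-style marker file written by [write_trc()]
#' @param path File path.
#' @return Marker stream list (`time`, `rate`, `data`).
#' @export
read_trc <- function(path) {
  hdr <- readLines(path, n = 5)
  meta <- strsplit(hdr[3], "\t")[[1]]
  rate <- as.numeric(meta[1])
  names_row <- strsplit(hdr[4], "\t")[[1]]
  nm <- names_row[names_row != ""][-(1:2)]
  dat <- utils::read.table(path, skip = 5, sep = "\t", header = FALSE)
  time <- dat[[2]]
  out <- list()
  for (i in seq_along(nm)) {
    out[[nm[i]]] <- as.matrix(dat[, (3 * i):(3 * i + 2)])
    dimnames(out[[nm[i]]]) <- NULL
  }
  list(time = time, rate = rate, data = out)
}

#' Write a data frame as an STO/MOT-style time-series file
#'
#' @param df Data frame whose first column is `time`.
#' @param path Output path.
#' @param name Header name field.
#' @export
write_sto <- function(df, path, name = basename(path)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(name,
               paste0("nRows=", nrow(df)),
               paste0("nColumns=", ncol(df)),
               "endheader",
               paste(names(df), collapse = "\t")), con)
  utils::write.table(format(df, digits = 10), con, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an STO/MOT-style file written by [write_sto()]
#' @param path File path.
#' @return Data frame.
#' @export
read_sto <- function(path) {
  lines <- readLines(path, n = 20)
  end <- which(lines == "endheader")[1]
  utils::read.table(path, skip = end, header = TRUE, sep = "\t")
}
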