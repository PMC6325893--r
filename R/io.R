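#' Read a cell-size frequency table
#'
#' Two plain-text layouts are supported, with tab or comma separation
#' inferred from the file extension (`.csv` means comma, anything else tab):
#'
#' * `wide`: first column is the size in fL, every remaining column one
#'   strain's frequencies; the header row carries the strain ids. Replicate
#'   suffixes appended to systematic names (e.g. `YPR086W.1`) are preserved
#'   verbatim.
#' * `long`: three columns `strain`, `size_fl`, `frequency`.
#'
#' @param path File path.
#' @param layout `"wide"` or `"long"`.
#' @param condition Optional condition label attached to every histogram.
#' @return Named list of [size_histogram()] objects, bins sorted ascending.
#' @export
read_frequency_table <- function(path, layout = c("wide", "long"),
                                 condition = NA_character_) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           comment.char = "", quote = "\"")
  if (layout == "wide") {
    if (ncol(raw) < 2) stop("wide layout needs a size column plus >= 1 strain")
    sizes <- parse_numeric_col(raw[[1]], colnames(raw)[1])
    out <- list()
    for (j in seq(2, ncol(raw))) {
      id <- colnames(raw)[j]
      fr <- parse_numeric_col(raw[[j]], id)
      if (anyDuplicated(sizes))
        stop("duplicate bin value within strain '", id, "'")
      if (!any(fr > 0))
        stop("all-zero frequency column for strain '", id, "'")
      o <- order(sizes)
      out[[id]] <- size_histogram(sizes[o], fr[o], strain_id = id,
                                  condition = condition)
    }
    out
  } else {
    need <- c("strain", "size_fl", "frequency")
    if (!all(need %in% colnames(raw)))
      stop("long layout needs columns: ", paste(need, collapse = ", "))
    sizes <- parse_numeric_col(raw$size_fl, "size_fl")
    freqs <- parse_numeric_col(raw$frequency, "frequency")
    out <- list()
    for (id in unique(raw$strain)) {
      k <- raw$strain == id
      s <- sizes[k]; f <- freqs[k]
      if (anyDuplicated(s))
        stop("duplicate bin value within strain '", id, "'")
      if (!any(f > 0))
        stop("all-zero frequency column for strain '", id, "'")
      o <- order(s)
      out[[id]] <- size_histogram(s[o], f[o], strain_id = id,
                                  condition = condition)
    }
    out
  }
}

parse_numeric_col <- function(x, colname) {
  v <- suppressWarnings(as.numeric(x))
  if (anyNA(v)) {
    row <- which(is.na(v))[1]
    stop(sprintf("non-numeric value '%s' at row %d, column '%s'",
                 x[row], row, colname))
  }
  v
}

#' Write histograms to a frequency table
#'
#' Inverse of [read_frequency_table()]. The wide layout requires all
#' histograms to share one bin grid.
#'
#' @param hists List of [size_histogram()] objects.
#' @param path Output path (`.csv` writes comma-separated, else tab).
#' @param layout `"wide"` or `"long"`.
#' @export
write_frequency_table <- function(hists, path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  if (inherits(hists, "size_histogram")) hists <- list(hists)
  if (length(hists) == 0) stop("no histograms to write")
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  if (layout == "wide") {
    b <- hists[[1]]$bin_values
    for (h in hists)
      if (!isTRUE(all.equal(h$bin_values, b, tolerance = 0)))
        stop("wide layout requires a shared bin grid across strains")
    df <- data.frame(size_fl = full_precision(b), check.names = FALSE)
    for (h in hists) df[[h$strain_id]] <- full_precision(h$frequencies)
  } else {
    df <- do.call(rbind, lapply(hists, function(h)
      data.frame(strain = h$strain_id,
                 size_fl = full_precision(h$bin_values),
                 frequency = full_precision(h$frequencies))))
  }
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

## shortest decimal string that round-trips the double exactly
full_precision <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    for (d in 1:17) {
      s <- sprintf("%.*g", d, v)
      if (as.numeric(s) == v) return(s)
    }
    sprintf("%.17g", v)
  }, character(1))
}

## fixed, documented column order of the screening table
screen_columns <- c(
  "strain", "condition", "n", "seed", "status", "sw_p", "sw_log_p",
  "gamma_shape", "gamma_rate", "lognormal_ad", "weibull_ad", "gamma_ad",
  "gamma_ks", "gamma_cvm", "gamma_ad_p", "fixed_null_ad", "fixed_null_p",
  "bic_gamma", "bic_gengamma", "median_fl", "size_class", "deviant_rank")

#' Write a screening table
#'
#' Tab-separated with the fixed column order documented in
#' [screen_cohort()]; floating-point values are written at full
#' (round-tripping) precision so a read-back reproduces every value.
#'
#' @param rows Data frame of screening rows (one per strain).
#' @param path Output path.
#' @export
write_screen_table <- function(rows, path) {
  if (!is.data.frame(rows) || nrow(rows) == 0)
    stop("rows must be a nonempty data frame")
  cols <- intersect(screen_columns, colnames(rows))
  rows <- rows[, c(cols, setdiff(colnames(rows), cols)), drop = FALSE]
  out <- rows
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- full_precision(out[[j]])
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open '", path, "' for writing: ", conditionMessage(e)))
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read back a screening table written by [write_screen_table()]
#' @param path File path.
#' @return Data frame.
#' @export
read_screen_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    quote = "", comment.char = "",
                    stringsAsFactors = FALSE)
}
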