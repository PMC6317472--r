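# Spot-level signal reduction. Raw microarray quantification arrives as one
# row per spot with a median foreground and mean local background; reduction
# subtracts the background, averages replicate spots within each array, then
# averages across replicate arrays. Negative net signals are kept by default
# (background subtraction can legitimately undershoot); clamping is opt-in.

#' Read a spot-level quantification table from TSV
#'
#' Expected columns: `array_id`, `protein`, `lectin`, `condition`,
#' `median_signal`, `mean_background`; optional `slide_id`, `spot_id`.
#'
#' @param path TSV file path.
#' @return A data frame of spot records.
#' @export
read_spot_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("array_id", "protein", "lectin", "condition",
            "median_signal", "mean_background")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("spot table lacks column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  df
}

#' Reduce spot records to observed response vectors
#'
#' Per spot, the net signal is `median_signal - mean_background`; replicate
#' spots are averaged within each array, and the array means are averaged
#' across replicate arrays. Channels are ordered to match the panel.
#'
#' @param records Spot-record data frame (see [read_spot_table()]).
#' @param panel A `gmap_panel` fixing the channel order. Every
#'   (protein, lectin, condition) channel must have at least one record.
#' @param clamp_negative Floor negative net signals at zero before averaging.
#' @return A named list of `observed_vector`s, one per protein (raw
#'   fluorescence units, not yet normalized).
#' @export
reduce_spot_table <- function(records, panel, clamp_negative = FALSE) {
  stopifnot(inherits(panel, "gmap_panel"))
  need <- c("array_id", "protein", "lectin", "condition",
            "median_signal", "mean_background")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop(sprintf("spot records lack column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  net <- records$median_signal - records$mean_background
  if (clamp_negative) net <- pmax(net, 0)
  records$net <- net
  out <- list()
  for (prot in sort(unique(records$protein))) {
    rec <- records[records$protein == prot, , drop = FALSE]
    vals <- numeric(nrow(panel$channels))
    gaps <- character(0)
    for (i in seq_len(nrow(panel$channels))) {
      sel <- rec$lectin == panel$channels$lectin[i] &
             rec$condition == panel$channels$condition[i]
      if (!any(sel)) {
        gaps <- c(gaps, paste(panel$channels$lectin[i],
                              panel$channels$condition[i], sep = " x "))
        next
      }
      per_array <- tapply(rec$net[sel], rec$array_id[sel], mean)
      vals[i] <- mean(per_array)
    }
    if (length(gaps)) {
      stop(sprintf("protein '%s' has no spots for channel(s): %s",
                   prot, paste(gaps, collapse = "; ")), call. = FALSE)
    }
    out[[prot]] <- observed_vector(vals, panel)
  }
  out
}

#' Map a GenePix-style results table onto spot records
#'
#' Minimal column-mapping convenience for GPR-like exports already read into
#' a data frame: renames a foreground-median and background-mean column pair
#' and attaches the experiment annotation columns.
#'
#' @param df Data frame of one scanner block.
#' @param median_col,background_col Source column names (GenePix defaults
#'   `"F635 Median"` / `"B635 Mean"`).
#' @param annotation Data frame or list with `array_id`, `protein`, `lectin`,
#'   `condition` (recycled across rows).
#' @return A spot-record data frame for [reduce_spot_table()].
#' @export
map_gpr_columns <- function(df, median_col = "F635 Median",
                            background_col = "B635 Mean", annotation) {
  if (!all(c(median_col, background_col) %in% names(df))) {
    stop("median/background columns not found in data frame", call. = FALSE)
  }
  out <- data.frame(median_signal = as.numeric(df[[median_col]]),
                    mean_background = as.numeric(df[[background_col]]),
                    stringsAsFactors = FALSE)
  for (nm in c("array_id", "protein", "lectin", "condition")) {
    if (is.null(annotation[[nm]])) {
      stop(sprintf("annotation lacks '%s'", nm), call. = FALSE)
    }
    out[[nm]] <- annotation[[nm]]
  }
  out
}
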