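#' Detect non-wear time from raw-signal window variability
#'
#' The recording is divided into consecutive blocks (default 15 min, aligned
#' to midnight). Each block is flagged non-wear when the raw acceleration
#' signal in the longer window centred on the block (default 60 min) shows
#' both a standard deviation below `sd_thresh_mg` and a range below
#' `range_thresh_mg`; the flag is then broadcast to the block's member epochs.
#'
#' Raw signal variability enters as per-epoch summaries rather than raw
#' waveforms: the window standard deviation is the root-mean-square of the
#' member epochs' `raw_sd_mg` values (pooled within-epoch variability,
#' treating between-epoch mean drift as negligible at 10 s epochs) and the
#' window range is the maximum of the member epochs' `raw_range_mg`.
#'
#' With tri-axial summary columns (`raw_sd_x_mg`, `raw_sd_y_mg`,
#' `raw_sd_z_mg` and matching `raw_range_*_mg`), a block is non-wear when at
#' least two of the three axes satisfy the rule; with the single-column form
#' the one provided summary decides. Windows are clipped at the edges of the
#' recording and only evaluated when at least `min_window_min` minutes of
#' signal remain; blocks without an evaluable window stay worn. Without any
#' raw summary columns, all epochs are marked worn with a warning
#' (counts-only mode).
#'
#' @param epochs tibble with `time` plus raw summary columns as above
#' @param block_min block length in minutes
#' @param window_min evaluation window length in minutes, centred on each block
#' @param sd_thresh_mg,range_thresh_mg non-wear thresholds in milli-gravity
#' @param min_window_min minimum clipped-window coverage to evaluate a block
#' @param epoch_len_s epoch length in seconds (inferred by default)
#' @return `epochs` with a logical `wear` column
#' @export
detect_nonwear <- function(epochs, block_min = 15, window_min = 60,
                           sd_thresh_mg = 13, range_thresh_mg = 50,
                           min_window_min = 30,
                           epoch_len_s = infer_epoch_len(epochs$time)) {
  stopifnot("time" %in% names(epochs))
  triax <- all(c("raw_sd_x_mg", "raw_sd_y_mg", "raw_sd_z_mg",
                 "raw_range_x_mg", "raw_range_y_mg", "raw_range_z_mg") %in% names(epochs))
  uniax <- all(c("raw_sd_mg", "raw_range_mg") %in% names(epochs))
  if (!triax && !uniax) {
    warn("no raw-signal summary columns; marking all epochs as worn (counts-only mode)")
    epochs$wear <- TRUE
    return(epochs)
  }
  axes <- if (triax) {
    list(c("raw_sd_x_mg", "raw_range_x_mg"),
         c("raw_sd_y_mg", "raw_range_y_mg"),
         c("raw_sd_z_mg", "raw_range_z_mg"))
  } else {
    list(c("raw_sd_mg", "raw_range_mg"))
  }
  need_axes <- if (triax) 2L else 1L

  t_num <- as.numeric(epochs$time)
  ord <- order(t_num)
  t_sorted <- t_num[ord]
  block_s <- block_min * 60
  half_w <- window_min * 60 / 2
  block_id <- floor(t_num / block_s)
  wear <- rep(TRUE, nrow(epochs))

  for (b in unique(block_id)) {
    center <- b * block_s + block_s / 2
    # window membership is [center - half_w, center + half_w)
    lo <- findInterval(center - half_w, t_sorted, left.open = TRUE) + 1L
    hi <- findInterval(center + half_w, t_sorted, left.open = TRUE)
    if (hi < lo) next
    idx <- ord[lo:hi]
    if (length(idx) * epoch_len_s < min_window_min * 60) next
    n_low <- 0L
    for (ax in axes) {
      sds <- epochs[[ax[1]]][idx]
      rngs <- epochs[[ax[2]]][idx]
      if (anyNA(sds) || anyNA(rngs)) next
      win_sd <- sqrt(mean(sds^2))
      win_range <- max(rngs)
      if (win_sd < sd_thresh_mg && win_range < range_thresh_mg) n_low <- n_low + 1L
    }
    if (n_low >= need_axes) wear[block_id == b] <- FALSE
  }
  epochs$wear <- wear
  epochs
}
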