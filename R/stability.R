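#' Divergence of each mesocosm from its pre-disturbance baseline
#'
#' For every mesocosm and sampled week, the Bray-Curtis similarity
#' (1 - dissimilarity) of that week's community to the SAME mesocosm's
#' baseline-week sample. Comparisons are within-mesocosm, so replicate
#' identity is never crossed. Mesocosms missing their baseline sample are
#' excluded with a warning.
#'
#' @param m Count matrix (samples x OTUs), typically an [active_table()];
#'   a Total (DNA) matrix can be passed instead to work on the Total
#'   community.
#' @param metadata Sample metadata covering the rows of `m`.
#' @param baseline_week Reference week, default 4 (end of acclimation).
#' @return data.frame of class `divergence_series`: `mesocosm_id`,
#'   `treatment`, `week`, `similarity`.
#' @export
divergence_series <- function(m, metadata, baseline_week = 4L) {
  metadata <- validate_metadata(metadata)
  metadata <- metadata[metadata$sample_id %in% rownames(m), , drop = FALSE]
  out <- list()
  for (meso in unique(metadata$mesocosm_id)) {
    sub <- metadata[metadata$mesocosm_id == meso, , drop = FALSE]
    base_id <- sub$sample_id[sub$week == baseline_week]
    if (length(base_id) == 0L) {
      warning("mesocosm ", meso, " has no week-", baseline_week,
              " baseline sample; excluded")
      next
    }
    base <- m[base_id[1], ]
    out[[meso]] <- data.frame(
      mesocosm_id = meso,
      treatment = sub$treatment,
      week = sub$week,
      similarity = vapply(sub$sample_id,
                          function(s) 1 - bray_curtis(m[s, ], base),
                          numeric(1)),
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  if (length(out) == 0L) stop("no mesocosm has a baseline sample")
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  res <- res[order(res$mesocosm_id, res$week), ]
  rownames(res) <- NULL
  class(res) <- c("divergence_series", "data.frame")
  res
}

#' Resistance index of community structure
#'
#' `RS = 1 - 2|y_c - y_d| / (y_c + |y_c - y_d|)`, where `y_c` is the mean
#' Bray-Curtis similarity of control replicates to the pre-disturbance
#' baseline at the focal week and `y_d` is the disturbed mesocosm's
#' similarity to its own baseline at that week. RS is unitless with
#' theoretical range -1 to 1; RS = 1 means the disturbed community is
#' displaced from baseline no more than the controls are.
#'
#' @param y_c Mean control similarity in \[0, 1\].
#' @param y_d Disturbed similarity in \[0, 1\].
#' @return RS in \[-1, 1\]; `NA` when `y_c` and the displacement are both
#'   zero (the index is undefined, never silently clamped).
#' @export
resistance_index <- function(y_c, y_d) {
  disp <- abs(y_c - y_d)
  denom <- y_c + disp
  ifelse(denom == 0, NA_real_, 1 - 2 * disp / denom)
}

#' Resilience index of community structure
#'
#' `RL = 2|y_c,s - y_d,s| / (|y_c,s - y_d,s| + |y_c,e - y_d,e|) - 1`, where
#' `s` and `e` are the start and end of the secondary-succession window.
#' RL = 1 when the displacement from controls has vanished by the end of
#' the window (full recovery), 0 when it is unchanged, negative when the
#' community diverged further.
#'
#' @param y_cs,y_ds Control mean and disturbed similarity at the window
#'   start.
#' @param y_ce,y_de Control mean and disturbed similarity at the window end.
#' @return RL in \[-1, 1\]; `NA` when start and end displacements are both
#'   zero (a fully resistant community has no recovery to measure).
#' @export
resilience_index <- function(y_cs, y_ds, y_ce, y_de) {
  s <- abs(y_cs - y_ds)
  e <- abs(y_ce - y_de)
  ifelse(s + e == 0, NA_real_, 2 * s / (s + e) - 1)
}

#' Resistance and resilience report for a disturbance experiment
#'
#' Computes, from a divergence series, the resistance index at the press
#' week for every disturbed mesocosm (control reference `y_c` = arithmetic
#' mean of control mesocosms' similarities at that week) and the resilience
#' index over each requested secondary-succession window. Mesocosms missing
#' a referenced week are omitted from that index and noted.
#'
#' @param series A [divergence_series()].
#' @param resistance_week Week at which resistance is evaluated (default
#'   10, the height of the press).
#' @param windows List of `c(start, end)` week pairs for resilience;
#'   default the full (16-45), initial (16-20) and long-term (20-45)
#'   secondary succession.
#' @return data.frame of class `press_stability`: `mesocosm_id`,
#'   `treatment`, `kind` (resistance/resilience), `window`, `value`, plus
#'   the similarity components (`y_c`, `y_d` at start and end).
#' @export
stability_report <- function(series, resistance_week = 10L,
                             windows = list(c(16L, 45L), c(16L, 20L), c(20L, 45L))) {
  stopifnot(inherits(series, "divergence_series") || is.data.frame(series))
  ctrl <- series[series$treatment == "control", , drop = FALSE]
  dist <- series[series$treatment != "control", , drop = FALSE]
  if (nrow(ctrl) == 0L) stop("no control mesocosms in the series")
  y_c_at <- function(w) {
    s <- ctrl$similarity[ctrl$week == w]
    if (length(s) == 0L) stop("no control mesocosm sampled at week ", w)
    mean(s)
  }
  rows <- list()
  ## resistance at the press week
  y_c <- y_c_at(resistance_week)
  for (meso in unique(dist$mesocosm_id)) {
    sub <- dist[dist$mesocosm_id == meso, , drop = FALSE]
    y_d <- sub$similarity[sub$week == resistance_week]
    if (length(y_d) == 0L) {
      message("mesocosm ", meso, " not sampled at week ", resistance_week,
              "; resistance omitted")
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      mesocosm_id = meso, treatment = sub$treatment[1], kind = "resistance",
      window = as.character(resistance_week),
      value = resistance_index(y_c, y_d[1]),
      y_c_start = y_c, y_d_start = y_d[1],
      y_c_end = NA_real_, y_d_end = NA_real_,
      stringsAsFactors = FALSE)
  }
  ## resilience over each window
  for (win in windows) {
    if (length(win) != 2L || win[1] >= win[2])
      stop("each window must be c(start, end) with start < end")
    y_cs <- y_c_at(win[1]); y_ce <- y_c_at(win[2])
    for (meso in unique(dist$mesocosm_id)) {
      sub <- dist[dist$mesocosm_id == meso, , drop = FALSE]
      y_ds <- sub$similarity[sub$week == win[1]]
      y_de <- sub$similarity[sub$week == win[2]]
      if (length(y_ds) == 0L || length(y_de) == 0L) {
        message("mesocosm ", meso, " missing week ", win[1], " or ", win[2],
                "; resilience ", win[1], "-", win[2], " omitted")
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        mesocosm_id = meso, treatment = sub$treatment[1], kind = "resilience",
        window = paste0(win[1], "-", win[2]),
        value = resilience_index(y_cs, y_ds[1], y_ce, y_de[1]),
        y_c_start = y_cs, y_d_start = y_ds[1],
        y_c_end = y_ce, y_d_end = y_de[1],
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, c(rows, make.row.names = FALSE))
  class(res) <- c("press_stability", "data.frame")
  res
}

#' @export
print.press_stability <- function(x, ...) {
  cat("press_stability indices (theoretical range -1 to 1)\n")
  print.data.frame(x[, c("mesocosm_id", "treatment", "kind", "window", "value")],
                   digits = 3)
  invisible(x)
}

#' @export
summary.press_stability <- function(object, ...) {
  agg <- stats::aggregate(value ~ kind + window + treatment, data = object,
                          FUN = function(v) c(median = stats::median(v, na.rm = TRUE),
                                              min = min(v, na.rm = TRUE),
                                              max = max(v, na.rm = TRUE)))
  out <- cbind(agg[, 1:3], as.data.frame(agg$value))
  class(out) <- c("summary.press_stability", "data.frame")
  out
}

#' @export
print.summary.press_stability <- function(x, ...) {
  cat("stability summary by treatment\n")
  print.data.frame(x, digits = 3)
  invisible(x)
}

#' Plot a divergence series
#'
#' Base-graphics rendering of per-mesocosm similarity-to-baseline
#' trajectories, coloured by treatment.
#'
#' @param x A [divergence_series()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot.divergence_series <- function(x, ...) {
  cols <- c(control = "goldenrod", disturbance = "steelblue",
            disturbance_immigration = "palevioletred")
  graphics::plot(NA, xlim = range(x$week), ylim = c(0, 1),
                 xlab = "week", ylab = "Bray-Curtis similarity to baseline", ...)
  for (meso in unique(x$mesocosm_id)) {
    sub <- x[x$mesocosm_id == meso, ]
    sub <- sub[order(sub$week), ]
    graphics::lines(sub$week, sub$similarity, col = cols[[sub$treatment[1]]])
  }
  graphics::legend("bottomleft", legend = names(cols), col = cols, lty = 1, bty = "n")
  invisible(x)
}
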