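#' Parameters for the synthetic plate-reader kinetics generator
#'
#' Emulates the fluorogenic elastase assay: product accumulates linearly
#' over 3 hours with readings every 15 minutes (13 timepoints, t = 0..180
#' min), in 3 technical replicates per well type. Sample wells follow
#' `baseline + rate * t * (1 - inhibition_fraction)` (the fraction applying
#' only when an inhibitor is present), blank wells contain buffer and
#' substrate only (`baseline`), and independent Gaussian noise is added per
#' reading.
#'
#' @param n_timepoints number of readings (default 13: every 15 min, 3 h).
#' @param t_step_min minutes between readings.
#' @param baseline blank signal level, AU.
#' @param rate_uninhibited product accumulation rate, AU/min.
#' @param inhibition_fraction fraction in \[0,1\] of the rate suppressed by
#'   each inhibitor (recycled over `inhibitors`).
#' @param inhibitors character vector of inhibitor well types.
#' @param noise_sd reading noise, AU.
#' @param n_technical_replicates replicate wells per condition.
#' @param condition label attached to the sample wells (e.g. "Dys_7.5").
#' @param seed integer RNG seed.
#' @return validated list of class `kinetic_sim_params`.
#' @export
kinetic_sim_params <- function(n_timepoints = 13, t_step_min = 15,
                               baseline = 50, rate_uninhibited = 2,
                               inhibition_fraction = 0.5,
                               inhibitors = "cocktail",
                               noise_sd = 1,
                               n_technical_replicates = 3,
                               condition = "sample",
                               seed = 1L) {
  p <- list(n_timepoints = as.integer(n_timepoints),
            t_step_min = t_step_min, baseline = baseline,
            rate_uninhibited = rate_uninhibited,
            inhibition_fraction = inhibition_fraction,
            inhibitors = inhibitors, noise_sd = noise_sd,
            n_technical_replicates = as.integer(n_technical_replicates),
            condition = condition, seed = as.integer(seed))
  stopifnot(p$n_timepoints >= 2, p$t_step_min > 0, p$noise_sd >= 0,
            p$n_technical_replicates >= 1,
            all(p$inhibition_fraction >= 0), all(p$inhibition_fraction <= 1))
  class(p) <- "kinetic_sim_params"
  p
}

#' Simulate a kinetic plate
#'
#' @param params a `kinetic_sim_params` object.
#' @return data.frame with columns `well`, `condition`, `inhibitor`
#'   (`"none"` for uninhibited sample wells and blanks), `replicate`,
#'   `time_min`, `signal`. Blank wells carry `condition = "blank"`.
#' @export
simulate_kinetics <- function(params = kinetic_sim_params()) {
  stopifnot(inherits(params, "kinetic_sim_params"))
  set.seed(params$seed)
  t <- (seq_len(params$n_timepoints) - 1) * params$t_step_min
  inh_frac <- rep_len(params$inhibition_fraction, length(params$inhibitors))
  well_types <- c("none", params$inhibitors, "blank")
  rows <- list()
  wi <- 0
  for (wt in well_types) {
    for (rep_i in seq_len(params$n_technical_replicates)) {
      wi <- wi + 1
      mean_sig <- if (wt == "blank") {
        rep(params$baseline, length(t))
      } else if (wt == "none") {
        params$baseline + params$rate_uninhibited * t
      } else {
        f <- inh_frac[match(wt, params$inhibitors)]
        params$baseline + params$rate_uninhibited * (1 - f) * t
      }
      sig <- mean_sig + if (params$noise_sd > 0)
        rnorm(length(t), 0, params$noise_sd) else 0
      rows[[wi]] <- data.frame(
        well = sprintf("W%02d", wi),
        condition = if (wt == "blank") "blank" else params$condition,
        inhibitor = if (wt == "blank") "none" else wt,
        replicate = rep_i, time_min = t, signal = sig)
    }
  }
  do.call(rbind, rows)
}

#' Blank subtraction of a kinetic series
#'
#' Pointwise `sample - blank` on a shared time grid (reaction product =
#' signal emitted by the sample minus the signal of a blank containing only
#' buffer and substrate). Negative values are retained, not clipped, and
#' flagged.
#'
#' @param sample,blank data.frames with columns `time_min`, `signal`,
#'   sharing an identical strictly increasing time grid.
#' @return data.frame `time_min`, `signal` with attribute
#'   `"negative_flagged"` (TRUE if any difference < 0).
#' @export
blank_subtract <- function(sample, blank) {
  if (!isTRUE(all.equal(sample$time_min, blank$time_min)))
    stop("blank_subtract: time grids differ")
  out <- data.frame(time_min = sample$time_min,
                    signal = sample$signal - blank$signal)
  attr(out, "negative_flagged") <- any(out$signal < 0)
  out
}

#' Average technical replicates into an activity curve
#'
#' @param series list of data.frames (`time_min`, `signal`) on a shared
#'   grid, or a single long data.frame with a `replicate` column.
#' @return data.frame `time_min`, `product` (mean), `sem`, `n_replicates`.
#' @export
average_replicates <- function(series) {
  if (is.data.frame(series)) {
    stopifnot("replicate" %in% names(series))
    series <- split(series[c("time_min", "signal")], series$replicate)
  }
  stopifnot(length(series) >= 1)
  grid <- series[[1]]$time_min
  for (s in series)
    if (!isTRUE(all.equal(s$time_min, grid)))
      stop("average_replicates: replicate time grids differ")
  m <- sapply(series, function(s) s$signal)
  if (is.null(dim(m))) m <- matrix(m, nrow = length(grid))
  n <- ncol(m)
  data.frame(time_min = grid,
             product = rowMeans(m),
             sem = if (n > 1) apply(m, 1, sd) / sqrt(n) else 0,
             n_replicates = n)
}

#' Inhibitor-sensitive activity fraction
#'
#' The product attributable to the inhibited enzyme:
#' `sensitive(t) = uninhibited(t) - inhibited(t)` at every timepoint, so
#' that inhibited + sensitive reconstructs the uninhibited curve exactly.
#'
#' @param uninhibited,inhibited activity curves (`time_min`, `product`).
#' @param inhibitor inhibitor name recorded in the output.
#' @return data.frame `inhibitor`, `time_min`, `sensitive_product`.
#' @export
sensitive_fraction <- function(uninhibited, inhibited, inhibitor = "inhibitor") {
  if (!isTRUE(all.equal(uninhibited$time_min, inhibited$time_min)))
    stop("sensitive_fraction: time grids differ")
  data.frame(inhibitor = inhibitor,
             time_min = uninhibited$time_min,
             sensitive_product = uninhibited$product - inhibited$product)
}

#' Least-squares activity rate of a curve
#'
#' Ordinary least-squares slope of product versus time over a window
#' (default: the full series).
#'
#' @param curve data.frame with `time_min` and `product` (or `signal`).
#' @param window optional `c(t_min, t_max)` restricting the fit.
#' @return list `rate` (AU/min), `se`, `intercept`, `n`.
#' @export
activity_rate <- function(curve, window = NULL) {
  y <- if ("product" %in% names(curve)) curve$product else curve$signal
  t <- curve$time_min
  if (!is.null(window)) {
    keep <- t >= window[1] & t <= window[2]
    t <- t[keep]; y <- y[keep]
  }
  if (length(t) < 2) stop("activity_rate: need at least 2 timepoints")
  n <- length(t)
  tc <- t - mean(t)
  sxx <- sum(tc^2)
  slope <- sum(tc * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(t)
  rss <- sum((y - intercept - slope * t)^2)
  se <- if (n > 2) sqrt(rss / (n - 2) / sxx) else NA_real_
  list(rate = slope, se = se, intercept = intercept, n = n)
}

#' Percent inhibition between two activity curves
#'
#' `1 - rate_inhibited / rate_uninhibited`, with a delta-method standard
#' error propagated from the two slope SEs. A non-positive uninhibited rate
#' leaves the ratio undefined (NA, flagged).
#'
#' @param uninhibited,inhibited activity curves.
#' @param window optional fit window passed to [activity_rate()].
#' @return list `percent_inhibition` (fraction), `se`, `rate_uninhibited`,
#'   `rate_inhibited`, `flag` (`NA` or `"nonpositive_uninhibited_rate"`).
#' @export
percent_inhibition <- function(uninhibited, inhibited, window = NULL) {
  ru <- activity_rate(uninhibited, window)
  ri <- activity_rate(inhibited, window)
  if (ru$rate <= 0) {
    return(list(percent_inhibition = NA_real_, se = NA_real_,
                rate_uninhibited = ru$rate, rate_inhibited = ri$rate,
                flag = "nonpositive_uninhibited_rate"))
  }
  est <- 1 - ri$rate / ru$rate
  se <- sqrt((ri$se / ru$rate)^2 + (ri$rate * ru$se / ru$rate^2)^2)
  list(percent_inhibition = est, se = se,
       rate_uninhibited = ru$rate, rate_inhibited = ri$rate, flag = NA)
}

#' Process a kinetic plate end-to-end
#'
#' Averages the blank wells, blank-subtracts every sample well, averages
#' technical replicates per (condition, inhibitor), and extracts the
#' inhibitor-sensitive fractions and percent inhibition for each inhibitor
#' against the matching uninhibited wells, following the figure-legend
#' procedure (fractions are extracted from the *averaged* curves).
#'
#' @param plate long data.frame as produced by [simulate_kinetics()]
#'   (columns `well`, `condition`, `inhibitor`, `replicate`, `time_min`,
#'   `signal`).
#' @return list of data.frames: `curves` (per condition x inhibitor
#'   averaged activity), `sensitive` (per inhibitor sensitive fraction),
#'   `rates` (slope, SE, percent inhibition per inhibitor).
#' @export
process_plate <- function(plate) {
  need <- c("condition", "inhibitor", "replicate", "time_min", "signal")
  if (!all(need %in% names(plate)))
    stop("process_plate: plate must have columns ",
         paste(need, collapse = ", "))
  blanks <- plate[plate$condition == "blank", ]
  if (nrow(blanks) == 0) stop("process_plate: no blank wells")
  blank_avg <- average_replicates(blanks)
  blank_series <- data.frame(time_min = blank_avg$time_min,
                             signal = blank_avg$product)
  samples <- plate[plate$condition != "blank", ]
  keys <- unique(samples[c("condition", "inhibitor")])
  curves <- list()
  for (i in seq_len(nrow(keys))) {
    sub <- samples[samples$condition == keys$condition[i] &
                     samples$inhibitor == keys$inhibitor[i], ]
    reps <- lapply(split(sub[c("time_min", "signal")], sub$replicate),
                   blank_subtract, blank = blank_series)
    avg <- average_replicates(reps)
    avg$condition <- keys$condition[i]
    avg$inhibitor <- keys$inhibitor[i]
    curves[[i]] <- avg
  }
  curves <- do.call(rbind, curves)
  sens <- list()
  rates <- list()
  k <- 0
  for (cond in unique(keys$condition)) {
    un <- curves[curves$condition == cond & curves$inhibitor == "none", ]
    if (nrow(un) == 0) next
    for (inh in setdiff(unique(keys$inhibitor[keys$condition == cond]),
                        "none")) {
      ic <- curves[curves$condition == cond & curves$inhibitor == inh, ]
      k <- k + 1
      sf <- sensitive_fraction(un, ic, inh)
      sf$condition <- cond
      sens[[k]] <- sf
      pi_ <- percent_inhibition(un, ic)
      rates[[k]] <- data.frame(condition = cond, inhibitor = inh,
                               rate_uninhibited = pi_$rate_uninhibited,
                               rate_inhibited = pi_$rate_inhibited,
                               percent_inhibition = pi_$percent_inhibition,
                               se = pi_$se)
    }
  }
  list(curves = curves,
       sensitive = if (k > 0) do.call(rbind, sens) else NULL,
       rates = if (k > 0) do.call(rbind, rates) else NULL)
}
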