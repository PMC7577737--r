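#' Plot a window-wise wave estimate time course
#'
#' Forward (blue) and backward (red) net wave amounts against window start
#' time, with the zero-dB reference line and the injection time marked.
#'
#' @param x a `wave_estimates` data frame.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.wave_estimates <- function(x, ...) {
  graphics::plot(x$t_start / 60, x$fw_db, type = "l", col = "steelblue",
                 xlab = "time from injection (min)", ylab = "net waves (dB)",
                 ylim = range(c(x$fw_db, x$bw_db)), ...)
  graphics::lines(x$t_start / 60, x$bw_db, col = "firebrick")
  graphics::abline(h = 0, lty = 3)
  graphics::abline(v = 0, lty = 2, col = "grey40")
  graphics::legend("topright", c("FW", "BW"), lty = 1, bty = "n",
                   col = c("steelblue", "firebrick"))
  invisible(x)
}

#' Plot minute-by-minute study series
#'
#' One panel per condition: group mean forward and backward wave amounts per
#' minute with standard-error bars; minutes whose FDR-corrected test against
#' zero is significant are marked with an asterisk.
#'
#' @param x a `wave_study` (from [run_study()]).
#' @param ... ignored.
#' @return `x`, invisibly.
#' @export
plot.wave_study <- function(x, ...) {
  conds <- names(x$series)
  old <- graphics::par(mfrow = c(1, length(conds)))
  on.exit(graphics::par(old))
  for (cond in conds) {
    tb <- x$series[[cond]]$table
    ylim <- range(c(tb$fw_mean - tb$fw_se, tb$fw_mean + tb$fw_se,
                    tb$bw_mean - tb$bw_se, tb$bw_mean + tb$bw_se, 0))
    graphics::plot(tb$minute + 0.5, tb$fw_mean, type = "b", col = "steelblue",
                   pch = 16, ylim = ylim, xlab = "minute from injection",
                   ylab = "net waves (dB)", main = cond)
    graphics::arrows(tb$minute + 0.5, tb$fw_mean - tb$fw_se, tb$minute + 0.5,
                     tb$fw_mean + tb$fw_se, angle = 90, code = 3,
                     length = 0.02, col = "steelblue")
    graphics::lines(tb$minute + 0.5, tb$bw_mean, type = "b", col = "firebrick",
                    pch = 16)
    graphics::arrows(tb$minute + 0.5, tb$bw_mean - tb$bw_se, tb$minute + 0.5,
                     tb$bw_mean + tb$bw_se, angle = 90, code = 3,
                     length = 0.02, col = "firebrick")
    graphics::abline(h = 0, lty = 3); graphics::abline(v = 0, lty = 2)
    sig <- tb$minute[tb$fw_sig]
    if (length(sig)) graphics::text(sig + 0.5, ylim[2], "*", col = "steelblue")
    sig <- tb$minute[tb$bw_sig]
    if (length(sig)) graphics::text(sig + 0.5, ylim[1], "*", col = "firebrick")
  }
  invisible(x)
}
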