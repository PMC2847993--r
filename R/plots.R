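#' Diagnostic figures
#'
#' Optional ggplot2 figures mirroring the standard views of the models:
#' concentration/flux panels on log and linear time scales, overlays of
#' the numeric and glued asymptotic solutions with transition-time guides,
#' and inhibition-scan curves. Figure generation has no side effects on
#' any numeric output. Requires the suggested package ggplot2.
#'
#' @param traj A `trajectory`.
#' @return A ggplot object (patchable 4-panel grid for
#'   [plot_trajectory_panels()]).
#' @export
plot_trajectory_panels <- function(traj) {
  require_ggplot()
  if (nrow(traj) == 0) stop("empty trajectory: nothing to plot")
  sp <- attr(traj, "species")
  fx <- grep("^w[0-9]+$", names(traj), value = TRUE)
  long <- function(cols, what) {
    do.call(rbind, lapply(cols, function(s)
      data.frame(time = traj$time, value = traj[[s]], series = s,
                 what = what)))
  }
  df <- rbind(long(sp, "concentrations"), long(fx, "fluxes"))
  pos <- df[df$time > 0 & df$value > 0, ]
  g1 <- ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value,
                                         colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~what, scales = "free_y") +
    ggplot2::labs(x = "time (model units)", y = "value (linear scale)")
  g2 <- ggplot2::ggplot(pos, ggplot2::aes(.data$time, .data$value,
                                          colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~what, scales = "free_y") +
    ggplot2::labs(x = "time (log scale)", y = "value (log scale)")
  if (requireNamespace("patchwork", quietly = TRUE))
    patchwork::wrap_plots(g1, g2, ncol = 1)
  else list(linear = g1, log = g2)
}

#' @rdname plot_trajectory_panels
#' @param ps A `piecewise_solution` from [glue()].
#' @param p The matching `nonlinear_params`.
#' @export
plot_asymptotic_overlay <- function(ps, p) {
  require_ggplot()
  t_end <- max(ps$relaxation_time * 2, 1)
  tr <- integrate_model(p, t_end = t_end, n_out = 600)
  tt <- exp(seq(log(max(min(tr$time[tr$time > 0]), 1e-6)), log(t_end),
                length.out = 250))
  ana <- ps$evaluate(tt)
  sp <- nonlinear_species
  dfn <- do.call(rbind, lapply(sp, function(s)
    data.frame(time = tr$time, value = tr[[s]], species = s,
               kind = "numeric")))
  dfa <- do.call(rbind, lapply(sp, function(s)
    data.frame(time = tt, value = ana[, s], species = s,
               kind = "asymptotic")))
  df <- rbind(dfn, dfa)
  df <- df[df$time > 0 & df$value > 1e-6, ]
  guides <- unlist(ps$transitions)
  guides <- guides[is.finite(guides)]
  g <- ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value,
                                        colour = .data$species,
                                        linetype = .data$kind)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (model units)", y = "concentration",
                  title = sprintf("Dominant-system approximation (%s)",
                                  ps$route))
  if (length(guides))
    g <- g + ggplot2::geom_vline(xintercept = guides, linetype = "dashed",
                                 colour = "grey40")
  g
}

#' @rdname plot_trajectory_panels
#' @param scan A `scan_result`.
#' @export
plot_scan <- function(scan) {
  require_ggplot()
  df <- rbind(
    data.frame(factor = scan$factor, value = scan$steady_rate,
               what = "steady rate"),
    data.frame(factor = scan$factor, value = scan$relaxation_time,
               what = "relaxation time"))
  ggplot2::ggplot(df, ggplot2::aes(.data$factor, .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~what, scales = "free_y") +
    ggplot2::labs(x = "inhibition factor",
                  title = sprintf("%s / %s", scan$setting[1],
                                  scan$mechanism[1]))
}

require_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for figure generation")
  invisible(TRUE)
}
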