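#' Numerically integrate a translation model
#'
#' Integrates the mass-action ODEs with [deSolve::lsoda] (adaptive,
#' stiff-capable). Dense output is returned on a log-friendly grid: a short
#' linear ramp through zero followed by logarithmically spaced times, so
#' both the fast initial transient and the slow relaxation are resolved.
#'
#' @param p A `linear_params` or `nonlinear_params` object.
#' @param init Initial state (named vector); defaults to all pools free.
#' @param t_end End time, > 0.
#' @param n_out Number of output samples.
#' @param rtol,atol Integration tolerances.
#' @param prsynth_def Transient definition of the protein synthesis rate for
#'   the non-linear model, see [nonlinear_rhs()].
#' @param times Optional explicit output time grid (overrides `t_end`/`n_out`).
#' @return A `trajectory`: data.frame with `time`, species columns, flux
#'   columns `w1..` and `prsynth`, with the parameter object attached as an
#'   attribute.
#' @examples
#' p <- nonlinear_params(2, 2, 5, 1)
#' tr <- integrate_model(p, t_end = 50)
#' tail(tr, 1)
#' @export
integrate_model <- function(p, init = initial_state(p), t_end = 100,
                            n_out = 400, rtol = 1e-8, atol = 1e-10,
                            prsynth_def = "k4", times = NULL) {
  UseMethod("integrate_model")
}

log_grid <- function(t_end, n_out, t_min) {
  t_min <- min(t_min, t_end / 10)
  n_log <- max(n_out - 8L, 16L)
  unique(c(0, seq(0, t_min, length.out = 9L)[-1],
           exp(seq(log(t_min), log(t_end), length.out = n_log))))
}

run_lsoda <- function(func, init, times, rtol, atol, label) {
  out <- try(deSolve::lsoda(y = init, times = times, func = func,
                            rtol = rtol, atol = atol, maxsteps = 50000),
             silent = TRUE)
  if (inherits(out, "try-error") || nrow(out) < length(times)) {
    t_reached <- if (inherits(out, "try-error")) NA_real_ else max(out[, 1])
    stop(sprintf(
      "integrator failure in %s model near t = %s (stiff interval); reached %s of %s",
      label, format(t_reached), format(t_reached), format(max(times))))
  }
  out
}

#' @export
integrate_model.linear_params <- function(p, init = initial_state(p),
                                          t_end = 100, n_out = 400,
                                          rtol = 1e-8, atol = 1e-10,
                                          prsynth_def = "k4", times = NULL) {
  stopifnot(t_end > 0)
  init <- check_state(init, linear_species)
  if (abs(sum(init) - p$total_40S) > 1e-6 * p$total_40S)
    stop("init does not satisfy the 40S conservation total")
  func <- function(t, y, parms) {
    r <- linear_rhs(pmax(y, 0), p)
    list(r$derivatives)
  }
  if (is.null(times))
    times <- log_grid(t_end, n_out, t_min = 1e-3 / max(p$k1, p$k2, p$k3))
  out <- run_lsoda(func, init, times, rtol, atol, "linear")
  df <- as.data.frame(out)
  names(df)[1] <- "time"
  df$w1 <- p$k1 * df$c40S
  df$w2 <- p$k2 * df$c_mRNA40S
  df$w3 <- p$k3 * df$cAUG
  df$prsynth <- df$w3
  new_trajectory(df, p, species = linear_species)
}

#' @export
integrate_model.nonlinear_params <- function(p, init = initial_state(p),
                                             t_end = 100, n_out = 400,
                                             rtol = 1e-8, atol = 1e-10,
                                             prsynth_def = "k4",
                                             times = NULL) {
  stopifnot(t_end > 0)
  init <- check_state(init, nonlinear_species)
  res <- conservation_residuals(init, p)
  scale <- max(p$total_40S, p$total_60S, p$total_eIF4F)
  if (any(abs(res) > 1e-6 * scale))
    stop("init does not satisfy the conservation totals: ",
         paste(names(res)[abs(res) > 1e-6 * scale], collapse = ", "))
  func <- function(t, y, parms) {
    y <- pmax(y, 0)
    w1 <- p$k1 * y[1] * y[3]
    w2 <- p$k2 * y[4]
    w3 <- p$k3 * y[5] * y[2]
    w4 <- p$k4 * y[6]
    list(c(w4 - w1, w4 - w3, w2 - w1, w1 - w2, w2 - w3, w3 - w4))
  }
  if (is.null(times)) {
    rate_scale <- max(p$k1 * p$total_eIF4F, p$k1 * p$total_40S, p$k2,
                      p$k3 * p$total_60S, p$k4)
    times <- log_grid(t_end, n_out, t_min = 1e-3 / rate_scale)
  }
  out <- run_lsoda(func, init, times, rtol, atol, "non-linear")
  df <- as.data.frame(out)
  names(df) <- c("time", nonlinear_species)
  df$w1 <- p$k1 * df$c40S * df$c_eIF4F
  df$w2 <- p$k2 * df$c_mRNA40S
  df$w3 <- p$k3 * df$cAUG * df$c60S
  df$w4 <- p$k4 * df$c80S
  df$prsynth <- if (identical(prsynth_def, "k3")) df$w3 else df$w4
  new_trajectory(df, p, species = nonlinear_species)
}

new_trajectory <- function(df, p, species) {
  structure(df, class = c("trajectory", "data.frame"),
            params = p, species = species)
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d samples on [%g, %g], %d species\n",
              nrow(x), min(x$time), max(x$time),
              length(attr(x, "species"))))
  print.data.frame(utils::head(as.data.frame(x), 4), row.names = FALSE)
  if (nrow(x) > 4) cat("...\n")
  invisible(x)
}

#' Maximum conservation residual along a trajectory
#'
#' @param traj A `trajectory` from a non-linear model.
#' @return Largest absolute residual of the three conservation laws,
#'   relative to the largest conserved total.
#' @export
trajectory_conservation_error <- function(traj) {
  p <- attr(traj, "params")
  stopifnot(inherits(p, "nonlinear_params"))
  scale <- max(p$total_40S, p$total_60S, p$total_eIF4F)
  r1 <- traj$c_eIF4F + traj$c_mRNA40S - p$total_eIF4F
  r2 <- traj$c60S + traj$c80S - p$total_60S
  r3 <- traj$c40S + traj$c_mRNA40S + traj$cAUG + traj$c80S - p$total_40S
  max(abs(c(r1, r2, r3))) / scale
}

#' Write a trajectory as TSV
#'
#' Writes the trajectory table with a comment header recording the
#' parameter values (and fixture name, if any), so outputs are
#' self-describing and byte-stable across runs.
#'
#' @param traj A `trajectory`.
#' @param path Output file path.
#' @param fixture Optional fixture name recorded in the header.
#' @return Invisibly, `path`.
#' @export
write_trajectory <- function(traj, path, fixture = NULL) {
  p <- attr(traj, "params")
  hdr <- c(
    sprintf("# mirtrans trajectory%s",
            if (is.null(fixture)) "" else paste0(" fixture=", fixture)),
    paste0("# params: ", param_signature(p)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  df <- as.data.frame(traj)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) signif(v, 12))
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

param_signature <- function(p) {
  paste(vapply(seq_along(p), function(i)
    sprintf("%s=%.12g", names(p)[i], p[[i]]), character(1)), collapse = " ")
}
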