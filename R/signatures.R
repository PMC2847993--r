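#' Relaxation time of a trajectory
#'
#' Operational definition used throughout: the latest time at which any
#' chemical species differs from its final steady-state value by more than
#' `band` (10% by default) of that value. Species whose steady value is
#' below an absolute floor (`1e-6` of the largest conserved total) are
#' compared on an absolute scale instead, to avoid division blow-ups for
#' near-zero steady states.
#'
#' @param traj A `trajectory` (non-linear model).
#' @param ss A `steady_state` for the same parameters (exact solve by
#'   default).
#' @param band Relative band half-width (default 0.10).
#' @return Relaxation time (0 if the trajectory starts inside the band).
#'   Errors if any species is still outside its band at the end of the
#'   trajectory, naming the offending species.
#' @export
relaxation_time <- function(traj, ss = NULL, band = 0.10) {
  p <- attr(traj, "params")
  species <- attr(traj, "species")
  if (is.null(ss)) ss <- steady_state_exact(p)
  cs <- ss$concentrations[species]
  floor_abs <- 1e-6 * max(p$total_40S, p$total_60S, p$total_eIF4F)
  thr <- band * pmax(abs(cs), floor_abs)
  dev <- abs(as.matrix(as.data.frame(traj)[species]) -
               matrix(cs, nrow(traj), length(species), byrow = TRUE))
  outside <- dev > matrix(thr, nrow(traj), length(species), byrow = TRUE)
  still_out <- outside[nrow(traj), ]
  if (any(still_out))
    stop("trajectory has not settled within the band for: ",
         paste(species[still_out], collapse = ", "),
         " (t_end = ", max(traj$time), ")")
  any_out <- apply(outside, 1, any)
  if (!any(any_out)) return(0)
  traj$time[max(which(any_out))]
}

# integrate until the 10%-band relaxation time is well inside the horizon;
# returns list(time, traj).  Horizon doubling is capped.
measure_relaxation <- function(p, band = 0.10, ss = steady_state_exact(p),
                               t_end = NULL, n_out = 500, max_extend = 8) {
  if (is.null(t_end)) {
    slow <- min(p$k2, p$k4, p$k1 * p$total_eIF4F,
                p$k3 * p$total_60S)
    t_end <- 200 / slow
  }
  for (i in seq_len(max_extend)) {
    traj <- integrate_model(p, t_end = t_end, n_out = n_out)
    t_rel <- try(relaxation_time(traj, ss, band = band), silent = TRUE)
    if (!inherits(t_rel, "try-error") && t_rel <= 0.5 * t_end)
      return(list(time = t_rel, trajectory = traj))
    t_end <- t_end * 5
  }
  stop("relaxation-time measurement did not converge by t = ", t_end / 5)
}

#' MicroRNA inhibition scan of the non-linear model
#'
#' Mimics microRNA action on one translation step by scaling the targeted
#' parameter by a sequence of inhibition factors in (0, 1]. For each factor
#' the steady protein synthesis rate is taken from the exact steady-state
#' solver and the relaxation time is measured on a fresh numerical
#' integration from the all-free initial condition.
#'
#' @param p_base Baseline `nonlinear_params`.
#' @param mechanism One of `"k1"`, `"k2"`, `"k3"`, `"k4"`,
#'   `"eIF4F_total"` (cap-competition mechanism: reduces the total eIF4F
#'   pool).
#' @param setting Optional label describing the experimental setting,
#'   carried through to the result.
#' @param factors Inhibition factors in (0, 1], descending; default 30
#'   log-spaced values from 1 to 1e-4.
#' @param band Relaxation band, see [relaxation_time()].
#' @return A data.frame of class `scan_result` with columns `mechanism`,
#'   `setting`, `factor`, `steady_rate`, `relaxation_time` (NA where a
#'   solver failed; failures are recorded in attribute `"log"`).
#' @export
inhibition_scan <- function(p_base, mechanism = c("k1", "k2", "k3", "k4",
                                                  "eIF4F_total"),
                            setting = "unnamed",
                            factors = default_scan_factors(),
                            band = 0.10) {
  stopifnot(inherits(p_base, "nonlinear_params"))
  mechanism <- match.arg(mechanism)
  if (any(factors <= 0) || any(factors > 1))
    stop("inhibition factors must lie in (0, 1]")
  factors <- sort(factors, decreasing = TRUE)
  field <- if (mechanism == "eIF4F_total") "total_eIF4F" else mechanism
  rows <- vector("list", length(factors))
  log <- character(0)
  for (i in seq_along(factors)) {
    pi <- p_base
    pi[[field]] <- p_base[[field]] * factors[i]
    res <- try({
      ss <- steady_state_exact(pi)
      mr <- measure_relaxation(pi, band = band, ss = ss)
      c(ss$prsynth, mr$time)
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      log <- c(log, sprintf("factor %g: %s", factors[i],
                            conditionMessage(attr(res, "condition"))))
      res <- c(NA_real_, NA_real_)
    }
    rows[[i]] <- data.frame(mechanism = mechanism, setting = setting,
                            factor = factors[i], steady_rate = res[1],
                            relaxation_time = res[2])
  }
  out <- do.call(rbind, rows)
  structure(out, class = c("scan_result", "data.frame"), log = log,
            params = p_base, band = band)
}

#' @rdname inhibition_scan
#' @export
default_scan_factors <- function() 10^seq(0, -4, length.out = 30)

#' Canonical experimental settings for the non-linear signature table
#'
#' The four settings cross cap structure (wild-type vs A-cap, the latter
#' modeled by `k1 = 0.01`) with initiation regime (inefficient, `beta =
#' 0.48`, vs efficient, `beta = 7.2`).
#'
#' @param setting Setting name.
#' @return A `nonlinear_params` object.
#' @export
signature_setting <- function(setting = c("wt_inefficient", "wt_efficient",
                                          "acap_inefficient",
                                          "acap_efficient")) {
  setting <- match.arg(setting)
  switch(setting,
         wt_inefficient   = fixture("default"),
         wt_efficient     = fixture("efficient_scan"),
         acap_inefficient = fixture("acap_default"),
         acap_efficient   = fixture("acap_efficient_scan"))
}

#' Classifier thresholds for qualitative signature labels
#'
#' The published signature tables use coarse order-of-magnitude vocabulary
#' ("decreases", "goes up and down", ...) without numeric definitions. The
#' classifier maps scan curves to that vocabulary through fixed thresholds
#' on fold-changes read off at reference inhibition depths (interpolated
#' in log-log space). The defaults were calibrated once against the
#' canonical wild-type/A-cap fixtures and then frozen; they are exposed
#' here so sensitivity to the calibration can be explored.
#'
#' Relaxation-time labels are assessed only over the inhibition range in
#' which the targeted step keeps its place in the rate hierarchy assumed
#' by the staged analysis (a step driven far below the recycling rate `k4`
#' changes the dominant system itself, which the tables treat as
#' non-physiological); conditions already violated at baseline (A-cap
#' settings) are not imposed.
#'
#' @param model `"nonlinear"` or `"linear"` (Table-level vocabulary).
#' @return Named list of thresholds.
#' @export
signature_thresholds <- function(model = c("nonlinear", "linear")) {
  model <- match.arg(model)
  list(model = model,
       # steady-rate rules (folds D(f) = rate(1)/rate(f))
       rate_flat = 1.25,        # D(0.01) below this: no change
       rate_early_562 = 1.2,    # early-onset proportional decrease ...
       rate_early_316 = 1.6,    # ... requires both folds
       rate_after_threshold = 20,  # D(0.01) at least this: past threshold
       rate_strong = 4,         # D(0.01) in [strong, after): late, partial
       # relaxation-time rules (folds T(f) = trel(f)/trel(1))
       time_flat = if (model == "nonlinear") 2 else 1.4,
       time_slight_max = 2,     # linear vocabulary: slight rise in [flat, 2)
       time_increase = 2,
       time_drastic = 10,
       updown_peak = 1.2,       # interior peak at least this fold ...
       updown_dip = 1.08,       # ... followed by at least this fall
       updown_shallow = 0.05,   # peak search restricted to f >= this
       sustain = 0.8,           # rise must persist to the deep end
       window_sep_k1 = 10, window_sep_k2 = 2, window_sep_k3 = 5)
}

# log-log interpolation of a scan column at a reference factor
scan_value_at <- function(factors, values, f0) {
  if (f0 >= max(factors)) return(values[which.max(factors)])
  if (f0 <= min(factors)) return(values[which.min(factors)])
  o <- order(factors)
  exp(stats::approx(log(factors[o]), log(pmax(values[o], 1e-300)),
                    xout = log(f0))$y)
}

# lower factor bound of the hierarchy-preserving window for the
# relaxation-time assessment
time_window_lo <- function(p, mechanism, th) {
  if (!inherits(p, "nonlinear_params")) return(0)
  lo <- switch(mechanism,
    k1 = if (p$k1 * p$total_eIF4F >= th$window_sep_k1 * p$k4)
           th$window_sep_k1 * p$k4 / (p$k1 * p$total_eIF4F) else 0,
    k2 = if (p$k2 >= th$window_sep_k2 * p$k4)
           th$window_sep_k2 * p$k4 / p$k2 else 0,
    k3 = th$window_sep_k3 * max(p$k2, p$k1 * p$total_eIF4F) /
           (p$k3 * p$total_60S),
    0)
  min(lo, 1)
}

#' Classify an inhibition scan into qualitative signature labels
#'
#' Deterministic mapping from the shape of the steady-rate and
#' relaxation-time curves of an [inhibition_scan()] (or
#' [linear_mirna_scan()]) to the closed label vocabulary of the signature
#' tables. Near-threshold shapes are flagged as low-confidence rather than
#' silently resolved.
#'
#' @param scan A `scan_result`.
#' @param thresholds From [signature_thresholds()]; the model type is
#'   inferred from the scan's parameters when omitted.
#' @return List with `rate_label`, `time_label`, `low_confidence`
#'   (logical), and the computed `features`.
#' @export
classify_signature <- function(scan, thresholds = NULL) {
  stopifnot(inherits(scan, "scan_result"))
  p <- attr(scan, "params")
  if (is.null(thresholds))
    thresholds <- signature_thresholds(
      if (inherits(p, "linear_params")) "linear" else "nonlinear")
  th <- thresholds
  sc <- scan[stats::complete.cases(scan[c("factor", "steady_rate",
                                          "relaxation_time")]), ]
  sc <- sc[order(-sc$factor), ]
  if (nrow(sc) < 4 || max(sc$factor) < 1 - 1e-9)
    stop("scan must include the unperturbed baseline (factor 1) and ",
         "several factors")
  if (log10(max(sc$factor) / min(sc$factor)) < 3 - 1e-9)
    stop("scan must cover at least 3 decades of inhibition")
  mech <- as.character(sc$mechanism[1])
  r0 <- sc$steady_rate[1]
  t0 <- sc$relaxation_time[1]
  near <- function(x, thr, tol = 0.1) abs(x - thr) <= tol * thr
  lowconf <- FALSE

  # ---- steady-rate label
  Dat <- function(f0) r0 / scan_value_at(sc$factor, sc$steady_rate, f0)
  D562 <- Dat(10^-0.25); D316 <- Dat(10^-0.5); D2 <- Dat(1e-2)
  if (D2 < th$rate_flat) {
    rate_label <- "no_change"
  } else if (D562 >= th$rate_early_562 && D316 >= th$rate_early_316) {
    rate_label <- "decreases"
  } else if (D2 >= th$rate_after_threshold) {
    rate_label <- "decreases_after_threshold"
  } else if (D2 >= th$rate_strong) {
    rate_label <- "slightly_decreases_after_strong_inhibition"
  } else {
    rate_label <- "decreases_slightly"
  }
  lowconf <- lowconf || near(D2, th$rate_flat) ||
    near(D562, th$rate_early_562) || near(D2, th$rate_after_threshold) ||
    near(D2, th$rate_strong)

  # ---- relaxation-time label, on the hierarchy-preserving window
  f_lo <- time_window_lo(p, mech, th)
  win <- sc[sc$factor >= f_lo - 1e-12, ]
  Tmax <- max(win$relaxation_time) / t0
  f_deep <- min(win$factor)
  T_end <- scan_value_at(win$factor, win$relaxation_time, f_deep) / t0
  time_label <- NA_character_
  # interior peak followed by a fall (assessed at shallow inhibition)
  shal <- win[win$factor >= max(th$updown_shallow, f_lo), ]
  if (nrow(shal) >= 4) {
    ipk <- which.max(shal$relaxation_time)
    if (ipk > 1 && ipk < nrow(shal)) {
      pk <- shal$relaxation_time[ipk]
      dip <- min(shal$relaxation_time[(ipk + 1):nrow(shal)])
      if (pk / t0 >= th$updown_peak && dip <= pk / th$updown_dip) {
        time_label <- "goes_up_and_down"
        lowconf <- lowconf || near(pk / t0, th$updown_peak) ||
          near(pk / dip, th$updown_dip)
      }
    }
  }
  if (is.na(time_label)) {
    if (T_end >= th$time_increase && T_end >= th$sustain * Tmax) {
      time_label <- if (T_end >= th$time_drastic) "increases_drastically"
                    else "increases"
    } else if (Tmax >= th$time_flat && th$model == "linear") {
      time_label <- if (Tmax >= th$time_drastic) "increases_drastically"
                    else "increases"
    } else if (Tmax >= th$time_flat && Tmax < th$time_slight_max &&
               th$model == "linear") {
      time_label <- "increases_slightly"
    } else if (th$model == "linear" && Tmax >= th$time_flat) {
      time_label <- "increases_slightly"
    } else {
      time_label <- "no_change"
    }
    lowconf <- lowconf || near(T_end, th$time_increase) ||
      near(Tmax, th$time_flat)
  }

  # linear tables use the coarser published vocabulary
  if (th$model == "linear") {
    if (rate_label %in% c("decreases_slightly",
                          "slightly_decreases_after_strong_inhibition",
                          "decreases_after_threshold"))
      rate_label <- "no_change"
    if (time_label == "increases" && Tmax < th$time_slight_max)
      time_label <- "increases_slightly"
  }
  list(rate_label = rate_label, time_label = time_label,
       low_confidence = lowconf,
       features = list(D562 = D562, D316 = D316, D2 = D2, Tmax = Tmax,
                       T_end = T_end, window_lo = f_lo))
}

#' Compute the full signature table
#'
#' Runs the inhibition scans for every (setting, mechanism) combination
#' and classifies each into the qualitative label pair: the machine form
#' of the published signature tables (4 settings x 4 mechanisms for the
#' non-linear model, 2 settings x 3 mechanisms for the linear one).
#'
#' @param model `"nonlinear"` or `"linear"`.
#' @param factors Inhibition grid (defaults chosen per model).
#' @param progress Print progress lines.
#' @return Data frame with columns `setting`, `mechanism`, `rate_label`,
#'   `time_label`, `low_confidence`.
#' @export
signature_table <- function(model = c("nonlinear", "linear"),
                            factors = NULL, progress = FALSE) {
  model <- match.arg(model)
  th <- signature_thresholds(model)
  rows <- list()
  if (model == "nonlinear") {
    if (is.null(factors)) factors <- 10^seq(0, -4, by = -0.1)
    settings <- c("wt_inefficient", "wt_efficient",
                  "acap_inefficient", "acap_efficient")
    for (s in settings) for (m in c("k1", "k2", "k3", "k4")) {
      if (progress) message("scanning ", s, " / ", m)
      sc <- inhibition_scan(signature_setting(s), m, s, factors)
      cl <- classify_signature(sc, th)
      rows[[paste(s, m)]] <- data.frame(
        setting = s, mechanism = m, rate_label = cl$rate_label,
        time_label = cl$time_label, low_confidence = cl$low_confidence)
    }
  } else {
    if (is.null(factors)) factors <- 10^seq(0, -4, length.out = 25)
    for (s in c("wt", "acap")) for (m in c("k1", "k2", "k3")) {
      sc <- linear_mirna_scan(linear_setting(s), m, s, factors)
      cl <- classify_signature(sc, th)
      rows[[paste(s, m)]] <- data.frame(
        setting = s, mechanism = m, rate_label = cl$rate_label,
        time_label = cl$time_label, low_confidence = cl$low_confidence)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Published signature tables (reference predictions)
#'
#' The qualitative predictions of the two translation models for each
#' microRNA mechanism and experimental setting, in machine form: the
#' reference against which [signature_table()] is checked and the row
#' source for [mechanism_lookup()].
#'
#' @param model `"nonlinear"` or `"linear"`.
#' @return Data frame with columns `setting`, `mechanism`, `rate_label`,
#'   `time_label`.
#' @export
reference_signature_table <- function(model = c("nonlinear", "linear")) {
  model <- match.arg(model)
  if (model == "linear") {
    return(data.frame(
      setting = rep(c("wt", "acap"), each = 3),
      mechanism = rep(c("k1", "k2", "k3"), 2),
      rate_label = c("decreases", "decreases", "no_change",
                     "decreases", "no_change", "no_change"),
      time_label = c("increases_slightly", "increases_slightly",
                     "no_change",
                     "no_change", "increases_drastically", "no_change")))
  }
  data.frame(
    setting = rep(c("wt_inefficient", "wt_efficient",
                    "acap_inefficient", "acap_efficient"), each = 4),
    mechanism = rep(c("k1", "k2", "k3", "k4"), 4),
    rate_label = c(
      "decreases_slightly", "decreases", "no_change",
        "decreases_after_threshold",
      "no_change", "slightly_decreases_after_strong_inhibition",
        "no_change", "decreases",
      "decreases", "decreases", "no_change",
        "slightly_decreases_after_strong_inhibition",
      "decreases_after_threshold",
        "slightly_decreases_after_strong_inhibition", "no_change",
        "decreases"),
    time_label = c(
      "no_change", "no_change", "no_change", "goes_up_and_down",
      "no_change", "goes_up_and_down", "no_change", "no_change",
      "no_change", "no_change", "no_change", "goes_up_and_down",
      "goes_up_and_down", "goes_up_and_down", "no_change", "increases"))
}

#' Invert the signature table: which mechanisms match observations?
#'
#' Given observed qualitative labels in one or more experimental settings,
#' returns every mechanism whose reference-table row matches all provided
#' observations. An observation is a list/vector with elements
#' `rate_label` and/or `time_label` (omitted elements are wildcards).
#' When every provided observation is "no change / no change" the
#' no-effect hypothesis is appended as `"none"`: it is explicitly
#' indistinguishable from action on a never-limiting step.
#'
#' @param observed Named list: names are settings, values carry
#'   `rate_label`/`time_label`.
#' @param model `"nonlinear"` or `"linear"`.
#' @return Character vector of candidate mechanisms (possibly empty).
#' @examples
#' mechanism_lookup(list(acap = list(rate_label = "no_change",
#'                                   time_label = "increases_drastically")),
#'                  model = "linear")   # "k2"
#' @export
mechanism_lookup <- function(observed, model = c("nonlinear", "linear")) {
  model <- match.arg(model)
  ref <- reference_signature_table(model)
  vocab <- unique(c(ref$rate_label, ref$time_label))
  if (!length(observed)) stop("at least one observation is required")
  if (is.null(names(observed)) || any(!nzchar(names(observed))))
    stop("observations must be named by setting")
  bad_setting <- setdiff(names(observed), unique(ref$setting))
  if (length(bad_setting))
    stop("unknown setting(s): ", paste(bad_setting, collapse = ", "))
  mechs <- unique(ref$mechanism)
  all_nochange <- TRUE
  for (s in names(observed)) {
    obs <- observed[[s]]
    for (fld in c("rate_label", "time_label")) {
      lab <- obs[[fld]]
      if (is.null(lab) || is.na(lab)) next
      if (!lab %in% vocab)
        stop("unknown label '", lab, "' (not in the table vocabulary)")
      if (lab != "no_change") all_nochange <- FALSE
      keep <- ref$setting == s & ref[[fld]] == lab
      mechs <- intersect(mechs, ref$mechanism[keep])
    }
  }
  if (all_nochange) mechs <- union(mechs, "none")
  mechs
}
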