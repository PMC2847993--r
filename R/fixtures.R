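#' Named parameter fixtures
#'
#' Canonical parameter sets used throughout the analyses and tests. All
#' values are in relative, unitless model units.
#'
#' \describe{
#'   \item{default}{Original Nissan-Parker set: `k1=k2=2, k3=5, k4=1`,
#'     pools 100/25/6 (40S/60S/eIF4F); `beta = 0.48`, inefficient
#'     initiation.}
#'   \item{efficient}{Same but `k4 = 0.1`; `beta = 4.8`, efficient
#'     initiation, three-stage relaxation.}
#'   \item{strong_separation}{`k1=1, k2=5, k3=50, k4=0.01`; `beta = 120`,
#'     strongly separated time scales, the staged approximation is tight.}
#'   \item{efficient_scan}{`k1=2, k2=3, k3=50, k4=0.1`; `beta = 7.2`, the
#'     efficient-initiation base used for inhibition scans.}
#'   \item{acap_default / acap_efficient_scan}{A-cap variants of `default`
#'     and `efficient_scan` with `k1 = 0.01`: an artificial cap with very
#'     weak capacity to recruit the initiation machinery.}
#' }
#'
#' @param name Fixture name; see Details.
#' @return A `nonlinear_params` object with attribute `"fixture"`.
#' @examples
#' beta(fixture("default"))
#' @export
fixture <- function(name = c("default", "efficient", "strong_separation",
                             "efficient_scan", "acap_default",
                             "acap_efficient_scan")) {
  name <- match.arg(name)
  p <- switch(name,
    default             = nonlinear_params(2, 2, 5, 1, 100, 25, 6),
    efficient           = nonlinear_params(2, 2, 5, 0.1, 100, 25, 6),
    strong_separation   = nonlinear_params(1, 5, 50, 0.01, 100, 25, 6),
    efficient_scan      = nonlinear_params(2, 3, 50, 0.1, 100, 25, 6),
    acap_default        = nonlinear_params(0.01, 2, 5, 1, 100, 25, 6),
    acap_efficient_scan = nonlinear_params(0.01, 3, 50, 0.1, 100, 25, 6))
  attr(p, "fixture") <- name
  p
}

#' @rdname fixture
#' @export
fixture_names <- function() {
  c("default", "efficient", "strong_separation", "efficient_scan",
    "acap_default", "acap_efficient_scan")
}

#' Linear-model base settings
#'
#' Two experimental base settings for the linear cycle: `"wt"`, a wild-type
#' cap with comparable initiation steps (`k1 = k2`), and `"acap"`, an
#' artificial cap with strongly reduced recruitment (`k1 = k2/100`). In both
#' the elongation constant is fast (`k3 = 1000*k2`) so the two-time-scale
#' analysis applies.
#'
#' @param setting `"wt"` or `"acap"`.
#' @return A `linear_params` object.
#' @export
linear_setting <- function(setting = c("wt", "acap")) {
  setting <- match.arg(setting)
  switch(setting,
         wt   = linear_params(k1 = 1,    k2 = 1, k3 = 1000, total_40S = 100),
         acap = linear_params(k1 = 0.01, k2 = 1, k3 = 1000, total_40S = 100))
}

#' Read/write parameter sets as YAML or JSON
#'
#' Parameter files hold a flat mapping of the constructor arguments plus a
#' `model:` key (`"linear"` or `"nonlinear"`). Format is chosen from the
#' file extension (`.yaml`/`.yml`/`.json`).
#'
#' @param path File path.
#' @return `read_params()`: a parameter object. `write_params()`:
#'   invisibly, `path`.
#' @export
read_params <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lst <- switch(ext,
                yaml = , yml = yaml::read_yaml(path),
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                stop("unsupported parameter file extension: ", ext))
  model <- lst$model
  if (is.null(model)) stop("parameter file must contain a 'model' key")
  lst$model <- NULL
  known <- switch(model,
                  linear = names(formals(linear_params)),
                  nonlinear = names(formals(nonlinear_params)),
                  stop("unknown model type: ", model))
  unknown <- setdiff(names(lst), known)
  if (length(unknown) > 0)
    stop("unknown keys in parameter file: ", paste(unknown, collapse = ", "))
  do.call(switch(model, linear = linear_params, nonlinear = nonlinear_params),
          lst)
}

#' @rdname read_params
#' @param p Parameter object to write.
#' @export
write_params <- function(p, path) {
  lst <- c(list(model = if (inherits(p, "linear_params")) "linear"
                        else "nonlinear"),
           unclass(p))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         yaml = , yml = yaml::write_yaml(lst, path),
         json = jsonlite::write_json(lst, path, auto_unbox = TRUE,
                                     digits = NA),
         stop("unsupported parameter file extension: ", ext))
  invisible(path)
}
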