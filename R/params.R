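#' @rdname validate_params
#' @export
param_names <- function() {
  c("K0", "K1", "N0", "N1", "C1", "C2", "f", "g",
    "P1", "P2", "R1", "R2", "beta1", "beta2", "H", "M", "alpha")
}

#' Validate a doctor-patient fraud-game parameter set
#'
#' Checks a named collection of the 17 model constants against their domain
#' constraints and returns a `game_params` object. The constants are:
#'
#' * `K0`, `K1`: doctor payoff under non-fraud / fraud (`K1 > K0`);
#' * `N0`, `N1`: patient payoff under non-fraud / fraud (`N1 > N0`);
#' * `C1`, `C2`: doctor / patient fraud cost (>= 0);
#' * `f`, `g`: doctor / patient moral-hazard coefficient, the fraction of
#'   the counterpart's honest payoff extracted under information asymmetry
#'   (open interval (0, 1));
#' * `P1`, `P2`: institutional penalties on fraud (>= 0);
#' * `R1`, `R2`: institutional rewards for honesty (>= 0);
#' * `beta1`, `beta2`: risk coefficients scaling the fraud payoff at risk
#'   (open interval (0, 1));
#' * `H`: bribe paid by the patient to the doctor under collusion (>= 0);
#' * `M`: collusion surplus extracted jointly from the insurer (>= 0);
#' * `alpha`: the doctor's share of `M` (open interval (0, 1)).
#'
#' @param raw named list or numeric vector containing all 17 parameters.
#' @param allow_boundary if `TRUE`, the moral-hazard coefficients `f` and
#'   `g` may sit at 0 (closed-left interval `[0, 1)`). Used by the built-in
#'   sweep experiments whose printed value lists include 0; user-supplied
#'   configurations keep the strict open interval by default.
#' @return an object of class `game_params`: a named list of 17 numerics.
#' @examples
#' p <- baseline_params()
#' validate_params(unclass(p))
#' @export
validate_params <- function(raw, allow_boundary = FALSE) {
  raw <- as.list(raw)
  wanted <- param_names()
  missing <- setdiff(wanted, names(raw))
  if (length(missing) > 0L) {
    stop("configuration error: missing parameter(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  p <- lapply(raw[wanted], function(v) as.numeric(v)[1L])
  bad <- wanted[!vapply(p, function(v) is.finite(v), logical(1))]
  if (length(bad) > 0L) {
    stop("configuration error: non-finite value for: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  chk <- function(ok, msg) if (!ok) stop("invalid parameters: ", msg, call. = FALSE)
  chk(p$K1 > p$K0, "K1 > K0 required (fraud must out-pay honesty for doctors)")
  chk(p$N1 > p$N0, "N1 > N0 required (fraud must out-pay honesty for patients)")
  lo <- if (allow_boundary) 0 else .Machine$double.xmin
  chk(p$f >= lo && p$f < 1,
      if (allow_boundary) "0 <= f < 1 required" else "0 < f < 1 required")
  chk(p$g >= lo && p$g < 1,
      if (allow_boundary) "0 <= g < 1 required" else "0 < g < 1 required")
  chk(p$beta1 > 0 && p$beta1 < 1, "0 < beta1 < 1 required")
  chk(p$beta2 > 0 && p$beta2 < 1, "0 < beta2 < 1 required")
  chk(p$alpha > 0 && p$alpha < 1, "0 < alpha < 1 required")
  for (nm in c("C1", "C2", "P1", "P2", "R1", "R2", "H", "M", "K0", "N0")) {
    chk(p[[nm]] >= 0, paste0(nm, " >= 0 required"))
  }
  structure(p, class = "game_params")
}

#' Baseline parameter set of the numerical study
#'
#' The reference parameter set used throughout the simulation experiments:
#' `C1 = 3, C2 = 2, N0 = 2, N1 = 5, K0 = 2, K1 = 8, f = 0.8, g = 0.6,
#' alpha = 0.5, beta1 = 0.5, beta2 = 0.5, P1 = 5, P2 = 3, R1 = 5, R2 = 3,
#' H = 2, M = 25`. Under these values the interior saddle exists
#' (bistable regime, [classify_case()] returns `"case3"`).
#'
#' @return a validated `game_params` object.
#' @examples
#' classify_case(baseline_params())$case_id
#' @export
baseline_params <- function() {
  validate_params(list(
    K0 = 2, K1 = 8, N0 = 2, N1 = 5,
    C1 = 3, C2 = 2, f = 0.8, g = 0.6,
    P1 = 5, P2 = 3, R1 = 5, R2 = 3,
    beta1 = 0.5, beta2 = 0.5, H = 2, M = 25, alpha = 0.5))
}

#' Modify and re-validate a parameter set
#'
#' @param p a `game_params` object.
#' @param ... named replacements, e.g. `C1 = 7`.
#' @inheritParams validate_params
#' @return a validated `game_params` object.
#' @examples
#' update_params(baseline_params(), C1 = 7)
#' @export
update_params <- function(p, ..., allow_boundary = FALSE) {
  stopifnot(inherits(p, "game_params"))
  repl <- list(...)
  unknown <- setdiff(names(repl), param_names())
  if (length(unknown) > 0L) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  validate_params(modifyList(unclass(p), repl), allow_boundary = allow_boundary)
}

#' Read a parameter set from a YAML or JSON config file
#'
#' The file must be a flat mapping whose keys are exactly the 17 parameter
#' names (see [validate_params()]). The format is chosen from the file
#' extension: `.yml`/`.yaml` or `.json`.
#'
#' @param path path to the config file.
#' @inheritParams validate_params
#' @return a validated `game_params` object.
#' @export
read_params <- function(path, allow_boundary = FALSE) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yml  = ,
    yaml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    stop("unsupported config format '.", ext, "' (use YAML or JSON)", call. = FALSE))
  validate_params(raw, allow_boundary = allow_boundary)
}

#' Write a parameter set to a YAML or JSON config file
#'
#' @param p a `game_params` object.
#' @param path destination path; format chosen from the extension.
#' @return `path`, invisibly.
#' @export
write_params <- function(p, path) {
  stopifnot(inherits(p, "game_params"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    yml  = ,
    yaml = yaml::write_yaml(unclass(p), path),
    json = jsonlite::write_json(unclass(p), path, auto_unbox = TRUE, digits = NA),
    stop("unsupported config format '.", ext, "' (use YAML or JSON)", call. = FALSE))
  invisible(path)
}

#' @export
print.game_params <- function(x, ...) {
  cat("Doctor-patient fraud game parameters:\n")
  v <- unlist(unclass(x))
  print(v)
  cv <- condition_values(x)
  cat(sprintf("Regime conditions: A1 = %.4g, B1 = %.4g, A2 = %.4g, B2 = %.4g\n",
              cv[["A1"]], cv[["B1"]], cv[["A2"]], cv[["B2"]]))
  invisible(x)
}
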