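# Unit convention, fixed package-wide: OCR in fmol/min, well volume in pL,
# dissolved oxygen concentration in uM. 1 uM * 1 pL = 1e-3 fmol.
UM_PL_TO_FMOL <- 1e-3

#' Unit conversion constant between concentration-volume and amount
#'
#' Returns the factor converting a quantity in micromolar picoliters
#' (uM * pL) to femtomoles. All OCR arithmetic in the package uses this
#' single constant.
#'
#' @return The scalar `1e-3` (fmol per uM*pL).
#' @export
ku_fmol_per_uM_pL <- function() UM_PL_TO_FMOL

stop_config <- function(...) {
  stop(structure(
    class = c("picoresp_config_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

stop_data <- function(...) {
  stop(structure(
    class = c("picoresp_data_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_config(name, " must be a single finite number")
  }
  if (strict_lower && x <= lower) {
    stop_config(name, " must be > ", lower, " (got ", x, ")")
  }
  if (!strict_lower && x < lower) {
    stop_config(name, " must be >= ", lower, " (got ", x, ")")
  }
  if (x > upper) stop_config(name, " must be <= ", upper, " (got ", x, ")")
  invisible(x)
}

assert_probability <- function(x, name) {
  assert_scalar_number(x, name, lower = 0, upper = 1)
}

# All stochastic entry points funnel through here: the caller's RNG state is
# never touched, and a missing seed is an error rather than a silent draw
# from global state.
with_seed_checked <- function(seed, code) {
  if (missing(seed) || is.null(seed) || !is.numeric(seed) ||
      length(seed) != 1L || !is.finite(seed)) {
    stop_config("an explicit integer seed is required")
  }
  withr::with_seed(as.integer(seed), code)
}
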