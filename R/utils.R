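#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so simulation helpers are deterministic
#' given their `seed` argument without disturbing the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
local_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

#' Clamp values to a closed interval
#' @param x numeric vector.
#' @param lo,hi interval bounds.
#' @keywords internal
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Derive a per-stage sub-seed from a global seed
#'
#' Fans one global seed out to independent substreams so pipeline stages can be
#' rerun in isolation. Kept below 2^31 - 1.
#'
#' @param seed integer global seed.
#' @param stage integer stage offset.
#' @keywords internal
sub_seed <- function(seed, stage) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(stage) * 7919L
}

#' Reference demographic table for the emulated cohort
#'
#' Demographics of the 17-adult unilateral cochlear-implant cohort whose study
#' design the simulator's defaults emulate: age, sex, implanted ear, device,
#' months of implant use and etiology.
#'
#' @return a data.frame with 17 rows and columns `participant`, `age`, `sex`,
#'   `ear`, `implant_type`, `array`, `time_of_use_months`, `etiology`.
#' @examples
#' demo <- cohort_demographics()
#' mean(demo$time_of_use_months)
#' @export
cohort_demographics <- function() {
  path <- system.file("extdata", "cohort_demographics.csv", package = "pupilci")
  utils::read.csv(path, stringsAsFactors = FALSE)
}
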