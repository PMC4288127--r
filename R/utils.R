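#' Canonical muscle channel order
#'
#' The seven shoulder muscles recorded by the pipeline, in the order used by
#' every matrix in the package: anterior deltoid (AD), median deltoid (MD),
#' posterior deltoid (PD), pectoralis major superior (PMS) and inferior (PMI),
#' latissimus dorsi (LD) and teres major (TM).
#'
#' @return Character vector of length 7.
#' @export
emg_muscles <- function() c("AD", "MD", "PD", "PMS", "PMI", "LD", "TM")

# Evaluate `expr` under a fixed RNG state, restoring the caller's state after.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Derive a stage seed from a master seed; offsets are the sum of the stage
# name's character codes, so the derivation is documented and reproducible.
stage_seed <- function(master_seed, stage) {
  offset <- sum(utf8ToInt(stage))
  as.integer((as.numeric(master_seed) + offset) %% .Machine$integer.max)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

check_token <- function(value, valid, what) {
  if (length(value) != 1L || !value %in% valid)
    stopf("invalid %s '%s'; valid tokens: %s", what, as.character(value)[1L],
          paste(valid, collapse = ", "))
  value
}

check_finite_matrix <- function(x, what) {
  if (!is.matrix(x) || !all(is.finite(x)))
    stopf("%s must be a matrix of finite values", what)
  invisible(x)
}

rms <- function(x) sqrt(mean(x^2))
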