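#' @keywords internal
"_PACKAGE"

# Internal validation helpers. All user-facing constructors funnel through
# these so error messages are uniform and condition classes are testable.

abort <- function(msg, class) {
  stop(structure(
    class = c(class, "mnswell_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

check_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive finite number", name),
          "mnswell_validation_error")
  }
  invisible(x)
}

check_scalar_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
    abort(sprintf("`%s` must be a single nonnegative finite number", name),
          "mnswell_validation_error")
  }
  invisible(x)
}

check_strictly_increasing <- function(x, name) {
  if (length(x) >= 2L && any(diff(x) <= 0)) {
    abort(sprintf("`%s` must be strictly increasing", name),
          "mnswell_validation_error")
  }
  invisible(x)
}

#' Summarize replicate measurements as mean and standard error
#'
#' Replicate-level estimates throughout the pipeline are reported as
#' mean +/- SEM, with SEM = sample standard deviation / sqrt(n) and the
#' convention SEM = 0 for a single replicate.
#'
#' @param values numeric vector of replicate values (n >= 1, finite).
#' @return list with `n`, `mean`, `sem`.
#' @examples
#' summarize_replicates(c(1, 2, 3))  # mean 2, sem 0.5774
#' @export
summarize_replicates <- function(values) {
  if (!is.numeric(values) || length(values) < 1L || anyNA(values) ||
      any(!is.finite(values))) {
    abort("`values` must be a non-empty finite numeric vector",
          "mnswell_validation_error")
  }
  n <- length(values)
  list(
    n = n,
    mean = mean(values),
    sem = if (n == 1L) 0 else stats::sd(values) / sqrt(n)
  )
}

#' Convert a swelling rate constant between unit conventions
#'
#' With swelling expressed in percent, the pseudo-second-order rate constant
#' k_s carries units of 1/(percent * min); expressed as a mg/mg mass fraction
#' the same physical constant is 100 times larger. These helpers make the
#' convention explicit instead of guessing.
#'
#' @param ks rate constant.
#' @return rate constant in the other convention.
#' @export
ks_percent_to_fraction <- function(ks) {
  check_scalar_pos(ks, "ks")
  ks * 100
}

#' @rdname ks_percent_to_fraction
#' @export
ks_fraction_to_percent <- function(ks) {
  check_scalar_pos(ks, "ks")
  ks / 100
}
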