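#' @keywords internal
"_PACKAGE"

# Internal argument checks -----------------------------------------------

.checkCount <- function(x, name, min = 0L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != round(x) || x < min)
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  as.integer(x)
}

.checkScalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < lower || x > upper)
    stop(sprintf("'%s' must be a single number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  as.numeric(x)
}

#' Derive a reproducible child seed from a master seed
#'
#' Deterministic splitting rule used throughout the cohort generator so that
#' individual subjects (and cohort-level draws such as the parcellation or the
#' connectivity template) can be regenerated independently of one another.
#' The result always lies in \code{[1, 2^31 - 2]}.
#'
#' @param master Master seed (single integer).
#' @param index Stream index, e.g. the subject number (0 reserved for
#'   cohort-level draws).
#' @param salt Sub-stream discriminator (e.g. 0 = morphometry, 1 =
#'   connectivity, 2 = mesh jitter).
#' @return A single integer seed.
#' @export
deriveSeed <- function(master, index, salt = 0L) {
  master <- .checkCount(master, "master", min = 0L)
  index <- .checkCount(index, "index", min = 0L)
  salt <- .checkCount(salt, "salt", min = 0L)
  s <- (as.double(master %% 1000003L) * 10007 +
        as.double(index) * 104729 + as.double(salt) * 7919) %% 2147483646
  as.integer(s) + 1L
}

# Root-mean-square error
.rmse <- function(truth, pred) sqrt(mean((truth - pred)^2))
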