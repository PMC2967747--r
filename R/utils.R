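#' Clip p-values away from zero
#'
#' Probabilities are clipped to `[lower, 1]` before any logarithm is taken,
#' so that Fisher's statistic and -log10 transforms stay finite.
#'
#' @param p numeric vector of probabilities.
#' @param lower positive lower clip bound (default `1e-300`).
#' @return clipped vector, same length.
#' @export
clip_pvalues <- function(p, lower = 1e-300) {
  if (!is.numeric(p)) stop("p must be numeric")
  if (!is.numeric(lower) || length(lower) != 1L || lower <= 0)
    stop("lower clip bound must be a single positive number")
  pmin(pmax(p, lower), 1)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# deterministic per-study substream seed derived from (master seed, index);
# kept below 2^31 so it is a valid R integer seed
substream_seed <- function(seed, index) {
  as.integer((as.numeric(seed) + 10007 * as.numeric(index)) %% .Machine$integer.max)
}
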