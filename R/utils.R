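#' @importFrom stats plogis
#' @importFrom utils head tail
#' @importFrom data.table as.data.table data.table fread fwrite rbindlist .N
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

inv_logit <- function(x) stats::plogis(x)

#' Hour-interval labels
#'
#' Discrete time is indexed by the integer clock hour `t` ending the interval:
#' `t` labels the interval `(t-1:00, t:00]`, printed as `"Before 8 AM"`,
#' `"Before noon"`, etc. This labelling convention is fixed package-wide and
#' echoed in every output header.
#'
#' @param t integer vector of clock hours in 0..24.
#' @return character vector of labels.
#' @examples
#' hour_label(c(8, 12, 23))
#' @export
hour_label <- function(t) {
  stopifnot(is.numeric(t), all(t == round(t)), all(t >= 0 & t <= 24))
  vapply(as.integer(t), function(h) {
    if (h %in% c(0L, 24L)) return("Before midnight")
    if (h == 12L) return("Before noon")
    if (h < 12L) sprintf("Before %d AM", h) else sprintf("Before %d PM", h - 12L)
  }, character(1))
}

## interval-labelling convention string stamped into output file headers
interval_convention <- function() {
  paste("Row 'Before t' denotes the clock interval (t-1:00, t:00];",
        "an event in that row means the personal average was first attained",
        "within that interval.")
}

assert_that <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

## deterministic per-participant sub-stream seed derived from a master seed,
## kept below 2^31 so it is a valid R integer
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(i) * 69621) %% 2147483647)
}
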