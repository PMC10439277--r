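# Classed conditions so callers and tests can distinguish failure modes.

abort_format <- function(msg, call. = FALSE) {
  stop(structure(
    class = c("scmosaic_format_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

abort_usage <- function(msg) {
  stop(structure(
    class = c("scmosaic_usage_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

abort_param <- function(msg) {
  stop(structure(
    class = c("scmosaic_parameter_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# data.table is used for grouped aggregation; this flag lets its [.data.table
# dispatch work from within the package namespace.
.datatable.aware <- TRUE

#' @import data.table
NULL

#' @importFrom stats rbinom rnbinom rpois rnorm runif rbeta cor cor.test
#'   wilcox.test phyper p.adjust quantile var sd rmultinom setNames
#'   aggregate ks.test median
#' @importFrom utils read.delim write.table head
NULL
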