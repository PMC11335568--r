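#' @importFrom data.table := .N .I data.table
#' @import methods
NULL

.datatable.aware <- TRUE

# silence R CMD check notes for data.table NSE column names
utils::globalVariables(c(".", "value", "pos", "norm", "pid", "mid", "pnorm",
                         "mnorm", "x.ppos", "mpos", "rstrand", "rpos", "x.pos"))
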