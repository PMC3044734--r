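#' Normalize gene symbols
#'
#' Uppercases and strips surrounding whitespace. No alias resolution is
#' attempted; mapping between identifier systems is the caller's job.
#'
#' @param x character vector of raw symbols
#' @return normalized character vector
#' @export
normalizeSymbols <- function(x) {
    if (!length(x)) return(character())
    toupper(trimws(as.character(x)))
}

# package-level message helper; suppress with options(ConvergeNet.quiet=TRUE)
cnMessage <- function(...) {
    if (!isTRUE(getOption("ConvergeNet.quiet", FALSE)))
        message("[ConvergeNet] ", sprintf(...))
}

# induced subgraph of an Interactome on a symbol set, as plain igraph
inducedGraph <- function(net, symbols) {
    igraph::induced_subgraph(net@graph, vids = symbols)
}
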