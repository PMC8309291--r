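# Typed conditions so callers can branch on failure mode (omission rule,
# ambiguous annotation, undeterminable orientation) rather than matching text.

chloroCondition <- function(class, message, call = sys.call(-1)) {
  structure(
    class = c(class, "chloronormError", "error", "condition"),
    list(message = message, call = call)
  )
}

#' @rdname chloronorm-errors
#' @name chloronorm-errors
#' @title Error conditions used by chloronorm
#' @description
#' `noIRError`: the record has no usable pair of annotated inverted repeats;
#' per the omission rule such records are classified `no_ir` and excluded
#' from standardization. `ambiguousStructureError`: repeat annotations exist
#' but cannot be reduced to one disjoint near-equal-length pair, or the two
#' single-copy arcs have equal length. `undeterminedOrientationError`: the
#' gene-strand majority vote (including the all-genes fallback) is tied or
#' has no evidence. All inherit from class `chloronormError`.
#' @param message character error message.
#' @return These functions signal an error; they do not return.
#' @keywords internal
NULL

noIRError <- function(message = "no pair of annotated inverted repeats found") {
  stop(chloroCondition("noIRError", message))
}

ambiguousStructureError <- function(message) {
  stop(chloroCondition("ambiguousStructureError", message))
}

undeterminedOrientationError <- function(message) {
  stop(chloroCondition("undeterminedOrientationError", message))
}

formatError <- function(message) {
  stop(chloroCondition("formatError", message))
}
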