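# Classed conditions: every user-facing failure carries a stable machine code
# (e.g. "RAGGED_MATRIX") as condition class "svgheatmap_ragged_matrix", so
# callers and the CLI can dispatch without parsing messages.

hm_abort <- function(code, msg, ...) {
  extra <- list(...)
  cond <- structure(
    class = c(paste0("svgheatmap_", tolower(code)), "svgheatmap_error",
              "error", "condition"),
    c(list(message = sprintf("[%s] %s", code, msg), call = NULL), extra)
  )
  stop(cond)
}

#' @keywords internal
is_hm_error <- function(x, code = NULL) {
  if (is.null(code)) inherits(x, "svgheatmap_error")
  else inherits(x, paste0("svgheatmap_", tolower(code)))
}
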