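# Internal helpers shared across modules.

# Single choke point for the microgram -> milligram conversion used when a
# TTC limit (ug/day) is compared against exposures and safety limits
# (mg/day). Keeping this in one tagged function guards against silent
# 1000-fold unit errors, the worst failure mode of the framework.
ug_to_mg <- function(ug) {
  stopifnot(is.numeric(ug))
  ug / 1000
}

mg_to_ug <- function(mg) {
  stopifnot(is.numeric(mg))
  mg * 1000
}

# Collects human-readable decision lines; every branch of the pipeline
# appends to one of these so the final report carries a full audit trail.
new_audit <- function() {
  env <- new.env(parent = emptyenv())
  env$lines <- character()
  env
}

audit_add <- function(audit, ...) {
  if (is.null(audit)) {
    return(invisible(NULL))
  }
  audit$lines <- c(audit$lines, paste0(...))
  invisible(NULL)
}

audit_lines <- function(audit) {
  if (is.null(audit)) character() else audit$lines
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x)
}

is_flag <- function(x) {
  is.logical(x) && length(x) == 1L && !is.na(x)
}

# Validation errors collect every violated invariant before aborting, so a
# dossier author sees the full list at once.
abort_validation <- function(violations) {
  abort(
    c("Dossier validation failed:", stats::setNames(violations, rep("x", length(violations)))),
    class = "vaportox_validation_error",
    violations = violations
  )
}

abort_insufficient_data <- function(message, ...) {
  abort(message, class = "vaportox_insufficient_data", ...)
}
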