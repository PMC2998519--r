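# Condition constructors. Every error raised by the package carries a class
# from this family so callers (and the CLI) can map failures to exit codes:
# usage errors -> 1, data/integrity errors -> 2.

pr_error <- function(class, message, ..., call = sys.call(-1)) {
  structure(
    class = c(class, "pathrepo_error", "error", "condition"),
    list(message = message, call = call, ...)
  )
}

stop_usage <- function(message, ...) {
  stop(pr_error("pathrepo_usage_error", message, ...))
}

stop_vocab <- function(message, ...) {
  stop(pr_error(c("pathrepo_vocab_error", "pathrepo_data_error"), message, ...))
}

stop_not_found <- function(message, ...) {
  stop(pr_error(c("pathrepo_not_found_error", "pathrepo_data_error"), message, ...))
}

stop_integrity <- function(message, ...) {
  stop(pr_error(c("pathrepo_integrity_error", "pathrepo_data_error"), message, ...))
}

stop_validation <- function(message, path = NULL, ...) {
  if (!is.null(path)) message <- sprintf("%s (at %s)", message, path)
  stop(pr_error(c("pathrepo_validation_error", "pathrepo_data_error"),
                message, path = path, ...))
}

stop_conflict <- function(message, ...) {
  stop(pr_error(c("pathrepo_conflict_error", "pathrepo_data_error"), message, ...))
}

stop_export <- function(message, ...) {
  stop(pr_error(c("pathrepo_export_error", "pathrepo_data_error"), message, ...))
}
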