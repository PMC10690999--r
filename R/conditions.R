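# Classed conditions so callers (and the CLI) can distinguish configuration,
# input, integrity and value errors without string-matching messages.

npm_error <- function(message, class) {
  stop(structure(
    class = c(class, "npm_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

npm_config_error    <- function(message) npm_error(message, "npm_config_error")
npm_input_error     <- function(message) npm_error(message, "npm_input_error")
npm_integrity_error <- function(message) npm_error(message, "npm_integrity_error")
npm_value_error     <- function(message) npm_error(message, "npm_value_error")
npm_classification_error <- function(message) npm_error(message, "npm_classification_error")
npm_generation_error <- function(message) npm_error(message, "npm_generation_error")

`%||%` <- function(a, b) if (is.null(a)) b else a
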