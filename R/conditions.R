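# Structured error conditions. Two top-level families matter downstream:
# "configError" (bad constraint/config, CLI exit 2) and "dataError" (bad or
# inconsistent input data, CLI exit 3). Finer classes inherit from one of them.

.ssError <- function(message, class, call = sys.call(-1L), data = list()) {
  structure(
    class = c(class, "sliderSelectError", "error", "condition"),
    list(message = message, call = call, data = data)
  )
}

stopConfig <- function(message, subclass = character(), data = list()) {
  stop(.ssError(message, c(subclass, "configError"), data = data))
}

stopData <- function(message, subclass = character(), data = list()) {
  stop(.ssError(message, c(subclass, "dataError"), data = data))
}

stopParse <- function(message, data = list()) {
  stopData(message, subclass = "parseError", data = data)
}

stopValidation <- function(message, data = list()) {
  stopData(message, subclass = "validationError", data = data)
}

stopLookup <- function(message, data = list()) {
  stopData(message, subclass = "lookupError", data = data)
}

stopMapping <- function(message, data = list()) {
  stopData(message, subclass = "mappingError", data = data)
}
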