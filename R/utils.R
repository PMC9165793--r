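# Classed conditions so callers and tests can distinguish failure modes
# without matching message text.
bgStop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(class = c(class, "bgnetError", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

bgWarn <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  warning(structure(class = c(class, "bgnetWarning", "warning", "condition"),
                    list(message = msg, call = sys.call(-1))))
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random number stream.
withSeed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(expr)
}

vcapply <- function(X, FUN, ...) vapply(X, FUN, character(1), ...)
vnapply <- function(X, FUN, ...) vapply(X, FUN, numeric(1), ...)
vlapply <- function(X, FUN, ...) vapply(X, FUN, logical(1), ...)

# named numeric with names even when empty
namedNumeric <- function(x = numeric()) {
  if (is.null(names(x))) names(x) <- character(length(x))
  x
}
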