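# internal helpers shared across modules

# round half away from zero (printed tables use commercial rounding,
# base round() is banker's)
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# run code with a temporary RNG state so generators are pure functions
# of their rng_seed argument
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_spellerseg <- function(msg, class) {
  stop(structure(class = c(class, "spellerseg_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
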