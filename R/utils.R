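# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Half-up rounding for display values: 62.5% prints as 63%, which round()
# (round-half-even) would not give.
round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  floor(x * s + 0.5) / s
}

# Stable content hash for stage logging (md5 of the serialized object).
obj_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  con <- file(f, "wb")
  serialize(x, connection = con, version = 2)
  close(con)
  unname(tools::md5sum(f))
}

stage_log <- function(verbose, stage, t0, ...) {
  if (!isTRUE(verbose)) return(invisible(NULL))
  el <- sprintf("%.2fs", as.numeric(difftime(Sys.time(), t0, units = "secs")))
  message(sprintf("[rsmvpa] stage=%s elapsed=%s %s", stage, el,
                  paste(c(...), collapse = " ")))
}
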