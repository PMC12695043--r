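#' @keywords internal
"_PACKAGE"

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Half-up rounding for display percentages (base round() is half-even).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

fmt_num <- function(x, digits = 15) {
  vapply(x, function(v) {
    if (is.na(v)) "NA" else format(v, digits = digits, scientific = FALSE,
                                   trim = TRUE)
  }, character(1))
}

fmt_p <- function(p) sprintf("%.3f", round_half_up(p, 3))

abort_stage <- function(stage, msg) {
  stop(structure(class = c("hct_error", "error", "condition"),
                 list(message = sprintf("[%s] %s", stage, msg),
                      call = NULL, stage = stage)))
}
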