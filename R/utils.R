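# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Derive `n` reproducible child seeds from one master seed without
# disturbing the caller's RNG stream. Values stay below 2^31 - 1.
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s].",
                  name, format(min), format(max)))
  }
  invisible(x)
}

# Reverse complement for plain character DNA (ACGTN).
revcomp <- function(x) {
  chartr("ACGTN", "TGCAN",
         vapply(strsplit(x, "", fixed = TRUE),
                function(s) paste(rev(s), collapse = ""), character(1)))
}
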