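# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's .Random.seed is restored afterwards so library code never
# perturbs user-level randomness.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

# Reverse-complement of a plain character vector of DNA strings.
rc <- function(x) {
  as.character(reverseComplement(DNAStringSet(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic TSV writer: fixed quoting/format so repeated runs are
# byte-identical.
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
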