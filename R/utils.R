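# Internal helpers shared across the package.

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards. All stochastic routines in the package funnel
# their randomness through this so a single master seed gives bit-identical
# results.
with_seed <- function(seed, code) {
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
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a child seed from a master seed and a stream label, keeping the
# result inside the 32-bit integer range.
child_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

# Stable content digest used for provenance: serialize to a temp file and
# md5 it. version = 2 keeps digests comparable across R minor versions.
object_digest <- function(x) {
  f <- tempfile(fileext = ".rds")
  on.exit(unlink(f), add = TRUE)
  con <- file(f, "wb")
  serialize(x, con, version = 2, xdr = TRUE)
  close(con)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_maacnn <- function(...) stop(..., call. = FALSE)
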