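#' @keywords internal
"_PACKAGE"

## All randomness in the package flows through this helper: the caller's
## global RNG state is saved and restored, so seeded functions are pure.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

## Derive a stream-specific child seed so that independent sub-generators
## (e.g. per-sample draws inside a cohort) do not share streams.
child_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) * 1103515245L + as.integer(stream) * 12345L) %% 2147483587L
}

stop_if_not <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

## Benjamini-Hochberg / Bonferroni wrapper kept in one place so the choice of
## stats::p.adjust is a single seam for the oracle tests.
adjust_p <- function(p, method = c("bonferroni", "BH")) {
  method <- match.arg(method)
  stats::p.adjust(p, method = method)
}
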