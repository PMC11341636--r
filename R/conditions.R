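## Structured conditions so callers (and the CLI) can tell parse errors,
## validation failures, enumeration-guard hits and taxon mismatches apart.

np_error <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "netpars_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

np_parse_error <- function(msg, ...) np_error("netpars_parse_error", msg, ...)
np_validation_error <- function(msg, ...) np_error("netpars_validation_error", msg, ...)
np_guard_error <- function(msg, ...) np_error("netpars_guard_error", msg, ...)
np_taxon_error <- function(msg, ...) np_error("netpars_taxon_error", msg, ...)

## Canonical total order on vertex identifiers: C-locale lexicographic.
## Fixed once and used for every tie-break (maximal blob choice, switching
## enumeration order, canonical Newick) so results are reproducible.
canon_sort <- function(x) sort(x, method = "radix")

## Run expr with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
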