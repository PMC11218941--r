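# internal utilities

#' @useDynLib stockgrid, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Deterministic per-purpose substream of one global seed, so that e.g.
# observation noise does not shift when the population substream grows.
substream_seed <- function(seed, purpose) {
  codes <- utf8ToInt(purpose)
  offs <- sum(codes * seq_along(codes)) %% 104729L
  as.integer((as.numeric(seed) * 7919 + offs * 31 + 17) %% 2147483647)
}

# md5 of an R object via a temporary serialised file (used for cache keys)
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 2)
  close(con)
  unname(tools::md5sum(f))
}

# format numerics with 15 significant digits for CSV payloads
fmt_num <- function(x) {
  if (is.numeric(x)) formatC(x, digits = 15, format = "g") else x
}
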