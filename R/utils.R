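# Internal helpers shared across modules.

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Locale-independent ordering; all user-visible character sorts go through
# these so outputs are byte-identical across platforms.
.lexOrder <- function(...) order(..., method = "radix")
.lexSort <- function(x) sort(x, method = "radix")

.clampProb <- function(p, eps) pmin(pmax(p, eps), 1 - eps)

# Derive per-stage seeds from one master seed (documented counter scheme:
# stage k gets the k-th draw of sample.int(2^31 - 2) under the master seed).
.stageSeeds <- function(master_seed, n) {
  .withSeed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}

.readTsv <- function(path, header = FALSE, ...) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, header = header, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, blank.lines.skip = TRUE,
                    quote = "", ...)
}

.writeTsv <- function(x, path, col.names = TRUE) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = col.names)
}

# Fixed-format number rendering for deterministic summary files.
.fmtNum <- function(x, digits = 6L) {
  out <- sprintf(paste0("%.", digits, "g"), x)
  out[!is.finite(x)] <- as.character(x[!is.finite(x)])
  out
}
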