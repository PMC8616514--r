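#' @keywords internal
"_PACKAGE"

#' Derive a child seed from a root seed and a stage name
#'
#' All randomness in the package flows from one root seed through named
#' child streams, so that e.g. changing the radiomics configuration can
#' never perturb the survival simulation. The child seed is a deterministic
#' 31-bit hash of the root seed and the stream label.
#'
#' @param seed integer root seed.
#' @param stream character label of the stage ("phantom", "survival", ...).
#' @return a single integer in `[0, 2^31 - 1]`, usable with [set.seed()].
#' @export
child_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- fnv1a32(paste0(format(as.integer(seed)), "/", stream))
  as.integer(h %% 2147483647)
}

# FNV-1a 32-bit hash of a character scalar, returned as a double in [0, 2^32).
# Arithmetic is done in double with explicit mod to stay exact (< 2^53).
fnv1a32 <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\x1f")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor32(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  h
}

# xor for doubles representing 32-bit unsigned ints
bitwXor32 <- function(a, b) {
  lo <- bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
  hi <- bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536))
  hi * 65536 + lo
}

#' Stable hexadecimal hash of a configuration object
#'
#' Used in run manifests so that outputs can be matched to the exact
#' configuration that produced them. The object is canonicalized through
#' JSON (sorted names, full precision) before hashing.
#'
#' @param x any JSON-serializable R object (nested lists, vectors).
#' @return an 8-character lowercase hex string.
#' @export
config_hash <- function(x) {
  s <- jsonlite::toJSON(canonicalize(x), auto_unbox = TRUE, digits = NA)
  h <- fnv1a32(as.character(s))
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

canonicalize <- function(x) {
  if (is.list(x)) {
    nm <- names(x)
    if (!is.null(nm)) x <- x[order(nm)]
    lapply(x, canonicalize)
  } else x
}

# Run `expr` with the RNG state set from `seed`, restoring the caller's state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Write a data.frame as a diffable CSV: fixed column order as given,
# period decimal separator, no quoting of numerics, no row names.
write_table_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pkg_version <- function() {
  tryCatch(as.character(utils::packageVersion("wltb")),
           error = function(e) "0.0.0")
}
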