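`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `code`, and
#' restores the previous state on exit, so library functions never clobber
#' the user's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
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

#' Derive a child seed from a root seed
#'
#' Hierarchical seed splitting: every source of randomness in the pipeline is
#' seeded from a single root through this map, keeping results below 2^31.
#'
#' @param seed root integer seed.
#' @param k child index (any integer, including a hashed label).
#' @return integer in [1, 2^31 - 2].
#' @export
derive_seed <- function(seed, k) {
  s <- (as.double(seed) * 48271 + as.double(k) * 16807) %% 2147483646
  as.integer(s) + 1L
}

#' Hash a label to an integer for seed derivation
#' @keywords internal
label_key <- function(label) {
  sum(utf8ToInt(label) * seq_along(utf8ToInt(label))) %% 1000003L
}

#' FNV-1a hash of a character string (32-bit, hex)
#'
#' Used to stamp outputs with a configuration fingerprint: the hash changes
#' iff any effective parameter changes.
#'
#' @param x character scalar.
#' @return 8-character hex string.
#' @export
fnv1a_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(x)
  h <- 2166136261
  m <- 16777619
  for (b in bytes) {
    # xor with a byte only touches the low 31 bits; track the top bit apart
    hi <- h %/% 2^31
    lo <- bitwXor(as.integer(h %% 2^31), b)
    h <- hi * 2^31 + lo
    # 32-bit modular multiply in doubles without exceeding 2^53
    h <- ((h %/% 2^16 * m) %% 2^16 * 2^16 + (h %% 2^16) * m) %% 2^32
  }
  lo16 <- h %% 2^16
  hi16 <- h %/% 2^16
  sprintf("%04x%04x", hi16, lo16)
}

#' Configuration fingerprint
#'
#' Canonical JSON serialization of a configuration list, hashed with FNV-1a.
#' @param config a named list.
#' @return 8-character hex string.
#' @export
config_hash <- function(config) {
  config <- config[order(names(config))]
  js <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  fnv1a_hash(as.character(js))
}
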