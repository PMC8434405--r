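# Internal helpers: classed conditions, seeded RNG scoping, small hashing.

hs_stop <- function(msg, class, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c(class, "hydrashell_error", "error")))
}

hs_warn <- function(msg, class, ...) {
  warning(warningCondition(sprintf(msg, ...), class = c(class, "hydrashell_warning", "warning")))
}

# Evaluate `code` under set.seed(seed), restoring the caller's RNG state.
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
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    set.seed(as.integer(seed))
  }
  force(code)
}

# 32-bit FNV-1a over raw bytes, reported as 8 hex digits. Used to stamp
# output files with a hash of the configuration that produced them.
# Arithmetic kept exact in doubles (all intermediates < 2^53).
fnv1a_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L))
  h <- 2166136261  # 0x811c9dc5
  m <- 16777619    # FNV prime
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * m + ((hi * m) %% 65536) * 65536) %% 4294967296
  }
  lo <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo) / 65536), as.integer(lo))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)

check_scalar <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      (strict && x <= min) || (!strict && x < min)) {
    hs_stop("'%s' must be a finite scalar %s %s", "hs_parameter_error",
            name, if (strict) ">" else ">=", format(min))
  }
  invisible(x)
}
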