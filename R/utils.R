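# Internal helpers: seed derivation, config hashing, stage logging.

# Derive a child seed from a master seed and a string tag, staying < 2^31.
# FNV-1a 32-bit over the tag, folded with the master seed.
derive_seed <- function(seed, tag) {
  h <- fnv1a32(paste0(format(seed, scientific = FALSE), "/", tag))
  as.integer(h %% 2147483629)
}

# FNV-1a 32-bit hash of a string, returned as a double in [0, 2^32).
# Arithmetic kept in doubles; the 32-bit multiply is split into 16-bit
# halves so no intermediate exceeds 2^53.
fnv1a32 <- function(s) {
  bytes <- utf8ToInt(enc2utf8(s))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    lo <- h %% 65536; hi <- h %/% 65536
    lo <- bitwXor(as.integer(lo), as.integer(b %% 256))
    h <- lo + hi * 65536
    hl <- h %% 65536; hh <- h %/% 65536
    h <- (hl * p + ((hh * p) %% 65536) * 65536) %% 4294967296
  }
  h
}

# config hash: short hex digest of a deparsed R object (stable across runs
# in one R version; used to stamp artifacts, not for cryptography)
config_hash <- function(x) {
  s <- paste(deparse(x, control = c("keepNA", "keepInteger", "niceNames", "showAttributes")),
             collapse = "\n")
  h <- fnv1a32(s)
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

with_seed <- function(seed, code) {
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
  set.seed(seed)
  force(code)
}

# structured per-stage log record (printed when verbose)
log_stage <- function(verbose, stage, ..., t0 = NULL) {
  if (!isTRUE(verbose)) return(invisible(NULL))
  extra <- list(...)
  msg <- paste0("[", stage, "]")
  if (length(extra)) {
    msg <- paste(msg, paste(names(extra), unlist(extra), sep = "=", collapse = " "))
  }
  if (!is.null(t0)) {
    msg <- paste0(msg, sprintf(" elapsed=%.1fs", as.numeric(Sys.time()) - t0))
  }
  message(msg)
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
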