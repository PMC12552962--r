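# Internal helpers: classed error conditions and seed hygiene.

stop_input <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("gocondense_input_error", "error")))
}

stop_structure <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("gocondense_structure_error", "error")))
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All randomness in the package flows through this; nothing touches the
# global stream as a side effect.
with_seed <- function(seed, expr) {
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
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Write `lines` (or a writer function) to `path` atomically: stage in a
# sibling temp file, then rename.
write_atomic <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}

write_tsv_atomic <- function(df, path) {
  write_atomic(path, function(tmp) {
    utils::write.table(df, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  })
}
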