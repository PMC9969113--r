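# internal helpers

# stop with a classed condition so callers/tests can match on error class
abort_eoc <- function(msg, class = "eoclines_error") {
  cond <- errorCondition(msg, class = c(class, "eoclines_error"))
  stop(cond)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

check_count_matrix <- function(x, what = "count matrix") {
  if (!is.matrix(x)) abort_eoc(sprintf("%s must be a matrix", what), "eoclines_input_error")
  if (any(!is.finite(x))) abort_eoc(sprintf("%s contains non-finite values", what), "eoclines_input_error")
  if (any(x < 0)) {
    bad <- which(x < 0, arr.ind = TRUE)[1, ]
    abort_eoc(sprintf("%s has a negative entry at gene '%s', sample '%s'",
                      what,
                      rownames(x)[bad[1]] %||% bad[1],
                      colnames(x)[bad[2]] %||% bad[2]),
              "eoclines_input_error")
  }
  invisible(x)
}

# transform provenance chain carried on expression matrices
transform_chain <- function(x) attr(x, "transform_chain") %||% character()

add_transform <- function(x, tag, from = NULL) {
  attr(x, "transform_chain") <- c(if (is.null(from)) transform_chain(x) else transform_chain(from), tag)
  x
}

rowVars <- function(x) {
  n <- ncol(x)
  m <- rowMeans(x)
  rowSums((x - m)^2) / (n - 1)
}
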