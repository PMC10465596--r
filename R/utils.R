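#' @keywords internal
"_PACKAGE"

# Classed conditions so callers/tests can distinguish failure modes.
al_stop <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "al_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

al_assert <- function(ok, class, fmt, ...) {
  if (!isTRUE(ok)) al_stop(class, fmt, ...)
  invisible(TRUE)
}

#' Derive a reproducible substream seed
#'
#' Generators use per-entity substreams derived from one master seed so that
#' adding one neuron (or glomerulus, clone, trace) does not perturb the random
#' draws of the others. The derivation is a small multiplicative hash of the
#' master seed and a string label, reduced below 2^31 so it is a valid R seed.
#'
#' @param master integer master seed.
#' @param label character label naming the substream.
#' @return a single integer seed.
#' @export
substream_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(label))
  m <- 2147483629 # prime < 2^31
  h <- (as.numeric(master) %% m)
  for (ch in utf8ToInt(paste(label, collapse = "/"))) {
    h <- (h * 131 + ch) %% m
  }
  as.integer(h %% (m - 1L) + 1L)
}

# Evaluate expr with a temporary RNG state.
with_seed <- function(seed, expr) {
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
  expr
}

# Write/read delimited tables with a uniform dialect (TSV, header, no quotes).
write_tsv <- function(df, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  al_assert(file.exists(path), "al_load_error", "missing file: %s", path)
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

vec3_norm <- function(v) sqrt(sum(v^2))

# Row-wise cross product for n x 3 matrices.
cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}
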