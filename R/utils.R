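# internal helpers

#' @useDynLib antennaSeq, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# Every stochastic stage derives its seed as baseSeed + a fixed stage offset,
# so reordering stages cannot change the draws within a stage.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# fixed per-stage seed offsets (kept < 2^31 for any small base seed)
stageSeed <- function(baseSeed, stage) {
  offs <- c(simulate_sn = 101L, simulate_bulk = 202L, simulate_pair = 303L,
            background = 404L, cluster = 505L, acceptance = 606L)
  if (!stage %in% names(offs)) stop("unknown seed stage: ", stage)
  (as.integer(baseSeed) + offs[[stage]]) %% .Machine$integer.max
}

# Deterministic TSV writer: fixed column order, fixed numeric formatting,
# no quoting surprises. Numbers are written with up to 10 significant
# digits so identical inputs give byte-identical files.
writeTsv <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]) && !is.integer(df[[j]]))
      df[[j]] <- formatC(df[[j]], digits = 10, format = "g")
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

readTsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "")
}

logMsg <- function(...) message("[antennaSeq] ", ...)
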