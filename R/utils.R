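# internal helpers shared across modules

.pairId <- function(gene_i, gene_j) paste(gene_i, gene_j, sep = "|")

.splitPairId <- function(id) {
  parts <- strsplit(id, "|", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 2L
  if (any(bad))
    stop("malformed pair id (expected 'genei|genej'): ", id[bad][1])
  data.frame(gene_i = vapply(parts, `[`, "", 1L),
             gene_j = vapply(parts, `[`, "", 2L),
             stringsAsFactors = FALSE)
}

.assertFileExists <- function(path, what) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop(what, " file not found: ", if (is.character(path)) path else "<not a path>")
  invisible(path)
}

# Canonicalize cohort labels: named character vector with values case/control.
# `labels` may be a named vector/factor or a data.frame(sample_id, class).
.canonLabels <- function(labels, sampleIds = NULL) {
  if (is.data.frame(labels)) {
    labs <- setNames(as.character(labels[[2]]), as.character(labels[[1]]))
  } else {
    labs <- setNames(as.character(labels), names(labels))
  }
  if (is.null(names(labs)) || any(!nzchar(names(labs))))
    stop("cohort labels must be named by sample id")
  bad <- setdiff(unique(labs), c("case", "control"))
  if (length(bad))
    stop("unknown class label(s): ", paste(bad, collapse = ", "),
         " (expected 'case'/'control')")
  if (anyDuplicated(names(labs)))
    stop("duplicated sample ids in labels: ",
         paste(unique(names(labs)[duplicated(names(labs))]), collapse = ", "))
  if (!is.null(sampleIds)) {
    missing <- setdiff(names(labs), sampleIds)
    if (length(missing))
      stop("labelled sample(s) absent from matrix: ",
           paste(missing, collapse = ", "))
  }
  labs
}

# run `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's .Random.seed afterwards so package functions do not disturb the
# session RNG stream
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# 31-base polynomial rolling hash mod 2^31; short reproducible stamp for
# run configs (doubles stay exact below 2^53, so no overflow)
.configHash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
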