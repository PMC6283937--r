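## Internal helpers shared across modules.

#' @importFrom methods new validObject is slot
#' @importFrom stats anova aov ave binomial coef confint cor cor.test df
#'   glm lm median pf plogis pnorm pt qnorm quantile rbinom rgamma rlnorm
#'   rmultinom rnorm runif sd setNames var
#' @importFrom utils read.table write.table
NULL

## Evaluate `expr` under a fixed RNG seed without disturbing the caller's
## RNG stream.
.withSeed <- function(seed, expr) {
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
    set.seed(seed)
  }
  force(expr)
}

## Derive a deterministic child seed for a named random stream so that
## occurrence, trial, morph and trait generation can be re-run independently
## from one top-level seed. Pure arithmetic (no RNG state used); result is a
## valid 32-bit seed.
.childSeed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  codes <- utf8ToInt(stream)
  h <- sum(codes * seq_along(codes)) %% 2147483647
  as.integer((abs(seed) %% 2147483647 * 48271 + h * 7919 + 1) %% 2147483647)
}

## Delimiter auto-detection: tab if the header line contains one, else comma.
.detectDelim <- function(headerLine) {
  if (grepl("\t", headerLine, fixed = TRUE)) "\t" else ","
}

.checkColumns <- function(df, expected, what) {
  if (!setequal(names(df), expected) || length(names(df)) != length(expected)) {
    stop(sprintf(
      "%s: unexpected columns [%s]; expected exactly [%s]",
      what, paste(names(df), collapse = ", "),
      paste(expected, collapse = ", ")
    ), call. = FALSE)
  }
  df[, expected, drop = FALSE]
}

## Counts must be nonnegative integers; report the first offending row.
.checkCounts <- function(count, what) {
  raw <- count
  if (is.character(count)) count <- suppressWarnings(as.numeric(count))
  bad <- which(!is.finite(count) | count < 0 |
                 abs(count - round(count)) > 1e-9)
  if (length(bad)) {
    stop(sprintf("%s: count must be a nonnegative integer (row %d has '%s')",
                 what, bad[1], raw[bad[1]]), call. = FALSE)
  }
  as.integer(round(count))
}

.checkNoDuplicates <- function(keys, what) {
  dup <- which(duplicated(keys))
  if (length(dup)) {
    stop(sprintf("%s: duplicate key '%s' (row %d)", what, keys[dup[1]], dup[1]),
         call. = FALSE)
  }
  invisible(TRUE)
}

## Tolerant missing-value sentinels on read; canonical empty field on write.
.parseMass <- function(x, what) {
  x <- as.character(x)
  x[x %in% c("", "NA", "-", "na", "NaN")] <- NA_character_
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad)) {
    stop(sprintf("%s: non-numeric mass '%s' (row %d)", what, x[bad[1]], bad[1]),
         call. = FALSE)
  }
  out
}

.readDelimited <- function(source, what) {
  lines <- if (length(source) == 1L && !grepl("\n", source) && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else if (inherits(source, "connection")) {
    readLines(source, warn = FALSE)
  } else {
    unlist(strsplit(paste(source, collapse = "\n"), "\n", fixed = TRUE))
  }
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop(sprintf("%s: empty input", what), call. = FALSE)
  delim <- .detectDelim(lines[1])
  read.table(text = paste(lines, collapse = "\n"), sep = delim, header = TRUE,
             stringsAsFactors = FALSE, colClasses = "character",
             check.names = FALSE, quote = "\"", comment.char = "")
}

.writeDelimited <- function(df, path, delim = "\t") {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = delim), con, sep = "\n")
  if (nrow(df)) {
    body <- do.call(paste, c(lapply(df, function(col) {
      col <- as.character(col)
      col[is.na(col)] <- ""
      col
    }), sep = delim))
    writeLines(body, con, sep = "\n")
  }
  invisible(path)
}
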