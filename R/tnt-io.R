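#' Write a continuous character matrix in TNT (modified Hennig86) format
#'
#' Emits an `xread` block declared `nstates cont`, taxa as rows, values
#' printed with 3 decimal places; ranged characters are written as
#' `low-high` tokens. Values must not exceed 65 (the TNT continuous
#' bound) — scale with [tntScale()] first. The companion [readTNT()]
#' round-trips the file bit-exactly at the printed precision.
#'
#' @param m An [AbundanceMatrix-class] (max value <= 65) or
#'   [RangeMatrix-class].
#' @param path Output file path.
#' @param title Matrix title written into the file.
#' @return `path`, invisibly.
#' @export
writeTNT <- function(m, path, title = "repeat abundance continuous characters") {
  if (is(m, "AbundanceMatrix")) {
    lo <- hi <- m@values
  } else if (is(m, "RangeMatrix")) {
    lo <- m@lo; hi <- m@hi
  } else stop("m must be an AbundanceMatrix or RangeMatrix")
  if (max(hi) > 65 + 1e-9)
    stop("values exceed 65, the TNT continuous-character bound; ",
         "apply tntScale() first")
  ntax <- nrow(lo); nchar_ <- ncol(lo)
  fmt <- function(x) sprintf("%.3f", x)
  rows <- vapply(seq_len(ntax), function(i) {
    cells <- ifelse(abs(hi[i, ] - lo[i, ]) < 5e-4,
                    fmt(lo[i, ]),
                    paste0(fmt(lo[i, ]), "-", fmt(hi[i, ])))
    paste(rownames(lo)[i], paste(cells, collapse = " "))
  }, character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("nstates cont;",
               "xread",
               paste0("'", title, "'"),
               paste(nchar_, ntax),
               rows,
               ";",
               "proc /;"), con)
  invisible(path)
}

#' Read a TNT continuous `xread` matrix
#'
#' Parses files written by [writeTNT()]: plain values become an
#' [AbundanceMatrix-class] (scaling recorded as `tnt`), `low-high`
#' tokens a [RangeMatrix-class].
#'
#' @param path Path to the TNT file.
#' @return An [AbundanceMatrix-class] or [RangeMatrix-class].
#' @export
readTNT <- function(path) {
  txt <- readLines(path, warn = FALSE)
  ix <- grep("^\\s*xread\\s*$", txt)
  if (!length(ix)) stop("no xread block found in ", path)
  i <- ix[1] + 1L
  if (grepl("^'", txt[i])) i <- i + 1L          # title line
  dims <- as.integer(strsplit(trimws(txt[i]), "\\s+")[[1]])
  nchar_ <- dims[1]; ntax <- dims[2]
  rows <- txt[(i + 1L):(i + ntax)]
  taxaNames <- character(ntax)
  lo <- hi <- matrix(NA_real_, ntax, nchar_)
  isRange <- FALSE
  for (r in seq_len(ntax)) {
    tok <- strsplit(trimws(rows[r]), "\\s+")[[1]]
    taxaNames[r] <- tok[1]
    cells <- tok[-1]
    if (length(cells) != nchar_)
      stop("taxon ", tok[1], ": expected ", nchar_, " characters, got ",
           length(cells))
    rangeTok <- grepl("^[0-9.]+-[0-9.]+$", cells)
    isRange <- isRange || any(rangeTok)
    lo[r, ] <- as.numeric(sub("-.*$", "", cells))
    hi[r, ] <- ifelse(rangeTok, as.numeric(sub("^[0-9.]+-", "", cells)),
                      lo[r, ])
  }
  dimnames(lo) <- dimnames(hi) <-
    list(taxaNames, paste0("CL", seq_len(nchar_)))
  if (isRange)
    new("RangeMatrix", lo = lo, hi = hi,
        annotations = rep(NA_character_, nchar_),
        provenance = list(nReplicates = 2L, seMultiplier = NA_real_,
                          source = path))
  else
    AbundanceMatrix(lo, scaling = list(type = "tnt", factor = NA_real_))
}

#' Write/read the plain whitespace frequency table for the ML module
#'
#' A phylip-like table: a header line `ntax nchar`, then one row per
#' taxon of name followed by frequency values in `[0, 1]`.
#'
#' @param m A frequency-scaled [AbundanceMatrix-class].
#' @param path File path.
#' @return `path` invisibly (write); an [AbundanceMatrix-class] (read).
#' @export
writeFrequencyTable <- function(m, path) {
  stopifnot(is(m, "AbundanceMatrix"))
  if (max(m@values) > 1 + 1e-9)
    stop("values exceed 1; apply frequencyScale() first")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(nrow(m@values), ncol(m@values)), con)
  for (i in seq_len(nrow(m@values)))
    writeLines(paste(rownames(m@values)[i],
                     paste(sprintf("%.6f", m@values[i, ]), collapse = " ")),
               con)
  invisible(path)
}

#' @rdname writeFrequencyTable
#' @export
readFrequencyTable <- function(path) {
  txt <- readLines(path, warn = FALSE)
  dims <- as.integer(strsplit(trimws(txt[1]), "\\s+")[[1]])
  vals <- matrix(NA_real_, dims[1], dims[2])
  nm <- character(dims[1])
  for (r in seq_len(dims[1])) {
    tok <- strsplit(trimws(txt[r + 1L]), "\\s+")[[1]]
    nm[r] <- tok[1]
    vals[r, ] <- as.numeric(tok[-1])
  }
  dimnames(vals) <- list(nm, paste0("CL", seq_len(dims[2])))
  AbundanceMatrix(vals, scaling = list(type = "frequency", factor = NA_real_))
}
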