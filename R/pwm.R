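#' Construct a position weight matrix from nucleotide counts
#'
#' @param counts A 4 x L non-negative numeric matrix of base counts with
#'   rows in A, C, G, T order (L >= 4 columns).
#' @param name Motif name.
#' @param pseudocount Pseudocount added to every cell before converting
#'   counts to frequencies (default 0.25, i.e. one observation spread over
#'   the four bases).
#' @param background Base composition used in the log-odds denominator;
#'   must be strictly positive and sum to 1 (default uniform).
#' @return An object of class `pwm`.
#' @export
pwm <- function(counts, name = "motif", pseudocount = 0.25,
                background = rep(0.25, 4)) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) abort("PWM counts must have 4 rows (A, C, G, T)")
  if (ncol(counts) < 4L) abort("PWM must have at least 4 columns")
  if (any(counts < 0)) abort("PWM counts must be non-negative")
  if (!is.numeric(pseudocount) || pseudocount <= 0) abort("pseudocount must be > 0")
  if (length(background) != 4L || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-6) {
    abort("background must be 4 strictly positive frequencies summing to 1")
  }
  rownames(counts) <- c("A", "C", "G", "T")
  structure(list(name = name, counts = counts, pseudocount = pseudocount,
                 background = background / sum(background)),
            class = "pwm")
}

#' Read a JASPAR-style count matrix
#'
#' Accepts the bracketed JASPAR text form (`A [ 3 10 ... ]` etc., with an
#' optional `>` header line) and the bare 4-row form (whitespace-separated
#' counts, rows in A, C, G, T order). Exactly four matrix rows of equal
#' length are required. All-zero columns are accepted; the pseudocount
#' keeps scoring defined.
#'
#' @param path Path to the matrix file.
#' @inheritParams pwm
#' @return A `pwm` object.
#' @export
read_pwm <- function(path, pseudocount = 0.25, background = rep(0.25, 4)) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  name <- "motif"
  if (length(lines) && startsWith(lines[1], ">")) {
    name <- sub("^>\\s*", "", lines[1])
    lines <- lines[-1]
  }
  if (length(lines) != 4L) {
    abort(paste0(path, ": expected 4 matrix rows (A, C, G, T), found ", length(lines)))
  }
  rows <- lapply(seq_along(lines), function(i) {
    x <- gsub("^[ACGTacgt]\\s*", "", lines[[i]])
    x <- gsub("[][]", " ", x)
    v <- suppressWarnings(as.numeric(strsplit(trimws(x), "\\s+")[[1]]))
    if (!length(v) || anyNA(v)) abort(paste0(path, ": row ", i, ": malformed counts"))
    v
  })
  len <- lengths(rows)
  if (length(unique(len)) != 1L) {
    abort(paste0(path, ": matrix rows have unequal lengths (",
                 paste(len, collapse = ", "), ")"))
  }
  pwm(do.call(rbind, rows), name = name, pseudocount = pseudocount,
      background = background)
}

#' @export
print.pwm <- function(x, ...) {
  cat("<pwm> ", x$name, ": ", ncol(x$counts), " positions, pseudocount ",
      x$pseudocount, "\n", sep = "")
  cat("consensus:", pwm_consensus(x), "\n")
  invisible(x)
}

#' Log2-odds score matrix of a PWM
#'
#' Row `j`, column `b` holds
#' `log2(((counts[b,j] + pseudocount) / column total) / background[b])`.
#' A fifth column of zeros scores `N` (and any other ambiguity code) as
#' background, contributing nothing.
#'
#' @param x A `pwm`.
#' @return An L x 5 numeric matrix (columns A, C, G, T, N).
#' @export
pwm_score_matrix <- function(x) {
  cc <- x$counts + x$pseudocount
  freq <- sweep(cc, 2, colSums(cc), "/")
  s <- t(log2(sweep(freq, 1, x$background, "/")))
  cbind(s, N = 0)
}

#' Maximum achievable log2-odds score of a PWM
#' @param x A `pwm`.
#' @return A single number (sum over positions of the best base score).
#' @export
pwm_max_score <- function(x) {
  sum(apply(pwm_score_matrix(x)[, 1:4, drop = FALSE], 1, max))
}

#' Consensus sequence of a PWM (highest-count base per position)
#' @param x A `pwm`.
#' @return A character string of length `ncol(x$counts)`.
#' @export
pwm_consensus <- function(x) {
  paste(rownames(x$counts)[apply(x$counts, 2, which.max)], collapse = "")
}

#' A synthetic CTCF-like position weight matrix
#'
#' A constructed 19-column count matrix whose consensus matches the core
#' CTCF-binding site consensus (CCAGCAGGGGGCGCTGGTG-like zinc-finger core).
#' It is a synthetic stand-in built for simulation and testing, not a
#' matrix taken from a motif database; real analyses should supply their
#' own matrix via [read_pwm()].
#'
#' @param informativeness Count given to the consensus base at each
#'   position; the other three bases share the remainder of 100.
#' @inheritParams pwm
#' @return A `pwm` object of length 19.
#' @export
ctcf_like_pwm <- function(informativeness = 85, pseudocount = 0.25,
                          background = rep(0.25, 4)) {
  consensus <- strsplit("CCAGCAGGGGGCGCTGGTG", "")[[1]]
  stopifnot(informativeness > 25, informativeness <= 100)
  counts <- matrix((100 - informativeness) / 3, nrow = 4,
                   ncol = length(consensus),
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(consensus)) counts[consensus[j], j] <- informativeness
  pwm(counts, name = "CTCF-like (synthetic)", pseudocount = pseudocount,
      background = background)
}

#' Write a PWM in JASPAR-style bracketed text
#' @param x A `pwm`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pwm <- function(x, path) {
  lines <- c(paste0(">", x$name),
             vapply(1:4, function(i) {
               paste0(rownames(x$counts)[i], " [ ",
                      paste(format(x$counts[i, ], trim = TRUE), collapse = " "),
                      " ]")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}
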