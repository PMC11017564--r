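#' Build a pairwise-alignment scoring scheme
#'
#' Bundles a substitution matrix with affine gap penalties. A gap run of
#' length L costs `gap_open + (L - 1) * gap_extend`. The alphabet is the 20
#' canonical residues plus `X`, which scores 0 against everything (including
#' itself), so ambiguous residues neither reward nor punish an alignment.
#'
#' @param matrix Name of a built-in matrix (currently `"BLOSUM62"`) or a
#'   symmetric numeric matrix with single-letter residue dimnames.
#' @param gap_open Gap opening penalty (negative; charged for the first
#'   residue of a gap run).
#' @param gap_extend Gap extension penalty (negative; `gap_open <= gap_extend`).
#' @param mode `"global"` (Needleman-Wunsch style, used for identity
#'   reporting) or `"local"` (Smith-Waterman style, available for detection).
#' @return An object of class `pga_scheme`.
#' @examples
#' sc <- scoring_scheme()
#' sc$matrix["A", "A"]
#' @export
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = -11,
                           gap_extend = -1, mode = c("global", "local")) {
  mode <- match.arg(mode)
  if (is.character(matrix)) {
    if (!identical(matrix, "BLOSUM62")) {
      stop("unknown built-in substitution matrix: ", matrix)
    }
    mat <- blosum62_x()
  } else {
    mat <- as.matrix(matrix)
  }
  if (is.null(rownames(mat)) || !identical(rownames(mat), colnames(mat))) {
    stop("substitution matrix must have identical row and column names")
  }
  if (max(abs(mat - t(mat))) > 0) stop("substitution matrix must be symmetric")
  if (!(gap_open < 0 && gap_extend < 0 && gap_open <= gap_extend)) {
    stop("gap penalties must satisfy gap_open <= gap_extend < 0")
  }
  structure(
    list(matrix = mat, alphabet = rownames(mat), gap_open = gap_open,
         gap_extend = gap_extend, mode = mode),
    class = "pga_scheme"
  )
}

# BLOSUM62 over the 20 canonical residues, with an X row/column pinned to 0.
blosum62_x <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  full <- env$BLOSUM62
  mat <- full[AA20, AA20]
  mat <- rbind(cbind(mat, X = 0), X = 0)
  storage.mode(mat) <- "double"
  mat
}

check_sequence <- function(x, alphabet, arg = "sequence") {
  if (length(x) != 1L || is.na(x) || !nzchar(x)) {
    stop(arg, " must be a non-empty amino-acid string")
  }
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% alphabet)
  if (length(bad) > 0) {
    stop(sprintf("%s contains illegal character '%s' at position %d",
                 arg, chars[bad[1]], bad[1]))
  }
  invisible(x)
}

#' @export
print.pga_scheme <- function(x, ...) {
  cat(sprintf("<pga_scheme> %s, gap open %g / extend %g, %s mode\n",
              "substitution matrix", x$gap_open, x$gap_extend, x$mode))
  invisible(x)
}
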