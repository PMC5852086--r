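# CIGAR arithmetic. The clip geometry is the raw material of junction
# evidence, so these helpers are exact and tested rather than approximated.

cigar_tokenize <- function(cigar) {
  regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))
}

#' Parse a CIGAR string into operation/length pairs
#'
#' @param cigar a single CIGAR string, e.g. `"50S50M"`.
#' @return data.frame with columns `op` (character) and `len` (integer).
#' @export
#' @examples
#' parse_cigar("50S50M")
parse_cigar <- function(cigar) {
  stopifnot(length(cigar) == 1L)
  if (is.na(cigar) || cigar == "*") {
    return(data.frame(op = character(), len = integer()))
  }
  tok <- cigar_tokenize(cigar)[[1]]
  if (paste0(tok, collapse = "") != cigar) {
    stop("malformed CIGAR: ", cigar)
  }
  data.frame(
    op = substring(tok, nchar(tok), nchar(tok)),
    len = as.integer(substring(tok, 1L, nchar(tok) - 1L)),
    stringsAsFactors = FALSE
  )
}

# Vectorized reference-consumed width (M, D, N, =, X).
cigar_ref_width <- function(cigar) {
  toks <- cigar_tokenize(cigar)
  vapply(toks, function(tok) {
    if (length(tok) == 0L) return(NA_integer_)
    op <- substring(tok, nchar(tok), nchar(tok))
    keep <- op %in% c("M", "D", "N", "=", "X")
    sum(as.integer(substring(tok[keep], 1L, nchar(tok[keep]) - 1L)))
  }, integer(1))
}

# Vectorized query-consumed width (M, I, S, =, X); excludes hard clips.
cigar_query_width <- function(cigar) {
  toks <- cigar_tokenize(cigar)
  vapply(toks, function(tok) {
    if (length(tok) == 0L) return(NA_integer_)
    op <- substring(tok, nchar(tok), nchar(tok))
    keep <- op %in% c("M", "I", "S", "=", "X")
    sum(as.integer(substring(tok[keep], 1L, nchar(tok[keep]) - 1L)))
  }, integer(1))
}

# Leading/trailing clip lengths (S or H) and whether each is soft.
# Returns a data.frame: left_len, right_len, left_soft, right_soft.
cigar_clips <- function(cigar) {
  toks <- cigar_tokenize(cigar)
  out <- vapply(toks, function(tok) {
    if (length(tok) == 0L) return(c(0, 0, 0, 0))
    op <- substring(tok, nchar(tok), nchar(tok))
    len <- as.integer(substring(tok, 1L, nchar(tok) - 1L))
    left <- 0L; right <- 0L; lsoft <- 0L; rsoft <- 0L
    i <- 1L
    while (i <= length(op) && op[i] %in% c("S", "H")) {
      left <- left + len[i]
      if (op[i] == "S") lsoft <- lsoft + len[i]
      i <- i + 1L
    }
    j <- length(op)
    while (j > i && op[j] %in% c("S", "H")) {
      right <- right + len[j]
      if (op[j] == "S") rsoft <- rsoft + len[j]
      j <- j - 1L
    }
    c(left, right, lsoft, rsoft)
  }, numeric(4))
  data.frame(
    left_len = as.integer(out[1, ]),
    right_len = as.integer(out[2, ]),
    left_soft = as.integer(out[3, ]),
    right_soft = as.integer(out[4, ])
  )
}
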