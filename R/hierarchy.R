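# Hierarchical decomposition of a fixed-length sequence into four levels
# (900 bp segments, 90-mers, 9-mers, bases) and k-mer tokenization.
#
# The per-parent fan-outs are 10 / 10 / 10 / 9: a 9000 bp input yields
# 10 x 900 bp, 100 x 90-mer, 1000 x 9-mer and 9000 base segments. Inputs
# shorter than 900 bp ("short mode") have no 900 bp level and the 90-mers
# become the top level.

LEVEL_NAMES <- c("900", "90", "9", "base")
LEVEL_WIDTHS <- c(`900` = 900L, `90` = 90L, `9` = 9L, base = 1L)

#' Pad a sequence up to the next multiple of a quantum
#'
#' Appends pad symbols (`"0"`) so the length becomes the smallest multiple
#' of `quantum` that is >= the current length. A 500 bp query, for example,
#' pads to 540 bp under `quantum = 90`.
#'
#' @param seq a single sequence string.
#' @param quantum one of 90, 900, 9000 (bp).
#' @return the padded string.
#' @export
pad_to_multiple <- function(seq, quantum) {
  stopifnot(length(seq) == 1, quantum %in% c(90L, 900L, 9000L))
  n <- nchar(seq)
  if (n == 0) stop("Cannot pad an empty sequence.", call. = FALSE)
  target <- as.integer(ceiling(n / quantum) * quantum)
  if (target > n) seq <- paste0(seq, strrep(PAD_SYMBOL, target - n))
  seq
}

# Split one string into consecutive chunks of the given width.
chop_string <- function(seq, width) {
  n <- nchar(seq)
  if (width == 1L) return(strsplit(seq, "", fixed = TRUE)[[1]])
  starts <- seq.int(1L, n, by = width)
  substring(seq, starts, starts + width - 1L)
}

#' Decompose a fixed-length sequence into the four graph levels
#'
#' Cuts the sequence left-to-right, without overlap, into 900 bp segments,
#' 90-mers, 9-mers and bases. Concatenating any level in order reconstructs
#' the input exactly. For inputs shorter than 900 bp the 900 bp level is
#' empty (short mode). Each level carries a pad mask flagging segments that
#' consist entirely of pad symbols; because padding is always a suffix, the
#' masks are suffix-monotone.
#'
#' @param seq a single sequence string whose length is divisible by 90 (and
#'   by 900 when >= 900 bp); use [pad_to_multiple()] first otherwise.
#' @return an object of class `gv_decomp`: list with `levels` (named list of
#'   character vectors `900`, `90`, `9`, `base`), `pad_mask` (parallel list
#'   of logicals) and `length`.
#' @examples
#' d <- decompose_sequence(strrep("ACGTACGTA", 60))  # 540 bp
#' lengths(d$levels)
#' @export
decompose_sequence <- function(seq) {
  stopifnot(length(seq) == 1)
  n <- nchar(seq)
  if (n %% 90L != 0L) {
    stop("Sequence length ", n, " is not divisible by 90; ",
         "pad it first with pad_to_multiple().", call. = FALSE)
  }
  if (n >= 900L && n %% 900L != 0L) {
    stop("Sequences of ", n, " bp (>= 900) must be divisible by 900; ",
         "pad to 9000 bp first.", call. = FALSE)
  }
  levels <- list(
    `900` = if (n >= 900L) chop_string(seq, 900L) else character(0),
    `90` = chop_string(seq, 90L),
    `9` = chop_string(seq, 9L),
    base = chop_string(seq, 1L)
  )
  pad_mask <- lapply(levels, function(segs) {
    if (!length(segs)) return(logical(0))
    !grepl(sprintf("[^%s]", PAD_SYMBOL), segs)
  })
  structure(
    list(levels = levels, pad_mask = pad_mask, length = n),
    class = "gv_decomp"
  )
}

#' @export
#' @method print gv_decomp
print.gv_decomp <- function(x, ...) {
  cat("<gv_decomp> ", x$length, " bp; segments per level: ",
      paste(sprintf("%s:%d", names(x$levels), lengths(x$levels)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' k-mer vocabulary with special tokens
#'
#' Clean tokens (pure A/C/G/T) are numbered 0..4^k-1 by base-4 lexicographic
#' encoding with A=0, C=1, G=2, T=3; a token containing N maps to the UNK id
#' (4^k) and a token containing the pad symbol maps to the PAD id (4^k + 1).
#' This integer identity is the compact realization of a one-hot encoding:
#' a one-hot vector times a weight matrix is just a row lookup.
#'
#' @param k token length (9 for 9-mers, 1 for bases).
#' @return object of class `gv_vocab` with fields `k`, `size`, `unk_id`,
#'   `pad_id`.
#' @export
kmer_vocab <- function(k) {
  stopifnot(k >= 1)
  structure(
    list(k = as.integer(k), size = 4L^k + 2L,
         unk_id = 4L^k, pad_id = 4L^k + 1L),
    class = "gv_vocab"
  )
}

#' Map k-mer tokens to integer ids
#'
#' Vectorized over tokens. Pad-containing tokens get the PAD id, tokens with
#' an N (but no pad) the UNK id, clean tokens their base-4 code.
#'
#' @param tokens character vector, every element of length `vocab$k`.
#' @param vocab a [kmer_vocab()].
#' @return integer vector of ids in `0 .. 4^k + 1`.
#' @export
token_id <- function(tokens, vocab) {
  stopifnot(inherits(vocab, "gv_vocab"))
  bad <- nchar(tokens) != vocab$k
  if (any(bad)) {
    stop("token_id(): tokens of wrong length (expected ", vocab$k, "): ",
         paste(utils::head(tokens[bad], 5), collapse = ", "), call. = FALSE)
  }
  ids <- rep(vocab$unk_id, length(tokens))
  has_pad <- grepl(PAD_SYMBOL, tokens, fixed = TRUE)
  clean <- !has_pad & !grepl("N", tokens, fixed = TRUE)
  ids[has_pad] <- vocab$pad_id
  if (any(clean)) {
    ids[clean] <- strtoi(chartr("ACGT", "0123", tokens[clean]), base = 4L)
  }
  ids
}

#' Serialize / restore a vocabulary as JSON
#' @param vocab a [kmer_vocab()].
#' @param path file path.
#' @export
write_vocab <- function(vocab, path) {
  jsonlite::write_json(unclass(vocab), path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_vocab
#' @export
read_vocab <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(lapply(x, as.integer), class = "gv_vocab")
}
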