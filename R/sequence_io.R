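# FASTA input/output and fixed-length windowing.
#
# Sequences live in a plain tibble (one row per record) so every downstream
# step can be piped. The alphabet after normalization is {A,C,G,T,N,0}: N is
# an unknown base, "0" is the pad symbol appended to reach fixed lengths.
# The two are kept distinct on purpose -- padding is masked out of the graph
# while N is a real (if uninformative) base.

PAD_SYMBOL <- "0"
SEQ_ALPHABET <- c("A", "C", "G", "T", "N", PAD_SYMBOL)

#' Read nucleotide sequences from a FASTA file
#'
#' Parses a (possibly multi-line) FASTA file into a tibble with one row per
#' entry, in file order. Sequences are uppercased and any letter outside
#' A/C/G/T (including the IUPAC ambiguity codes R, Y, S, W, K, M, B, D, H, V)
#' is mapped to N. Class labels may be carried in the header as a
#' `|virus` / `|host` suffix, or supplied separately via [read_labels()].
#'
#' @param path path to a FASTA file.
#' @param labels optional tibble from [read_labels()] (columns `id`, `label`)
#'   joined onto the records by `id`.
#' @return a tibble with columns `id`, `seq`, `label` (`NA` when unknown) and
#'   `source_length` (length in bp before any padding/windowing).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "acgtr", ">b|virus", "NNNN"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path, labels = NULL) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  ids <- names(set)
  seqs <- unname(as.character(set))
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop("FASTA entry with empty sequence: ",
         paste(ids[empty], collapse = ", "), call. = FALSE)
  }
  label <- rep(NA_character_, length(ids))
  tagged <- grepl("\\|(virus|host)\\s*$", ids)
  label[tagged] <- sub("^.*\\|(virus|host)\\s*$", "\\1", ids[tagged])
  ids <- sub("\\|(virus|host)\\s*$", "", ids)
  ids <- sub("\\s.*$", "", ids)
  out <- tibble::tibble(
    id = ids,
    seq = normalize_sequence(seqs),
    label = label,
    source_length = nchar(seqs)
  )
  if (!is.null(labels)) {
    out$label <- labels$label[match(out$id, labels$id)]
  }
  out
}

#' Write sequence records to FASTA
#'
#' Round-trips with [read_fasta()]: ids and sequences are preserved
#' byte-for-byte. Labels, when present, are appended to the header as a
#' `|virus` / `|host` suffix.
#'
#' @param records tibble with columns `id`, `seq` and optionally `label`.
#' @param path output path.
#' @param with_labels append the label suffix to headers (default `TRUE`
#'   when a label column with any non-missing value exists).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path,
                        with_labels = !all(is.na(records$label %||% NA))) {
  ids <- records$id
  if (isTRUE(with_labels) && !is.null(records$label)) {
    has <- !is.na(records$label)
    ids[has] <- paste0(ids[has], "|", records$label[has])
  }
  set <- Biostrings::BStringSet(records$seq)
  names(set) <- ids
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a two-column id/label TSV
#'
#' @param path TSV with columns `id` and `label` (no header required; when a
#'   header row `id<TAB>label` is present it is detected and skipped).
#' @return tibble with columns `id`, `label`.
#' @export
read_labels <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("id", "label"),
                          colClasses = "character")
  if (nrow(df) && df$id[1] == "id" && df$label[1] == "label") {
    df <- df[-1, , drop = FALSE]
  }
  bad <- !df$label %in% c("virus", "host")
  if (any(bad)) {
    stop("Unknown labels in ", path, ": ",
         paste(unique(df$label[bad]), collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' Write an id/label TSV alongside a FASTA file
#' @param records tibble with `id` and `label` columns.
#' @param path output path.
#' @export
write_labels <- function(records, path) {
  utils::write.table(records[, c("id", "label")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Normalize a nucleotide string to the working alphabet
#'
#' Uppercases and maps every letter that is not A, C, G or T (ambiguity
#' codes, gaps, stray characters) to N. The pad symbol `"0"` is preserved.
#'
#' @param x character vector of sequences.
#' @return character vector over the alphabet `A C G T N 0`.
#' @export
normalize_sequence <- function(x) {
  x <- toupper(x)
  gsub("[^ACGT0]", "N", x)
}

#' Reduce or pad records to a fixed window length
#'
#' Sequences shorter than `target_len` are suffix-padded with the pad symbol
#' `"0"`; sequences longer than `target_len` contribute one contiguous
#' window whose start offset is drawn uniformly (or taken centrally with
#' `window = "center"`). Records already at `target_len` pass through
#' unchanged, so the operation is idempotent. `source_length` always keeps
#' the pre-padding length.
#'
#' @param records tibble of sequence records (see [read_fasta()]).
#' @param target_len window length in bp (default 9000).
#' @param seed integer seed for the window draws.
#' @param window `"random"` (uniform start offset) or `"center"`.
#' @param min_length records shorter than this are rejected with an error;
#'   the finest useful graph needs at least one 90-mer.
#' @return tibble with the same columns; every `seq` has exactly
#'   `target_len` characters.
#' @export
to_fixed_window <- function(records, target_len = 9000L, seed = 1L,
                            window = c("random", "center"),
                            min_length = 90L) {
  window <- match.arg(window)
  stopifnot(target_len > 0)
  len <- nchar(records$seq)
  if (any(len < min_length)) {
    stop("Records shorter than ", min_length, " bp: ",
         paste(utils::head(records$id[len < min_length], 10), collapse = ", "),
         call. = FALSE)
  }
  out <- records
  out$source_length <- ifelse(is.na(records$source_length),
                              len, records$source_length)
  short <- len < target_len
  long <- len > target_len
  if (any(short)) {
    out$seq[short] <- paste0(
      records$seq[short],
      strrep(PAD_SYMBOL, target_len - len[short])
    )
  }
  if (any(long)) {
    starts <- integer(sum(long))
    if (window == "random") {
      withr::with_seed(seed, {
        # one uniform draw per long record over start offsets 0..len-target
        starts <- floor(runif(sum(long)) * (len[long] - target_len + 1))
      })
    } else {
      starts <- floor((len[long] - target_len) / 2)
    }
    out$seq[long] <- substr(records$seq[long], starts + 1, starts + target_len)
  }
  out
}
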