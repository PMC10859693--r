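# Two-class synthetic nucleotide sequences.
#
# Both classes are generated from order-m Markov chains. A shared base
# transition matrix is drawn once per run; each class interpolates between
# it and an independent class-specific Dirichlet draw with weight delta, so
# delta = 0 makes the two generative processes identical and larger delta
# increases the compositional divergence between classes. Optionally a set
# of 9-mer motifs is planted into the virus class at a Poisson rate of
# lambda occurrences per kb. This stands in for a real training corpus: it
# reproduces class-specific k-mer composition and enriched motifs, but has
# no gene structure, no shared homology blocks and no chimeric contigs.

#' Synthetic corpus configuration
#'
#' @param n_per_class records per class.
#' @param length either a single fixed length in bp or a `c(min, max)`
#'   range sampled uniformly per record (default 9000).
#' @param markov_order Markov chain order (default 2, capturing codon-scale
#'   bias cheaply).
#' @param delta compositional divergence in `[0, 1]`: weight of the
#'   class-specific transition matrices against the shared one.
#' @param motifs optional character vector of 9-mers planted into the virus
#'   class; when `NULL` and `motif_rate > 0`, `n_motifs` random 9-mers are
#'   drawn once per run.
#' @param motif_rate lambda, planted motif occurrences per kb (default 0).
#' @param n_motifs number of motifs drawn when `motifs` is `NULL`.
#' @param gc_offset optional extra GC bias applied to the virus class
#'   (default 0).
#' @param seed integer seed; the whole corpus is reproducible from it.
#' @return object of class `gv_sim_config`.
#' @export
synthetic_config <- function(n_per_class = 100L, length = 9000L,
                             markov_order = 2L, delta = 0,
                             motifs = NULL, motif_rate = 0, n_motifs = 4L,
                             gc_offset = 0, seed = 1L) {
  if (delta < 0 || delta > 1) {
    stop("delta must lie in [0, 1].", call. = FALSE)
  }
  if (motif_rate < 0) stop("motif_rate must be >= 0.", call. = FALSE)
  if (!length(length) %in% c(1L, 2L) || any(length < 10)) {
    stop("length must be a fixed value or a c(min, max) range.",
         call. = FALSE)
  }
  if (length(length) == 2L && length[1] > length[2]) {
    stop("Empty length range.", call. = FALSE)
  }
  structure(
    list(n_per_class = as.integer(n_per_class), length = as.integer(length),
         markov_order = as.integer(markov_order), delta = delta,
         motifs = motifs, motif_rate = motif_rate,
         n_motifs = as.integer(n_motifs), gc_offset = gc_offset,
         seed = as.integer(seed)),
    class = "gv_sim_config"
  )
}

rdirichlet_rows <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha), n,
              length(alpha), byrow = TRUE)
  g / rowSums(g)
}

#' Simulate a labeled two-class corpus
#'
#' Draws `n_per_class` sequences per class from the class Markov chains and
#' plants motifs into the virus class. The returned tibble has the standard
#' record columns; the `manifest` attribute records the transition
#' matrices, the motif set and positions, and the seed, so a run is fully
#' reproducible and auditable.
#'
#' @param cfg a [synthetic_config()].
#' @return record tibble (`id`, `seq`, `label`, `source_length`) with
#'   attribute `manifest`.
#' @export
simulate_sequences <- function(cfg) {
  stopifnot(inherits(cfg, "gv_sim_config"))
  m <- cfg$markov_order
  nctx <- 4L^m
  bases <- c("A", "C", "G", "T")

  withr::with_seed(cfg$seed, {
    shared <- rdirichlet_rows(nctx, rep(20, 4))
    class_mats <- lapply(c(host = 1, virus = 2), function(i) {
      spec <- rdirichlet_rows(nctx, rep(2, 4))
      p <- (1 - cfg$delta) * shared + cfg$delta * spec
      p / rowSums(p)
    })
    if (cfg$gc_offset != 0) {
      p <- class_mats$virus
      p[, c(2, 3)] <- p[, c(2, 3)] * (1 + cfg$gc_offset)
      class_mats$virus <- p / rowSums(p)
    }
    motifs <- cfg$motifs
    if (is.null(motifs) && cfg$motif_rate > 0) {
      motifs <- vapply(seq_len(cfg$n_motifs), function(i) {
        paste(sample(bases, 9, replace = TRUE), collapse = "")
      }, character(1))
    }

    n_tot <- 2L * cfg$n_per_class
    lens <- if (length(cfg$length) == 1L) {
      rep(cfg$length, n_tot)
    } else {
      cfg$length[1] + floor(runif(n_tot) *
                              (cfg$length[2] - cfg$length[1] + 1))
    }
    label <- rep(c("host", "virus"), each = cfg$n_per_class)
    maxlen <- max(lens)

    # vectorized chain: one draw per record per position
    chars <- matrix(0L, n_tot, maxlen)  # base codes 1..4
    chars[, seq_len(m)] <- sample.int(4L, n_tot * m, replace = TRUE)
    pmat <- rbind(class_mats$host, class_mats$virus)  # stacked by class
    class_off <- ifelse(label == "virus", nctx, 0L)
    pow <- 4L^((m - 1L):0L)
    for (pos in (m + 1L):maxlen) {
      ctx <- as.integer(chars[, (pos - m):(pos - 1L), drop = FALSE] %*%
                          pow - sum(pow) + 1L)
      rows <- pmat[class_off + ctx, , drop = FALSE]
      u <- runif(n_tot)
      cum <- rows[, 1]
      nxt <- rep(4L, n_tot)
      nxt[u < cum] <- 1L
      sel <- u >= cum; cum <- cum + rows[, 2]
      nxt[sel & u < cum] <- 2L
      sel <- u >= cum; cum <- cum + rows[, 3]
      nxt[sel & u < cum] <- 3L
      chars[, pos] <- nxt
    }

    seqs <- vapply(seq_len(n_tot), function(i) {
      paste(bases[chars[i, seq_len(lens[i])]], collapse = "")
    }, character(1))

    motif_positions <- vector("list", n_tot)
    if (!is.null(motifs) && cfg$motif_rate > 0) {
      for (i in which(label == "virus")) {
        k <- stats::rpois(1, cfg$motif_rate * lens[i] / 1000)
        if (k > 0 && lens[i] >= 9) {
          pos <- 1L + floor(runif(k) * (lens[i] - 8L))
          chosen <- motifs[1L + floor(runif(k) * length(motifs))]
          s <- seqs[i]
          for (j in seq_len(k)) {
            substr(s, pos[j], pos[j] + 8L) <- chosen[j]
          }
          seqs[i] <- s
          motif_positions[[i]] <- tibble::tibble(pos = pos, motif = chosen)
        }
      }
    }
  })

  ids <- sprintf("%s_%04d", label, c(seq_len(cfg$n_per_class),
                                     seq_len(cfg$n_per_class)))
  records <- tibble::tibble(
    id = ids, seq = seqs, label = label, source_length = lens
  )
  attr(records, "manifest") <- list(
    seed = cfg$seed, config = unclass(cfg),
    shared_matrix = shared, class_matrices = class_mats,
    motifs = motifs, motif_positions = motif_positions
  )
  records
}

#' Write a simulated corpus to disk
#'
#' Emits FASTA (labels in the headers), a sidecar id/label TSV and a
#' manifest JSON, so both label ingestion paths are exercised.
#'
#' @param records a [simulate_sequences()] result.
#' @param stem output path stem (writes `<stem>.fasta`, `<stem>.labels.tsv`,
#'   `<stem>.manifest.json`).
#' @export
write_simulation <- function(records, stem) {
  write_fasta(records, paste0(stem, ".fasta"))
  write_labels(records, paste0(stem, ".labels.tsv"))
  man <- attr(records, "manifest")
  man$motif_positions <- NULL  # tabular detail; matrices and motifs suffice
  jsonlite::write_json(man, paste0(stem, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' Small fixed fixture records for tests and examples
#'
#' A deterministic bundle covering the pipeline's edge cases: a 9000 bp
#' virus/host pair, a 500 bp pair (short mode), a 12 000 bp record (random
#' windowing), an all-N record and a minimal 90 bp record.
#'
#' @param seed integer seed.
#' @return named list of record tibbles.
#' @export
make_fixture_suite <- function(seed = 1L) {
  sim <- function(n, len, delta, extra = 0L) {
    simulate_sequences(synthetic_config(
      n_per_class = n, length = len, delta = delta,
      seed = derive_seed(seed, paste0("fix", len, extra))
    ))
  }
  all_n <- tibble::tibble(
    id = "allN_0001", seq = strrep("N", 9000), label = "host",
    source_length = 9000L
  )
  list(
    pair_9000 = sim(1L, 9000L, 0.5),
    pair_500 = sim(1L, 500L, 0.5),
    rec_12000 = sim(1L, 12000L, 0.5)[2, ],
    all_n = all_n,
    rec_90 = sim(1L, 90L, 0.5, extra = 1L)[1, ]
  )
}
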