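# Level-by-level GCN node embedding.
#
# Four two-layer GCNs are trained in sequence on bipartite corpus graphs,
# one per level pair: whole sequences / 900 bp segments, 900 bp / 90-mers,
# 90-mers / 9-mers, 9-mers / bases. Each stage's child vectors initialize
# the next stage's parent features, and each stage is supervised by the
# parent sequence's class (virus/host) through a softmax head on the
# second-layer output. The second-layer vectors (width d = 30) are the node
# embeddings.
#
# One-hot initial features over unbounded vocabularies (there is no finite
# set of 90-mer or 900 bp "types") are represented implicitly: a one-hot
# times a weight matrix is a row lookup, so child tokens carry a learned
# row table instead. At inference, vectors for novel 90-mer / 900 bp nodes
# are composed by propagating their children's vectors through the trained
# stage weights over a parent+children star graph.

#' Cascade training configuration
#'
#' @param d embedding width for every level (default 30).
#' @param hidden width of the first GCN layer (the second-layer output is
#'   the embedding; default 64).
#' @param epochs,lr,batch Adam training schedule (defaults 200 epochs,
#'   learning rate 0.003, batch of 200 parent nodes per step).
#' @param tol,patience early stop when the relative change of the epoch
#'   loss stays below `tol` for `patience` epochs (defaults 1e-4, 10).
#' @param max_parents cap on the number of parent nodes per stage (parents
#'   are subsampled with the stage seed when exceeded); `Inf` to disable.
#' @param tfidf weight parent-child edges by TF-IDF over token occurrences
#'   (default); `FALSE` uses binary weights.
#' @param mode `"cascade"` trains all four stages level by level;
#'   `"flat"` trains only the finest stage (9-mer/base) and forms
#'   higher-level vectors by degree-normalized child averaging (the flat
#'   ablation).
#' @return object of class `gv_cascade_config`.
#' @export
cascade_config <- function(d = 30L, hidden = 64L, epochs = 200L, lr = 0.003,
                           batch = 200L, tol = 1e-4, patience = 10L,
                           max_parents = Inf, tfidf = TRUE,
                           mode = c("cascade", "flat")) {
  mode <- match.arg(mode)
  stopifnot(d >= 2, hidden >= 1, epochs >= 0, lr > 0, batch >= 1)
  structure(
    list(d = as.integer(d), hidden = as.integer(hidden),
         epochs = as.integer(epochs), lr = lr, batch = as.integer(batch),
         tol = tol, patience = as.integer(patience),
         max_parents = max_parents, tfidf = isTRUE(tfidf), mode = mode),
    class = "gv_cascade_config"
  )
}

# Symmetric degree normalization of an adjacency with self-loops added:
# D^{-1/2} (A + I) D^{-1/2}.
normalize_adjacency <- function(adj) {
  n <- nrow(adj)
  a <- adj + Matrix::Diagonal(n)
  deg <- Matrix::rowSums(a)
  dinv <- 1 / sqrt(deg)
  Matrix::Diagonal(n, dinv) %*% a %*% Matrix::Diagonal(n, dinv)
}

#' One graph convolution layer
#'
#' Computes `activation(Ahat %*% features %*% weights)` where `Ahat` is the
#' symmetrically degree-normalized adjacency with self-loops. The first
#' layer of each two-layer stage uses ReLU, the second the identity.
#'
#' @param features node-by-width feature matrix.
#' @param adjacency square sparse/dense weighted adjacency over the same
#'   nodes (self-loops are added internally).
#' @param weights width-by-out weight matrix.
#' @param activation `"relu"` or `"identity"`.
#' @return node-by-out matrix.
#' @export
gcn_layer <- function(features, adjacency, weights,
                      activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  stopifnot(nrow(adjacency) == nrow(features),
            ncol(features) == nrow(weights))
  ahat <- normalize_adjacency(adjacency)
  out <- as.matrix(ahat %*% features %*% weights)
  if (activation == "relu") out <- pmax(out, 0)
  out
}

# ---------------------------------------------------------------------------
# Corpus graphs

# Occurrence pairs (parent token, child token) for one level pair, pooled
# over a list of decompositions. Fully padded segments are dropped; 9-mers
# containing N collapse onto a single UNK token at the child side.
stage_pairs <- function(decomps, labels, parent_level, child_level) {
  fan <- if (parent_level == "seq") {
    NA_integer_
  } else {
    LEVEL_WIDTHS[[parent_level]] %/% LEVEL_WIDTHS[[child_level]]
  }
  res <- lapply(seq_along(decomps), function(i) {
    d <- decomps[[i]]
    if (parent_level == "seq") {
      par_tok <- paste(d$levels$base, collapse = "")
      par_of_child <- rep(1L, length(d$levels$`900`))
      child_tok <- d$levels$`900`
      child_pad <- d$pad_mask$`900`
      par_tok_of <- rep(par_tok, length(child_tok))
    } else {
      child_tok <- d$levels[[child_level]]
      child_pad <- d$pad_mask[[child_level]]
      par_idx <- (seq_along(child_tok) - 1L) %/% fan + 1L
      par_tok_of <- d$levels[[parent_level]][par_idx]
      par_pad <- d$pad_mask[[parent_level]][par_idx]
      child_pad <- child_pad | par_pad
    }
    keep <- !child_pad
    tibble::tibble(parent = par_tok_of[keep], child = child_tok[keep],
                   label = labels[i])
  })
  out <- dplyr::bind_rows(res)
  if (child_level == "9") {
    out$child[grepl("N", out$child, fixed = TRUE)] <- "UNK"
  }
  if (child_level == "base") {
    # no pad bases reach here; N stays its own token
  }
  out
}

# Assemble a bipartite corpus graph from occurrence pairs. Parents are
# deduplicated by token (label by majority); children by token. Edge weight
# is the within-parent occurrence count, TF-IDF scaled when requested.
build_corpus_graph <- function(pairs, tfidf = TRUE, max_parents = Inf,
                               seed = 1L) {
  lab <- dplyr::summarise(
    dplyr::group_by(pairs, .data$parent),
    label = names(sort(table(.data$label), decreasing = TRUE))[1],
    .groups = "drop"
  )
  if (is.finite(max_parents) && nrow(lab) > max_parents) {
    withr::with_seed(seed, {
      lab <- lab[sort(sample.int(nrow(lab), max_parents)), ]
    })
    pairs <- pairs[pairs$parent %in% lab$parent, , drop = FALSE]
  }
  counts <- dplyr::count(pairs, .data$parent, .data$child, name = "tf")
  parents <- lab$parent
  children <- sort(unique(counts$child))
  pi <- match(counts$parent, parents)
  ci <- match(counts$child, children)
  w <- as.numeric(counts$tf)
  if (tfidf) {
    df <- tabulate(ci, nbins = length(children))
    idf <- log((1 + length(parents)) / (1 + df)) + 1
    w <- w * idf[ci]
  }
  structure(
    list(parents = parents, labels = lab$label, children = children,
         edges = tibble::tibble(parent = pi, child = ci, weight = w)),
    class = "gv_corpus"
  )
}

# ---------------------------------------------------------------------------
# Stage training

#' Train one embedding stage
#'
#' Trains a two-layer GCN plus softmax head on a bipartite parent/child
#' corpus graph with cross-entropy on the parent class labels, using Adam.
#' Parent initial features come from the previous stage (`parent_init`);
#' when `NULL` (first stage) a learned row per parent token is used. Child
#' features are always a learned row table. The second-layer vectors of the
#' child nodes are the stage's output embeddings.
#'
#' @param corpus a corpus graph (internal class `gv_corpus`).
#' @param cfg a [cascade_config()].
#' @param parent_init optional matrix (n_parents x d) of fixed parent
#'   features from the previous stage.
#' @param seed integer seed; training is deterministic given the seed.
#' @return list with `weights` (`W1`, `W2`, `Wc`, `bc`), `child_vectors`,
#'   `parent_vectors`, `loss_trace`, `children`, `parents`.
#' @export
train_embedding_stage <- function(corpus, cfg = cascade_config(),
                                  parent_init = NULL, seed = 1L) {
  stopifnot(inherits(corpus, "gv_corpus"))
  classes <- c("host", "virus")
  y <- match(corpus$labels, classes)
  if (length(unique(y)) < 2) {
    stop("Embedding stage needs parents from both classes.", call. = FALSE)
  }
  np <- length(corpus$parents)
  nc <- length(corpus$children)
  n <- np + nc
  d <- cfg$d

  adj <- Matrix::sparseMatrix(
    i = c(corpus$edges$parent, corpus$edges$child + np),
    j = c(corpus$edges$child + np, corpus$edges$parent),
    x = rep(corpus$edges$weight, 2),
    dims = c(n, n)
  )
  ahat <- normalize_adjacency(adj)

  withr::with_seed(seed, {
    params <- list(
      E_child = matrix(rnorm(nc * d, sd = 0.1), nc, d),
      W1 = glorot(d, cfg$hidden),
      W2 = glorot(cfg$hidden, d),
      Wc = glorot(d, 2L),
      bc = numeric(2)
    )
    if (is.null(parent_init)) {
      params$E_par <- matrix(rnorm(np * d, sd = 0.1), np, d)
    }
    perm_seeds <- sample.int(.Machine$integer.max, max(cfg$epochs, 1))
  })

  x_of <- function(p) {
    rbind(if (is.null(parent_init)) p$E_par else parent_init, p$E_child)
  }
  forward <- function(p) {
    x <- x_of(p)
    m1 <- as.matrix(ahat %*% x)
    z1 <- pmax(m1 %*% p$W1, 0)
    m2 <- as.matrix(ahat %*% z1)
    z2 <- m2 %*% p$W2
    list(x = x, m1 = m1, z1 = z1, m2 = m2, z2 = z2)
  }

  opt <- adam_init(params)
  trace <- numeric(0)
  yhot <- diag(2)[y, , drop = FALSE]

  if (cfg$epochs > 0) {
    for (epoch in seq_len(cfg$epochs)) {
      withr::with_seed(perm_seeds[epoch], perm <- sample.int(np))
      starts <- seq.int(1L, np, by = cfg$batch)
      ep_loss <- 0
      for (s in starts) {
        bp <- perm[s:min(s + cfg$batch - 1L, np)]
        fw <- forward(params)
        logits <- sweep(fw$z2[bp, , drop = FALSE] %*% params$Wc, 2,
                        params$bc, `+`)
        pr <- softmax_rows(logits)
        loss <- -mean(log(pmax(pr[cbind(seq_along(bp), y[bp])], 1e-12)))
        ep_loss <- ep_loss + loss * length(bp)

        dlogits <- (pr - yhot[bp, , drop = FALSE]) / length(bp)
        grads <- list(
          Wc = t(fw$z2[bp, , drop = FALSE]) %*% dlogits,
          bc = colSums(dlogits)
        )
        dz2 <- matrix(0, n, d)
        dz2[bp, ] <- dlogits %*% t(params$Wc)
        grads$W2 <- t(fw$m2) %*% dz2
        dm2 <- dz2 %*% t(params$W2)
        dz1 <- as.matrix(ahat %*% dm2)
        dpre <- dz1 * (fw$z1 > 0)
        grads$W1 <- t(fw$m1) %*% dpre
        dm1 <- dpre %*% t(params$W1)
        dx <- as.matrix(ahat %*% dm1)
        grads$E_child <- dx[(np + 1L):n, , drop = FALSE]
        if (is.null(parent_init)) {
          grads$E_par <- dx[seq_len(np), , drop = FALSE]
        }
        upd <- adam_step(params, grads, opt, cfg$lr)
        params <- upd$params
        opt <- upd$state
      }
      trace <- c(trace, ep_loss / np)
      if (length(trace) > cfg$patience) {
        recent <- trace[(length(trace) - cfg$patience):length(trace)]
        if (max(abs(diff(recent))) / max(abs(recent[1]), 1e-12) < cfg$tol) {
          break
        }
      }
    }
  }

  fw <- forward(params)
  list(
    weights = params[c("W1", "W2", "Wc", "bc")],
    child_vectors = fw$z2[(np + 1L):n, , drop = FALSE],
    parent_vectors = fw$z2[seq_len(np), , drop = FALSE],
    loss_trace = trace,
    children = corpus$children,
    parents = corpus$parents
  )
}

# ---------------------------------------------------------------------------
# Cascade

#' Train the full embedding cascade
#'
#' Decomposes the (padded/windowed) training records and trains the stages
#' in order, coarse to fine: sequence/900 bp, 900 bp/90-mer, 90-mer/9-mer,
#' 9-mer/base. Each stage's child vectors become the next stage's fixed
#' parent features. The reusable artifacts are the base vector table, the
#' observed 9-mer vector table (with an UNK vector for unseen or ambiguous
#' 9-mers and a zero PAD vector) and the stage weights used to compose
#' vectors for novel 90-mer / 900 bp nodes at inference time.
#'
#' @param records labeled record tibble (columns `id`, `seq`, `label`);
#'   sequences are windowed/padded to 9000 bp internally.
#' @param cfg a [cascade_config()].
#' @param seed integer seed controlling every random draw.
#' @return object of class `gv_embeddings`.
#' @export
run_cascade <- function(records, cfg = cascade_config(), seed = 1L) {
  stopifnot(all(records$label %in% c("virus", "host")))
  recs <- to_fixed_window(records, 9000L, seed = derive_seed(seed, "window"))
  decomps <- lapply(recs$seq, decompose_sequence)
  labels <- recs$label
  d <- cfg$d
  vocab9 <- kmer_vocab(9L)

  stage_defs <- list(
    list(name = "stage1", parent = "seq", child = "900"),
    list(name = "stage2", parent = "900", child = "90"),
    list(name = "stage3", parent = "90", child = "9"),
    list(name = "stage4", parent = "9", child = "base")
  )
  run_idx <- if (cfg$mode == "flat") 4L else seq_len(4L)

  stages <- list()
  traces <- list()
  prev_children <- NULL
  prev_vectors <- NULL
  for (si in run_idx) {
    def <- stage_defs[[si]]
    pairs <- stage_pairs(decomps, labels, def$parent, def$child)
    if (!is.null(prev_children)) {
      # chain: this stage's parents are the previous stage's children
      pairs <- pairs[pairs$parent %in% prev_children, , drop = FALSE]
    }
    corpus <- build_corpus_graph(
      pairs, tfidf = cfg$tfidf, max_parents = cfg$max_parents,
      seed = derive_seed(seed, paste0("cap", si))
    )
    parent_init <- NULL
    if (!is.null(prev_children)) {
      parent_init <- prev_vectors[match(corpus$parents, prev_children), ,
                                  drop = FALSE]
    }
    st <- train_embedding_stage(corpus, cfg, parent_init = parent_init,
                                seed = derive_seed(seed, def$name))
    stages[[def$name]] <- st
    traces[[def$name]] <- st$loss_trace
    prev_children <- st$children
    prev_vectors <- st$child_vectors
  }

  # base table: rows A, C, G, T, N, PAD (PAD fixed at zero)
  st4 <- stages$stage4
  base_table <- matrix(0, length(SEQ_ALPHABET), d,
                       dimnames = list(SEQ_ALPHABET, NULL))
  seen <- match(c("A", "C", "G", "T", "N"), st4$children)
  for (i in seq_along(seen)) {
    if (!is.na(seen[i])) {
      base_table[i, ] <- st4$child_vectors[seen[i], ]
    }
  }
  if (is.na(seen[5])) {  # no N observed: UNK base = mean of observed bases
    obs <- seen[!is.na(seen)]
    if (length(obs)) base_table["N", ] <- colMeans(
      st4$child_vectors[obs, , drop = FALSE])
  }

  # 9-mer table
  if (cfg$mode == "flat") {
    tokens <- st4$parents
    vecs <- st4$parent_vectors
  } else {
    tokens <- stages$stage3$children
    vecs <- stages$stage3$child_vectors
  }
  is_unk <- tokens == "UNK"
  clean <- !is_unk
  ids <- token_id(tokens[clean], vocab9)
  o <- order(ids)
  unk <- if (any(is_unk)) {
    vecs[which(is_unk)[1], ]
  } else {
    colMeans(vecs[clean, , drop = FALSE])
  }

  # fix the overall feature scale: cascade outputs are unbounded and their
  # magnitude varies run to run, while the classifier initialization
  # assumes O(1) inputs. ReLU propagation is positively homogeneous, so a
  # single global rescale carries exactly through the compositional
  # inference of 90-mer/900 bp vectors.
  kmat <- vecs[clean, , drop = FALSE][o, , drop = FALSE]
  scale <- mean(sqrt(rowSums(kmat^2)))
  if (!is.finite(scale) || scale <= 0) scale <- 1
  base_table <- base_table / scale

  structure(
    list(
      d = d,
      mode = cfg$mode,
      base_table = base_table,
      kmer9 = list(ids = ids[o], mat = kmat / scale, unk = unk / scale),
      stage_weights = if (cfg$mode == "flat") NULL else list(
        `90` = stages$stage3$weights[c("W1", "W2")],
        `900` = stages$stage2$weights[c("W1", "W2")]
      ),
      loss_traces = traces,
      cfg = cfg,
      seed = seed,
      hash = config_hash(list(cfg, seed))
    ),
    class = "gv_embeddings"
  )
}

#' @export
#' @method print gv_embeddings
print.gv_embeddings <- function(x, ...) {
  cat("<gv_embeddings> d=", x$d, ", mode=", x$mode, ", ",
      length(x$kmer9$ids), " observed 9-mers, hash ", x$hash, "\n", sep = "")
  invisible(x)
}

# Closed-form two-layer GCN propagation over parent+children star graphs,
# vectorized across parents. Children carry `feats`, the parent slot is
# zero; weights are per-child multiplicities. Returns the parents' second
# layer vectors.
gcn_compose_star <- function(feats, parent, w, W1, W2, n_parents) {
  degp <- 1 + rowsum_vec(w, parent, n_parents)
  degc <- 1 + w
  apc <- w / sqrt(degp[parent] * degc)
  sp <- rowsum_mat(feats * apc, parent, n_parents)
  z1p <- pmax(sp %*% W1, 0)
  z1c <- pmax((feats / degc) %*% W1, 0)
  agg <- rowsum_mat(z1c * apc, parent, n_parents)
  ((1 / degp) * z1p + agg) %*% W2
}

#' Initialize graph node features from trained embeddings
#'
#' Base nodes take rows of the base table; 9-mer nodes look up the observed
#' 9-mer table (UNK vector for unseen or ambiguous tokens); 90-mer and
#' 900 bp nodes are composed from their children's vectors through the
#' trained stage weights (or by child averaging in flat mode). Fully padded
#' nodes get the zero vector.
#'
#' @param g a [build_graph()] result.
#' @param tables a [run_cascade()] result.
#' @return `g` with the `features` slot set (matrix, nodes x d, rows in
#'   `node_id` order).
#' @export
init_node_features <- function(g, tables) {
  stopifnot(inherits(g, "gv_graph"), inherits(tables, "gv_embeddings"))
  d <- tables$d
  n <- nrow(g$nodes)
  feats <- matrix(0, n, d)
  nodes <- g$nodes
  vocab9 <- kmer_vocab(9L)

  bi <- which(nodes$level == "base" & !nodes$pad)
  if (length(bi)) {
    feats[bi, ] <- tables$base_table[match(nodes$token[bi], SEQ_ALPHABET), ,
                                     drop = FALSE]
  }

  ki <- which(nodes$level == "9" & !nodes$pad)
  if (length(ki)) {
    ids <- token_id(nodes$token[ki], vocab9)
    row <- match(ids, tables$kmer9$ids)
    hit <- !is.na(row) & ids < vocab9$unk_id
    if (any(hit)) {
      feats[ki[hit], ] <- tables$kmer9$mat[row[hit], , drop = FALSE]
    }
    if (any(!hit)) {
      feats[ki[!hit], ] <- matrix(tables$kmer9$unk, sum(!hit), d,
                                  byrow = TRUE)
    }
  }

  compose_level <- function(level, child_level, weights) {
    pi <- which(nodes$level == level & !nodes$pad)
    if (!length(pi)) return()
    fan <- LEVEL_WIDTHS[[level]] %/% LEVEL_WIDTHS[[child_level]]
    child_rows <- which(nodes$level == child_level)
    # children of parent pos t are child positions fan*t .. fan*t+fan-1
    cp <- nodes$pos[child_rows]
    par_pos <- cp %/% fan
    keep <- !nodes$pad[child_rows] & (par_pos %in% nodes$pos[pi])
    cr <- child_rows[keep]
    pidx <- match(par_pos[keep], nodes$pos[pi])
    # collapse identical child tokens within a parent into count weights
    key <- paste(pidx, nodes$token[cr])
    first <- !duplicated(key)
    wts <- as.numeric(table(key)[key[first]])
    cfeat <- feats[cr[first], , drop = FALSE]
    pgrp <- pidx[first]
    if (is.null(weights)) {
      wsum <- rowsum_vec(wts, pgrp, length(pi))
      feats[pi, ] <<- rowsum_mat(cfeat * wts, pgrp, length(pi)) / wsum
    } else {
      feats[pi, ] <<- gcn_compose_star(cfeat, pgrp, wts, weights$W1,
                                       weights$W2, length(pi))
    }
  }
  compose_level("90", "9", tables$stage_weights$`90`)
  compose_level("900", "90", tables$stage_weights$`900`)

  g$features <- feats
  g$embedding_hash <- tables$hash
  g
}
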