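# Independent oracles and small fixtures used across the test files.
# Everything here is written as a direct, literal transcription of the
# rules being tested (loops, dense matrices), deliberately avoiding the
# package's own vectorized implementations.

random_dna <- function(n, seed = 1) {
  withr::with_seed(seed,
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""))
}

labeled_records <- function(n_per_class, len, seed = 1, delta = 0.6,
                            motif_rate = 5) {
  simulate_sequences(synthetic_config(
    n_per_class = n_per_class, length = len, delta = delta,
    motif_rate = motif_rate, seed = seed
  ))
}

# Tiny trained pipeline shared by classifier tests (built once per run).
tiny_pipeline <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      recs <- labeled_records(12, 900, seed = 401)
      tables <- run_cascade(recs, cascade_config(epochs = 8,
                                                 max_parents = 300),
                            seed = 402)
      fit <- train_classifier(recs, tables,
                              classifier_config(epochs = 4, lr = 0.002,
                                                batch = 8),
                              seed = 403)
      cache <<- list(records = recs, tables = tables, fit = fit)
    }
    cache
  }
})

# --- brute-force edge enumeration oracle -----------------------------------

# Enumerates the typed edge set of the multilayer graph by explicit loops
# over the textual rules. Nodes are identified as "level:pos". Returns a
# sorted character vector "src|dst|type".
oracle_edge_set <- function(seq, k = 4, spans = c(E2 = 10, E3 = 6, E4 = 3),
                            bidirectional = TRUE) {
  n <- nchar(seq)
  chars <- strsplit(seq, "")[[1]]
  seg <- function(width) {
    m <- n %/% width
    vapply(seq_len(m) - 1, function(t) {
      paste(chars[(t * width + 1):((t + 1) * width)], collapse = "")
    }, character(1))
  }
  has900 <- n >= 900
  segs <- list(`900` = if (has900) seg(900) else character(0),
               `90` = seg(90), `9` = seg(9), base = chars)
  padded <- lapply(segs, function(x) {
    vapply(x, function(s) all(strsplit(s, "")[[1]] == "0"), logical(1))
  })
  acc <- vector("list", 600000)
  cnt <- 0L
  add <- function(lv1, p1, lv2, p2, type, both) {
    cnt <<- cnt + 1L
    acc[[cnt]] <<- paste0(lv1, ":", p1, "|", lv2, ":", p2, "|", type)
    if (both) {
      cnt <<- cnt + 1L
      acc[[cnt]] <<- paste0(lv2, ":", p2, "|", lv1, ":", p1, "|", type)
    }
  }
  # direct edges (dropped only when both endpoints are padding)
  fan_pairs <- list(c("900", "90", 10), c("90", "9", 10), c("9", "base", 9))
  for (fp in fan_pairs) {
    np <- length(segs[[fp[1]]])
    if (np == 0) next
    for (c_pos in seq_along(segs[[fp[2]]]) - 1) {
      p_pos <- c_pos %/% as.integer(fp[3])
      if (padded[[fp[1]]][p_pos + 1] && padded[[fp[2]]][c_pos + 1]) next
      add(fp[1], p_pos, fp[2], c_pos, "direct", bidirectional)
    }
  }
  # E1 local edges
  for (i in seq_len(n) - 1) {
    if (padded$base[i + 1]) next
    for (j in (i - k):(i + k)) {
      if (j < 0 || j >= n || j == i) next
      if (padded$base[j + 1]) next
      add("base", i, "base", j, "E1", FALSE)
    }
  }
  # E2/E3/E4 segment edges
  for (p in seq_len(n) - 1) {
    if (padded$base[p + 1]) next
    for (t in (p %/% 9) + 0:(spans[["E2"]] - 1)) {
      if (t >= length(segs$`9`) || padded$`9`[t + 1]) next
      add("base", p, "9", t, "E2", bidirectional)
    }
    for (t in (p %/% 90) + 1:spans[["E3"]]) {
      if (t >= length(segs$`90`) || padded$`90`[t + 1]) next
      add("base", p, "90", t, "E3", bidirectional)
    }
    if (has900) {
      for (t in (p %/% 900) + 1:spans[["E4"]]) {
        if (t >= length(segs$`900`) || padded$`900`[t + 1]) next
        add("base", p, "900", t, "E4", bidirectional)
      }
    }
  }
  sort(unlist(acc[seq_len(cnt)]))
}

# Edge set of a built graph in the oracle's "src|dst|type" key format.
graph_edge_set <- function(g) {
  lab <- paste0(g$nodes$level, ":", g$nodes$pos)
  sort(paste0(lab[g$edges$src + 1], "|", lab[g$edges$dst + 1], "|",
              as.character(g$edges$type)))
}

# --- dense GCN oracle ------------------------------------------------------

# Literal dense computation of one GCN layer with self-loops and symmetric
# normalization.
dense_gcn_layer <- function(X, A, W, relu = TRUE) {
  A2 <- as.matrix(A) + diag(nrow(A))
  dinv <- diag(1 / sqrt(rowSums(A2)))
  out <- dinv %*% A2 %*% dinv %*% X %*% W
  if (relu) out[out < 0] <- 0
  out
}

# --- dense masked attention oracle -----------------------------------------

# Full N x N masked multi-head attention with relative-position terms,
# computed row by row.
dense_gsa <- function(H, edges, params, use_relpos = TRUE) {
  n <- nrow(H)
  d <- params$d
  dh <- params$dh
  out <- H
  heads <- matrix(0, n, d)
  has_nbr <- rep(FALSE, n)
  for (i in seq_len(params$heads)) {
    cols <- ((i - 1) * dh + 1):(i * dh)
    Q <- H %*% params$Wq[, cols]
    K <- H %*% params$Wk[, cols]
    V <- H %*% params$Wv[, cols]
    logits <- matrix(-Inf, n, n)
    for (e in seq_len(nrow(edges))) {
      u <- edges$src[e]; v <- edges$dst[e]
      key <- K[v, ]
      if (use_relpos) key <- key + params$R[edges$rel_row[e], cols]
      logits[u, v] <- sum(Q[u, ] * key) / sqrt(d)
    }
    for (u in seq_len(n)) {
      row <- logits[u, ]
      if (all(is.infinite(row) & row < 0)) next
      has_nbr[u] <- TRUE
      w <- exp(row - max(row[is.finite(row)]))
      w[!is.finite(row)] <- 0
      w <- w / sum(w)
      heads[u, cols] <- colSums(V * w)
    }
  }
  upd <- heads %*% params$Wo
  out[has_nbr, ] <- upd[has_nbr, ]
  out
}

# Random edge arrays on n nodes for oracle comparisons.
random_graph_arrays <- function(n, n_edges, rel_rows, seed) {
  withr::with_seed(seed, {
    src <- sample(n, n_edges, replace = TRUE)
    dst <- sample(n, n_edges, replace = TRUE)
    keep <- src != dst
    src <- src[keep]; dst <- dst[keep]
    dd <- !duplicated(paste(src, dst))
    rel <- sample(rel_rows, sum(dd), replace = TRUE)
  })
  list(src = src[dd], dst = dst[dd], rel_row = rel)
}
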