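test_that("gcn_layer matches a dense oracle on small graphs", {
  for (seed in 1:10) {
    withr::with_seed(seed, {
      n <- sample(3:20, 1)
      X <- matrix(rnorm(n * 5), n, 5)
      W <- matrix(rnorm(5 * 4), 5, 4)
      A <- matrix(rbinom(n * n, 1, 0.3), n, n)
      A[lower.tri(A)] <- t(A)[lower.tri(A)]
      diag(A) <- 0
    })
    As <- methods::as(Matrix::Matrix(A, sparse = TRUE), "generalMatrix")
    expect_equal(gcn_layer(X, As, W, "relu"),
                 dense_gcn_layer(X, A, W, relu = TRUE), tolerance = 1e-6)
    expect_equal(gcn_layer(X, As, W, "identity"),
                 dense_gcn_layer(X, A, W, relu = FALSE), tolerance = 1e-6)
  }
})

test_that("gcn_layer degenerate cases: lone self-loop and zero features", {
  x <- matrix(c(-1, 2, 3), 1, 3)
  A <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                            dims = c(1, 1))
  expect_equal(gcn_layer(x, A, diag(3), "relu"), pmax(x, 0))
  X0 <- matrix(0, 4, 3)
  A4 <- Matrix::sparseMatrix(i = c(1, 2), j = c(2, 1), x = 1, dims = c(4, 4))
  expect_equal(gcn_layer(X0, A4, matrix(rnorm(9), 3, 3)),
               matrix(0, 4, 3))
})

test_that("stage training reduces the loss and is seed-deterministic", {
  recs <- labeled_records(10, 900, seed = 31)
  decomps <- lapply(graphvir:::prepare_records(recs, 1)$seq,
                    decompose_sequence)
  pairs <- graphvir:::stage_pairs(decomps, recs$label, "90", "9")
  corpus <- graphvir:::build_corpus_graph(pairs, max_parents = 100,
                                          seed = 1)
  cfg <- cascade_config(epochs = 30, batch = 50)
  st <- train_embedding_stage(corpus, cfg, seed = 5)
  expect_lt(utils::tail(st$loss_trace, 1), st$loss_trace[1])
  expect_equal(ncol(st$child_vectors), 30L)

  st2 <- train_embedding_stage(corpus, cfg, seed = 5)
  expect_identical(st$weights, st2$weights)
  expect_identical(st$child_vectors, st2$child_vectors)

  st0 <- train_embedding_stage(corpus, cascade_config(epochs = 0), seed = 5)
  expect_length(st0$loss_trace, 0)

  bad <- corpus
  bad$labels[] <- "virus"
  expect_error(train_embedding_stage(bad, cfg, seed = 1), "both classes")
})

test_that("cascade produces 30-wide tables with correct bookkeeping", {
  recs <- labeled_records(8, 900, seed = 33)
  tab <- run_cascade(recs, cascade_config(epochs = 6, max_parents = 200),
                     seed = 34)
  expect_equal(ncol(tab$base_table), 30L)
  expect_equal(ncol(tab$kmer9$mat), 30L)
  expect_equal(unname(tab$base_table["0", ]), rep(0, 30))  # PAD row frozen
  expect_true(all(is.finite(tab$kmer9$mat)))
  # observed 9-mer ids are exactly the clean 9-mers of the training set
  v9 <- kmer_vocab(9L)
  seen <- sort(unique(unlist(lapply(
    graphvir:::prepare_records(recs, 1)$seq,
    function(s) token_id(decompose_sequence(s)$levels$`9`, v9)
  ))))
  seen <- seen[seen < v9$unk_id]
  expect_setequal(tab$kmer9$ids, seen)
  expect_true(any(tab$kmer9$mat != 0))
})

test_that("flat mode trains only the finest stage", {
  recs <- labeled_records(8, 900, seed = 35)
  tab <- run_cascade(recs, cascade_config(epochs = 6, max_parents = 200,
                                          mode = "flat"), seed = 36)
  expect_identical(tab$mode, "flat")
  expect_null(tab$stage_weights)
  expect_named(tab$loss_traces, "stage4")
  expect_equal(ncol(tab$kmer9$mat), 30L)
})

test_that("node features: padding, purity, and compositional consistency", {
  recs <- labeled_records(6, 900, seed = 37)
  tab <- run_cascade(recs, cascade_config(epochs = 5, max_parents = 200),
                     seed = 38)

  s <- pad_to_multiple(random_dna(950, 39), 9000L)
  g <- init_node_features(build_graph(decompose_sequence(s)), tab)
  expect_true(all(g$features[g$nodes$pad, ] == 0))
  g2 <- init_node_features(build_graph(decompose_sequence(s)), tab)
  expect_identical(g$features, g2$features)  # pure function

  # repeated 90 bp block gives identical 90-mer vectors at every occurrence
  block <- random_dna(90, 40)
  rep_seq <- strrep(block, 10)
  gr <- init_node_features(build_graph(decompose_sequence(rep_seq)), tab)
  f90 <- gr$features[gr$nodes$level == "90", ]
  expect_equal(f90, f90[rep(1, 10), ], tolerance = 1e-12)

  # 90-mer composition equals the dense star-graph oracle over its children
  gi <- init_node_features(build_graph(decompose_sequence(block)), tab)
  kids <- gi$features[gi$nodes$level == "9", ]
  toks <- gi$nodes$token[gi$nodes$level == "9"]
  keep <- !duplicated(toks)
  w <- as.numeric(table(toks)[toks[keep]])
  m <- sum(keep)
  A <- matrix(0, m + 1, m + 1)
  A[1, 2:(m + 1)] <- w
  A[2:(m + 1), 1] <- w
  X <- rbind(0, kids[keep, , drop = FALSE])
  z1 <- dense_gcn_layer(X, A, tab$stage_weights$`90`$W1, relu = TRUE)
  z2 <- dense_gcn_layer(z1, A, tab$stage_weights$`90`$W2, relu = FALSE)
  got <- gi$features[gi$nodes$level == "90", , drop = FALSE]
  expect_equal(unname(got[1, ]), unname(z2[1, ]), tolerance = 1e-8)
})

test_that("cascade is reproducible under a fixed seed", {
  recs <- labeled_records(5, 900, seed = 41)
  t1 <- run_cascade(recs, cascade_config(epochs = 4, max_parents = 100),
                    seed = 42)
  t2 <- run_cascade(recs, cascade_config(epochs = 4, max_parents = 100),
                    seed = 42)
  expect_identical(t1$base_table, t2$base_table)
  expect_identical(t1$kmer9, t2$kmer9)
  expect_identical(t1$stage_weights, t2$stage_weights)
})

test_that("a separable toy corpus is fit to high training accuracy", {
  # two classes with disjoint child token usage are linearly separable
  pairs <- tibble::tibble(
    parent = rep(sprintf("p%02d", 1:20), each = 4),
    child = c(replicate(10, paste0("tA", sample(1:4))),
              replicate(10, paste0("tB", sample(1:4)))),
    label = rep(c("virus", "host"), each = 40)
  )
  corpus <- graphvir:::build_corpus_graph(pairs)
  st <- train_embedding_stage(corpus, cascade_config(epochs = 150,
                                                     batch = 20,
                                                     patience = 200),
                              seed = 7)
  logits <- st$parent_vectors %*% st$weights$Wc
  pred <- ifelse(logits[, 2] + st$weights$bc[2] >
                   logits[, 1] + st$weights$bc[1], "virus", "host")
  expect_gte(mean(pred == corpus$labels), 0.95)
  expect_lt(utils::tail(st$loss_trace, 1), 0.2)
})
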