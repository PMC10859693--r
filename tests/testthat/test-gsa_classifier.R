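test_that("attention matches the dense masked oracle on random graphs", {
  p <- gsa_params(d = 12, heads = 3, rel_clip = 5, seed = 51)
  for (seed in 1:12) {
    n <- 5 + (seed %% 6) * 8
    ed <- random_graph_arrays(n, 4 * n, rel_rows = 1:11, seed = 60 + seed)
    withr::with_seed(70 + seed, H <- matrix(rnorm(n * 12), n, 12))
    for (relpos in c(TRUE, FALSE)) {
      fast <- graphvir:::attend_forward(H, ed$src, ed$dst, ed$rel_row, p,
                                        use_relpos = relpos)$U
      dense <- dense_gsa(H, tibble::tibble(src = ed$src, dst = ed$dst,
                                           rel_row = ed$rel_row), p,
                         use_relpos = relpos)
      expect_equal(fast, dense, tolerance = 1e-6)
    }
  }
})

test_that("attention weights are a proper distribution over neighbors", {
  p <- gsa_params(d = 12, heads = 3, rel_clip = 5, seed = 52)
  ed <- random_graph_arrays(20, 100, 1:11, seed = 53)
  withr::with_seed(54, H <- matrix(rnorm(240), 20, 12))
  fw <- graphvir:::attend_forward(H, ed$src, ed$dst, ed$rel_row, p)
  for (alpha in fw$cache$alphas) {
    expect_true(all(alpha >= 0))
    sums <- tapply(alpha, fw$cache$si, sum)
    expect_equal(as.numeric(sums), rep(1, length(sums)), tolerance = 1e-12)
  }
})

test_that("singleton and constant-key neighborhoods behave analytically", {
  d <- 12
  p <- gsa_params(d = d, heads = 3, rel_clip = 5, seed = 55)
  withr::with_seed(56, H <- matrix(rnorm(5 * d), 5, d))
  # one neighbor: weight 1, output = neighbor value projection through Wo
  fw <- graphvir:::attend_forward(H, src = 2L, dst = 4L, rel_row = 6L, p,
                                  use_relpos = FALSE)
  v <- unlist(lapply(1:3, function(i) {
    H[4, ] %*% p$Wv[, ((i - 1) * 4 + 1):(i * 4)]
  }))
  expect_equal(fw$U[2, ], as.numeric(v %*% p$Wo), tolerance = 1e-10)
  expect_equal(fw$U[1, ], H[1, ])  # untouched node passes through

  # identical keys/values: uniform weights regardless of query
  Hc <- H
  Hc[3, ] <- Hc[4, ]
  Hc[5, ] <- Hc[4, ]
  fw2 <- graphvir:::attend_forward(Hc, src = c(1L, 1L, 1L),
                                   dst = c(3L, 4L, 5L),
                                   rel_row = c(6L, 6L, 6L), p,
                                   use_relpos = FALSE)
  expect_equal(unname(fw2$cache$alphas[[1]]), rep(1 / 3, 3),
               tolerance = 1e-12)
})

test_that("relative positions change attention only at distinct offsets", {
  d <- 12
  p <- gsa_params(d = d, heads = 3, rel_clip = 5, seed = 57)
  withr::with_seed(58, H <- matrix(rnorm(6 * d), 6, d))
  same <- graphvir:::attend_forward(H, src = c(1L, 1L), dst = c(2L, 3L),
                                    rel_row = c(4L, 4L), p,
                                    use_relpos = TRUE)
  base <- graphvir:::attend_forward(H, src = c(1L, 1L), dst = c(2L, 3L),
                                    rel_row = c(4L, 4L), p,
                                    use_relpos = FALSE)
  # a shared offset shifts both logits equally only when keys project
  # identically; with distinct offsets the distribution must move
  distinct <- graphvir:::attend_forward(H, src = c(1L, 1L), dst = c(2L, 3L),
                                        rel_row = c(2L, 9L), p,
                                        use_relpos = TRUE)
  expect_false(isTRUE(all.equal(distinct$U[1, ], base$U[1, ])))
  expect_s3_class(p, "gv_gsa_params")
  expect_error(gsa_params(d = 30, heads = 7), "divisible")
})

test_that("graph-level attention masks padded nodes", {
  pl <- tiny_pipeline()
  s <- pad_to_multiple(random_dna(950, 59), 9000L)
  g <- init_node_features(build_graph(decompose_sequence(s)), pl$tables)
  up <- gsa_attend(g, gsa_params(seed = 60))
  expect_true(all(up$features[up$nodes$pad, ] == 0))
  expect_equal(dim(up$features), dim(g$features))
})

test_that("forward output is a probability and softmax halves on zero head",
{
  pl <- tiny_pipeline()
  g <- init_node_features(build_graph(decompose_sequence(
    random_dna(900, 61))), pl$tables)
  pr <- classify_graph(g, pl$fit)
  expect_gte(pr, 0)
  expect_lte(pr, 1)

  zfit <- pl$fit
  zfit$readout$W1[] <- 0
  zfit$readout$b1[] <- 0
  zfit$readout$W2[] <- 0
  zfit$readout$b2[] <- 0
  expect_equal(classify_graph(g, zfit), 0.5, tolerance = 1e-12)
})

test_that("forward is invariant to node relabeling", {
  pl <- tiny_pipeline()
  g <- init_node_features(build_graph(decompose_sequence(
    random_dna(900, 62))), pl$tables)
  base <- classify_graph(g, pl$fit)

  # permute node ids while preserving edges, offsets and readout order
  n <- nrow(g$nodes)
  withr::with_seed(63, perm <- sample.int(n) - 1L)  # new id of old id+1
  g2 <- g
  ord <- order(perm)
  g2$nodes <- g$nodes[ord, ]
  g2$nodes$node_id <- 0:(n - 1L)
  g2$features <- g$features[ord, , drop = FALSE]
  g2$edges$src <- perm[g$edges$src + 1L]
  g2$edges$dst <- perm[g$edges$dst + 1L]
  expect_equal(classify_graph(g2, pl$fit), base, tolerance = 1e-6)
})

test_that("training learns strong synthetic signal and stays deterministic",
{
  pl <- tiny_pipeline()
  expect_lt(utils::tail(pl$fit$loss_trace, 1), pl$fit$loss_trace[1])

  refit <- train_classifier(pl$records, pl$tables,
                            classifier_config(epochs = 4, lr = 0.002,
                                              batch = 8),
                            seed = 403)
  expect_identical(refit$gsa, pl$fit$gsa)
  expect_identical(refit$readout, pl$fit$readout)
  expect_identical(refit$loss_trace, pl$fit$loss_trace)

  pr1 <- predict(pl$fit, pl$records, pl$tables, seed = 9)
  pr2 <- predict(refit, pl$records, pl$tables, seed = 9)
  expect_identical(pr1, pr2)
  ev <- evaluate_predictions(pr1, pl$records[, c("id", "label")])
  expect_gt(ev$metrics$auc, 0.9)  # in-sample recovery of planted signal

  expect_error(
    train_classifier(dplyr::mutate(pl$records, label = "virus"),
                     pl$tables, classifier_config(epochs = 1)),
    "both classes")
})

test_that("the GCN classifier variant trains on the same graphs", {
  pl <- tiny_pipeline()
  fit <- train_classifier(pl$records, pl$tables,
                          classifier_config(epochs = 4, lr = 0.005,
                                            batch = 8),
                          variant = "gcn", seed = 404)
  expect_identical(fit$variant, "gcn")
  expect_lt(utils::tail(fit$loss_trace, 1), fit$loss_trace[1])
  pr <- predict(fit, pl$records, pl$tables)
  expect_equal(nrow(pr), nrow(pl$records))
  expect_true(all(pr$score >= 0 & pr$score <= 1))
})

test_that("prediction respects thresholds, order and the length floor", {
  pl <- tiny_pipeline()
  recs <- pl$records[1:6, ]
  pr0 <- predict(pl$fit, recs, pl$tables, threshold = 0)
  expect_true(all(pr0$call == "virus"))
  pr1 <- predict(pl$fit, recs, pl$tables, threshold = 1)
  expect_true(all((pr1$score == 1) == (pr1$call == "virus")))
  expect_identical(pr0$id, recs$id)

  withshort <- dplyr::bind_rows(
    recs, tibble::tibble(id = "runt", seq = random_dna(50, 64),
                         label = "host", source_length = 50L))
  expect_warning(prs <- predict(pl$fit, withshort, pl$tables),
                 "shorter than 90")
  expect_equal(nrow(prs), 6L)
})

test_that("checkpoints round-trip through disk", {
  pl <- tiny_pipeline()
  f <- withr::local_tempfile(fileext = ".rds")
  write_checkpoint(pl$fit, pl$tables, f)
  ck <- read_checkpoint(f)
  expect_identical(ck$fit$gsa, pl$fit$gsa)
  pr1 <- predict(pl$fit, pl$records[1:3, ], pl$tables)
  pr2 <- predict(ck$fit, pl$records[1:3, ], ck$tables)
  expect_identical(pr1$score, pr2$score)
})

test_that("stacked layers and ablation switches run end to end", {
  pl <- tiny_pipeline()
  fit2 <- train_classifier(pl$records[c(1:4, 13:16), ], pl$tables,
                           classifier_config(epochs = 1, layers = 2,
                                             batch = 4),
                           seed = 405)
  expect_length(fit2$loss_trace, 1L)
  pr <- predict(fit2, pl$records[c(1, 13), ], pl$tables)
  expect_true(all(is.finite(pr$score)))

  norel <- train_classifier(pl$records[c(1:4, 13:16), ], pl$tables,
                            classifier_config(epochs = 1, batch = 4,
                                              use_relpos = FALSE),
                            seed = 406)
  expect_true(all(norel$gsa$R == gsa_params(seed =
    graphvir:::derive_seed(406, "gsa"))$R))  # untouched without relpos
})
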