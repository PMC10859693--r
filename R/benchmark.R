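# Desk-scale end-to-end benchmark: simulate -> embed -> train -> evaluate.
#
# The desk profile shrinks the full-scale training schedule so the whole
# pipeline runs in minutes on one CPU: 1800 bp records, capped corpus
# stages and short Adam schedules. Full-scale defaults remain available
# through the individual configuration constructors.

#' Desk-scale training profile
#'
#' @param embed_epochs,classifier_epochs,batch,lr shrunk schedules for the
#'   embedding cascade and the classifier.
#' @param max_parents corpus-stage parent cap.
#' @return named list of settings consumed by [run_benchmark()].
#' @export
desk_profile <- function(embed_epochs = 30L, classifier_epochs = 15L,
                         batch = 32L, lr = 0.002, max_parents = 2000L) {
  list(embed_epochs = as.integer(embed_epochs),
       classifier_epochs = as.integer(classifier_epochs),
       batch = as.integer(batch), lr = lr,
       max_parents = as.integer(max_parents))
}

#' Stratified train/test split
#'
#' @param records labeled record tibble.
#' @param test_fraction held-out fraction per class (default 0.25).
#' @param seed integer seed.
#' @return list with `train` and `test` tibbles.
#' @export
split_records <- function(records, test_fraction = 0.25, seed = 1L) {
  withr::with_seed(seed, {
    test_idx <- unlist(lapply(split(seq_len(nrow(records)), records$label),
                              function(ix) {
                                sample(ix, round(length(ix) * test_fraction))
                              }), use.names = FALSE)
  })
  list(train = records[-test_idx, , drop = FALSE],
       test = records[sort(test_idx), , drop = FALSE])
}

#' Run the end-to-end desk-scale benchmark
#'
#' Simulates a labeled corpus, splits it, trains the embedding cascade and
#' the requested classifier variants on the training part, scores the
#' held-out part and returns per-model metrics. Variants: `full` (cascade
#' embedding + attention classifier), `variant1` (flat embedding +
#' attention classifier), `variant2` (cascade embedding + plain-GCN
#' classifier). The cascade is shared between `full` and `variant2`.
#'
#' @param seed integer seed for the whole run.
#' @param n_per_class,length,delta,motif_rate,n_motifs corpus settings
#'   (defaults: 200 per class, 1800 bp).
#' @param variants subset of `c("full", "variant1", "variant2")`.
#' @param profile a [desk_profile()].
#' @param graph_cfg a [graph_config()].
#' @return object of class `gv_benchmark`: list with `metrics` (tibble, one
#'   row per model), `fits`, `tables`, `predictions`, `seed`.
#' @export
run_benchmark <- function(seed = 1L, n_per_class = 200L, length = 1800L,
                          delta = 0.5, motif_rate = 5, n_motifs = 4L,
                          variants = c("full", "variant1", "variant2"),
                          profile = desk_profile(),
                          graph_cfg = graph_config()) {
  variants <- match.arg(variants, several.ok = TRUE)
  records <- simulate_sequences(synthetic_config(
    n_per_class = n_per_class, length = length, delta = delta,
    motif_rate = motif_rate, n_motifs = n_motifs,
    seed = derive_seed(seed, "sim")
  ))
  parts <- split_records(records, 0.25, seed = derive_seed(seed, "split"))

  emb_cfg <- function(mode) {
    cascade_config(epochs = profile$embed_epochs, batch = 200L,
                   max_parents = profile$max_parents, mode = mode)
  }
  cls_cfg <- classifier_config(epochs = profile$classifier_epochs,
                               lr = profile$lr, batch = profile$batch)

  tables <- NULL
  tables_flat <- NULL
  if (any(c("full", "variant2") %in% variants)) {
    tables <- run_cascade(parts$train, emb_cfg("cascade"),
                          seed = derive_seed(seed, "cascade"))
  }
  if ("variant1" %in% variants) {
    tables_flat <- run_cascade(parts$train, emb_cfg("flat"),
                               seed = derive_seed(seed, "cascade"))
  }

  # graphs are identical across table sets; build them once per record
  graphs_for <- function(recs, which) {
    prepped <- prepare_records(recs,
                               seed = derive_seed(seed,
                                                  paste0("window_", which)))
    lapply(prepped$seq,
           function(s) build_graph(decompose_sequence(s), graph_cfg))
  }
  gtrain <- graphs_for(parts$train, "train")
  gtest <- graphs_for(parts$test, "test")
  bundles_for <- function(graphs, tb) {
    lapply(graphs, function(g) graph_arrays(init_node_features(g, tb)))
  }

  specs <- list(
    full = list(tables = tables, variant = "gsa"),
    variant1 = list(tables = tables_flat, variant = "gsa"),
    variant2 = list(tables = tables, variant = "gcn")
  )[variants]

  btrain <- list()
  btest <- list()
  fits <- list()
  preds <- list()
  rows <- list()
  for (nm in names(specs)) {
    sp <- specs[[nm]]
    key <- sp$tables$hash
    if (is.null(btrain[[key]])) {
      btrain[[key]] <- bundles_for(gtrain, sp$tables)
      btest[[key]] <- bundles_for(gtest, sp$tables)
    }
    fit <- train_classifier(parts$train, sp$tables, cls_cfg, graph_cfg,
                            variant = sp$variant,
                            seed = derive_seed(seed, paste0("train_", nm)),
                            bundles = btrain[[key]])
    pr <- predict(fit, parts$test, sp$tables,
                  seed = derive_seed(seed, "predict"),
                  bundles = btest[[key]])
    ev <- evaluate_predictions(pr, parts$test[, c("id", "label")])
    fits[[nm]] <- fit
    preds[[nm]] <- pr
    rows[[nm]] <- dplyr::mutate(ev$metrics, model = nm, .before = 1)
  }

  structure(
    list(metrics = dplyr::bind_rows(rows), fits = fits,
         predictions = preds, tables = tables %||% tables_flat,
         n_train = nrow(parts$train), n_test = nrow(parts$test),
         seed = seed),
    class = "gv_benchmark"
  )
}

#' @export
#' @method print gv_benchmark
print.gv_benchmark <- function(x, ...) {
  cat("<gv_benchmark> seed ", x$seed, ": ", x$n_train, " training / ",
      x$n_test, " held-out records\n", sep = "")
  print(x$metrics)
  invisible(x)
}
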