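# Graph self-attention classifier.
#
# Node representations are updated by multi-head attention restricted to
# each node's graph neighborhood: queries come from the node, keys and
# values from its neighbors, with a learned relative-position embedding
# added to the keys. Head outputs are concatenated and projected
# (h^u = [head_1 .. head_h] W^O). After attention, the ten 900 bp node
# vectors (the 90-mer vectors in short mode, right-padded with zeros to the
# same width) are concatenated in positional order and fed through a
# 20-unit fully connected layer and a softmax over {host, virus}.
#
# Attention logits are scaled by 1/sqrt(d) with d the full width;
# dividing by sqrt(d_h) instead is available via `scale_by_head`. The
# kernels compute projections only for the rows that queries and keys
# actually touch, so a readout-restricted update on a mostly padded graph
# costs far less than a full one.

CLASSES <- c("host", "virus")
READOUT_SLOTS <- 10L

#' Graph self-attention parameters
#'
#' Per-head query/key/value projections (d x d_h each, stored side by side
#' as d x d matrices), the output projection W^O and the per-head
#' relative-position embedding table with one row per clipped signed offset.
#'
#' @param d node representation width (default 30).
#' @param heads number of attention heads (default 6; must divide `d`).
#' @param rel_clip offset clip; must match the graph's
#'   [graph_config()]`$rel_clip`.
#' @param seed seed for the random initialization.
#' @return object of class `gv_gsa_params`.
#' @export
gsa_params <- function(d = 30L, heads = 6L, rel_clip = 16L, seed = 1L) {
  if (d %% heads != 0) {
    stop("d (", d, ") must be divisible by the number of heads (", heads,
         ").", call. = FALSE)
  }
  withr::with_seed(seed, {
    p <- list(
      Wq = glorot(d, d), Wk = glorot(d, d), Wv = glorot(d, d),
      Wo = glorot(d, d),
      R = matrix(rnorm((2 * rel_clip + 1) * d, sd = 0.05),
                 2 * rel_clip + 1, d)
    )
  })
  structure(c(p, list(d = as.integer(d), heads = as.integer(heads),
                      dh = as.integer(d %/% heads),
                      rel_clip = as.integer(rel_clip))),
            class = "gv_gsa_params")
}

#' Readout (merge + fully connected) parameters
#'
#' @param d node width; the merge concatenates 10 slot vectors (10*d in).
#' @param hidden hidden units of the fully connected layer (default 20).
#' @param seed initialization seed.
#' @return object of class `gv_readout_params`.
#' @export
readout_params <- function(d = 30L, hidden = 20L, seed = 1L) {
  withr::with_seed(seed, {
    p <- list(
      W1 = glorot(READOUT_SLOTS * d, hidden), b1 = numeric(hidden),
      W2 = glorot(hidden, 2L), b2 = numeric(2)
    )
  })
  structure(c(p, list(d = as.integer(d), hidden = as.integer(hidden))),
            class = "gv_readout_params")
}

head_cols <- function(i, dh) ((i - 1L) * dh + 1L):(i * dh)

# Active (non-padded) view of a graph as flat arrays for the attention
# kernels: 1-based active-node indices, per-edge relative-offset rows, the
# feature matrix and the readout slot map.
graph_arrays <- function(g) {
  stopifnot(!is.null(g$features))
  act <- !g$nodes$pad
  new_id <- cumsum(act)            # active nodes renumbered 1..na
  keep <- act[g$edges$src + 1L] & act[g$edges$dst + 1L]
  ro_lv <- if (any(g$nodes$level == "900")) "900" else "90"
  ro <- g$nodes[g$nodes$level == ro_lv & act, ]
  list(
    H = g$features[act, , drop = FALSE],
    src = new_id[g$edges$src[keep] + 1L],
    dst = new_id[g$edges$dst[keep] + 1L],
    rel_row = g$edges$rel[keep] + g$cfg$rel_clip + 1L,
    ro_rows = new_id[ro$node_id + 1L],
    ro_slots = ro$pos + 1L,
    na = sum(act)
  )
}

# --- attention kernel ------------------------------------------------------

# One attention layer over flat edge arrays. `active_q` optionally restricts
# the set of query (updated) nodes; all other nodes pass through unchanged.
# Projections are computed only on the rows queries/keys touch. Returns the
# updated features and a cache for the backward pass.
attend_forward <- function(H, src, dst, rel_row, params, use_relpos = TRUE,
                           active_q = NULL) {
  n <- nrow(H)
  d <- params$d
  dh <- params$dh
  if (!is.null(active_q)) {
    qmask <- logical(n)
    qmask[active_q] <- TRUE
    keep <- qmask[src]
    src <- src[keep]; dst <- dst[keep]; rel_row <- rel_row[keep]
  }
  if (!length(src)) {
    return(list(U = H, cache = list(empty = TRUE)))
  }
  us <- unique(src); ud <- unique(dst)
  si <- match(src, us); di <- match(dst, ud)
  nus <- length(us); nud <- length(ud)
  Hq <- H[us, , drop = FALSE]
  Hk <- H[ud, , drop = FALSE]
  sc <- sqrt(params$d_scale %||% d)
  ho_us <- matrix(0, nus, d)
  alphas <- vector("list", params$heads)
  for (i in seq_len(params$heads)) {
    cols <- head_cols(i, dh)
    Q <- Hq %*% params$Wq[, cols, drop = FALSE]
    K <- Hk %*% params$Wk[, cols, drop = FALSE]
    V <- Hk %*% params$Wv[, cols, drop = FALSE]
    kk <- K[di, , drop = FALSE]
    if (use_relpos) kk <- kk + params$R[rel_row, cols, drop = FALSE]
    lg <- rowSums(Q[si, , drop = FALSE] * kk) / sc
    alpha <- grouped_softmax(lg, si, nus)
    ho_us[, cols] <- rowsum_mat(V[di, , drop = FALSE] * alpha, si, nus)
    alphas[[i]] <- alpha
  }
  U <- H
  U[us, ] <- ho_us %*% params$Wo
  list(U = U, cache = list(empty = FALSE, us = us, ud = ud, si = si,
                           di = di, rel_row = rel_row, Hq = Hq, Hk = Hk,
                           ho_us = ho_us, alphas = alphas,
                           use_relpos = use_relpos, n = n))
}

# Backward pass of one attention layer. Returns parameter gradients and the
# gradient with respect to the input features.
attend_backward <- function(dU, cache, params) {
  grads <- list(Wq = params$Wq * 0, Wk = params$Wk * 0, Wv = params$Wv * 0,
                Wo = params$Wo * 0, R = params$R * 0)
  if (isTRUE(cache$empty)) {
    return(list(grads = grads, dH = dU))
  }
  d <- params$d
  dh <- params$dh
  us <- cache$us; ud <- cache$ud
  si <- cache$si; di <- cache$di
  rel_row <- cache$rel_row
  Hq <- cache$Hq; Hk <- cache$Hk
  nus <- length(us); nud <- length(ud)
  sc <- sqrt(params$d_scale %||% d)

  dH <- dU
  dH[us, ] <- 0          # updated nodes do not pass their input through
  dUus <- dU[us, , drop = FALSE]
  grads$Wo <- t(cache$ho_us) %*% dUus
  dho_us <- dUus %*% t(params$Wo)
  dHq <- matrix(0, nus, d)
  dHk <- matrix(0, nud, d)
  for (i in seq_len(params$heads)) {
    cols <- head_cols(i, dh)
    alpha <- cache$alphas[[i]]
    Q <- Hq %*% params$Wq[, cols, drop = FALSE]
    K <- Hk %*% params$Wk[, cols, drop = FALSE]
    V <- Hk %*% params$Wv[, cols, drop = FALSE]
    dho <- dho_us[, cols, drop = FALSE]
    dho_e <- dho[si, , drop = FALSE]
    vd <- V[di, , drop = FALSE]
    dalpha <- rowSums(dho_e * vd)
    dV <- rowsum_mat(dho_e * alpha, di, nud)
    s <- rowsum_vec(alpha * dalpha, si, nus)
    dlg <- alpha * (dalpha - s[si]) / sc
    kk <- K[di, , drop = FALSE]
    if (cache$use_relpos) kk <- kk + params$R[rel_row, cols, drop = FALSE]
    qs <- Q[si, , drop = FALSE]
    dQ <- rowsum_mat(kk * dlg, si, nus)
    dK <- rowsum_mat(qs * dlg, di, nud)
    if (cache$use_relpos) {
      grads$R[, cols] <- rowsum_mat(qs * dlg, rel_row, nrow(params$R))
    }
    grads$Wq[, cols] <- t(Hq) %*% dQ
    grads$Wk[, cols] <- t(Hk) %*% dK
    grads$Wv[, cols] <- t(Hk) %*% dV
    dHq <- dHq + dQ %*% t(params$Wq[, cols, drop = FALSE])
    dHk <- dHk + dK %*% t(params$Wk[, cols, drop = FALSE]) +
      dV %*% t(params$Wv[, cols, drop = FALSE])
  }
  dH[us, ] <- dH[us, , drop = FALSE] + dHq
  dH[ud, ] <- dH[ud, , drop = FALSE] + dHk
  list(grads = grads, dH = dH)
}

#' Apply one graph self-attention update to a graph
#'
#' Updates every active (non-padded) node's representation by multi-head
#' attention over its neighborhood; padded nodes are excluded both as
#' queries and as neighbors, and nodes with an empty neighbor set keep
#' their representation unchanged.
#'
#' @param g a [build_graph()] graph with features (see
#'   [init_node_features()]).
#' @param params a [gsa_params()] object.
#' @param use_relpos add the relative-position embedding to the keys.
#' @return `g` with updated `features`.
#' @export
gsa_attend <- function(g, params, use_relpos = TRUE) {
  stopifnot(inherits(g, "gv_graph"), inherits(params, "gv_gsa_params"))
  if (params$rel_clip != g$cfg$rel_clip) {
    stop("rel_clip mismatch between graph and attention parameters.",
         call. = FALSE)
  }
  ar <- graph_arrays(g)
  fw <- attend_forward(ar$H, ar$src, ar$dst, ar$rel_row, params,
                       use_relpos = use_relpos)
  feats <- g$features
  feats[!g$nodes$pad, ] <- fw$U
  g$features <- feats
  g
}

# --- readout ---------------------------------------------------------------

# Concatenate readout slot vectors (zero for absent/padded slots) into one
# 10*d vector.
readout_concat <- function(U, ro_rows, ro_slots, d) {
  x <- numeric(READOUT_SLOTS * d)
  for (j in seq_along(ro_rows)) {
    x[((ro_slots[j] - 1L) * d + 1L):(ro_slots[j] * d)] <- U[ro_rows[j], ]
  }
  x
}

readout_forward <- function(X, ro) {
  hid <- pmax(sweep(X %*% ro$W1, 2, ro$b1, `+`), 0)
  logits <- sweep(hid %*% ro$W2, 2, ro$b2, `+`)
  list(hid = hid, logits = logits, prob = softmax_rows(logits))
}

# --- classifier ------------------------------------------------------------

#' Classifier training configuration
#'
#' Defaults follow the reference schedule: Adam with learning rate 0.0002,
#' batch size 128, 50 epochs, one attention layer, 20 hidden readout units.
#'
#' @param epochs,lr,batch Adam schedule.
#' @param layers number of stacked attention layers.
#' @param use_relpos use relative positional coding (default `TRUE`).
#' @param heads attention heads (default 6, giving d_h = 5 at d = 30).
#' @param hidden readout hidden units (default 20).
#' @param gcn_hidden hidden width of the plain-GCN classifier variant.
#' @param scale_by_head divide attention logits by sqrt(d_h) instead of
#'   the default sqrt(d) (default `FALSE`).
#' @param class_weights weight the loss by inverse class frequency.
#' @param residual add a residual connection u + GSA(u) (off by default).
#' @return object of class `gv_classifier_config`.
#' @export
classifier_config <- function(epochs = 50L, lr = 2e-4, batch = 128L,
                              layers = 1L, use_relpos = TRUE, heads = 6L,
                              hidden = 20L, gcn_hidden = 30L,
                              scale_by_head = FALSE, class_weights = TRUE,
                              residual = FALSE) {
  stopifnot(epochs >= 0, lr > 0, batch >= 1, layers >= 1)
  structure(
    list(epochs = as.integer(epochs), lr = lr, batch = as.integer(batch),
         layers = as.integer(layers), use_relpos = isTRUE(use_relpos),
         heads = as.integer(heads), hidden = as.integer(hidden),
         gcn_hidden = as.integer(gcn_hidden),
         scale_by_head = isTRUE(scale_by_head),
         class_weights = isTRUE(class_weights), residual = isTRUE(residual)),
    class = "gv_classifier_config"
  )
}

# Normalize record lengths for graph building: short records (padding to a
# multiple of 90 stays under 900 bp) keep their own short graph; everything
# else is padded or randomly windowed to 9000 bp.
prepare_records <- function(records, seed = 1L) {
  len <- nchar(records$seq)
  pad90 <- as.integer(ceiling(len / 90) * 90)
  short <- pad90 < 900L
  out <- records
  if (any(short)) {
    out$seq[short] <- vapply(records$seq[short], pad_to_multiple,
                             character(1), quantum = 90L)
  }
  if (any(!short)) {
    fixed <- to_fixed_window(records[!short, , drop = FALSE], 9000L,
                             seed = seed)
    out$seq[!short] <- fixed$seq
  }
  out$source_length <- ifelse(is.na(records$source_length %||%
                                      NA_integer_), len,
                              records$source_length)
  out
}

# Per-record scoring/training bundle: graph arrays with embedded features.
make_bundle <- function(seq, tables, graph_cfg) {
  g <- build_graph(decompose_sequence(seq), graph_cfg)
  g <- init_node_features(g, tables)
  graph_arrays(g)
}

# Add the normalized adjacency and the constant first propagation needed by
# the plain-GCN variant.
augment_gcn <- function(ar) {
  if (!is.null(ar$ahat)) return(ar)
  ij <- unique(cbind(ar$src, ar$dst))
  adj <- Matrix::sparseMatrix(i = ij[, 1], j = ij[, 2], x = 1,
                              dims = c(ar$na, ar$na))
  adj <- (adj + Matrix::t(adj) > 0) * 1
  ar$ahat <- normalize_adjacency(adj)
  ar$M1 <- as.matrix(ar$ahat %*% ar$H)
  ar
}

bundle_score_gsa <- function(ar, gsa, cfg) {
  H <- ar$H
  L <- cfg$layers
  for (l in seq_len(L)) {
    aq <- if (l == L) ar$ro_rows else NULL
    fw <- attend_forward(H, ar$src, ar$dst, ar$rel_row, gsa,
                         use_relpos = cfg$use_relpos, active_q = aq)
    H <- if (cfg$residual) H + fw$U else fw$U
  }
  H
}

bundle_score_gcn <- function(ar, gcnp) {
  ar <- augment_gcn(ar)
  z1 <- pmax(ar$M1 %*% gcnp$Wg1, 0)
  m2 <- as.matrix(ar$ahat %*% z1)
  m2 %*% gcnp$Wg2
}

# Score one bundle with a trained model. The GCN variant only needs the
# readout rows of the second layer, so it goes through the two-hop view.
score_bundle <- function(ar, fit) {
  if (fit$variant == "gsa") {
    U <- bundle_score_gsa(ar, fit$gsa, fit$cfg)
    x <- readout_concat(U, ar$ro_rows, ar$ro_slots, fit$d)
  } else {
    U <- gcn_view_output(build_gcn_view_one(ar), fit$gcn)
    x <- readout_concat(U, seq_along(ar$ro_rows), ar$ro_slots, fit$d)
  }
  readout_forward(matrix(x, 1), fit$readout)$prob[1, 2]
}

#' Train the graph classifier
#'
#' Minimizes cross-entropy over {host, virus} with Adam. `variant = "gsa"`
#' is the full model (attention + relative positional coding);
#' `variant = "gcn"` swaps the attention stack for a plain two-layer GCN
#' over the same graph (the classifier ablation). Training is deterministic
#' given the seed.
#'
#' @param records labeled record tibble.
#' @param tables trained [run_cascade()] embeddings.
#' @param cfg a [classifier_config()].
#' @param graph_cfg a [graph_config()].
#' @param variant `"gsa"` or `"gcn"`.
#' @param seed integer seed.
#' @param bundles optional list of precomputed per-record bundles (from the
#'   same records, tables and graph configuration), used to share graph
#'   construction across fits.
#' @return object of class `gv_classifier` with the trained parameters, the
#'   per-epoch loss trace and the configuration fingerprint.
#' @export
train_classifier <- function(records, tables, cfg = classifier_config(),
                             graph_cfg = graph_config(),
                             variant = c("gsa", "gcn"), seed = 1L,
                             bundles = NULL) {
  variant <- match.arg(variant)
  stopifnot(inherits(tables, "gv_embeddings"))
  y <- match(records$label, CLASSES)
  if (any(is.na(y))) stop("Records must be labeled virus/host.",
                          call. = FALSE)
  if (length(unique(y)) < 2) {
    stop("Training set must contain both classes.", call. = FALSE)
  }
  d <- tables$d
  if (is.null(bundles)) {
    recs <- prepare_records(records, seed = derive_seed(seed, "window"))
    bundles <- lapply(recs$seq, make_bundle, tables = tables,
                      graph_cfg = graph_cfg)
  }
  nrec <- length(bundles)

  cw <- c(1, 1)
  if (cfg$class_weights) {
    tab <- tabulate(y, 2)
    cw <- nrec / (2 * pmax(tab, 1))
  }
  wts <- cw[y]

  gsa <- gsa_params(d = d, heads = cfg$heads, rel_clip = graph_cfg$rel_clip,
                    seed = derive_seed(seed, "gsa"))
  ro <- readout_params(d = d, hidden = cfg$hidden,
                       seed = derive_seed(seed, "readout"))
  withr::with_seed(derive_seed(seed, "init"), {
    gcnp <- list(Wg1 = glorot(d, cfg$gcn_hidden),
                 Wg2 = glorot(cfg$gcn_hidden, d))
    perm_seeds <- sample.int(.Machine$integer.max, max(cfg$epochs, 1))
  })
  if (cfg$scale_by_head) gsa$d_scale <- gsa$dh

  params <- c(
    if (variant == "gsa") gsa[c("Wq", "Wk", "Wv", "Wo", "R")] else gcnp,
    ro[c("W1", "b1", "W2", "b2")]
  )
  opt <- adam_init(params)

  if (variant == "gcn") {
    res <- train_loop_gcn_fast(build_gcn_views(bundles), y, wts, params,
                               opt, cfg, d, perm_seeds)
  } else if (cfg$layers == 1L && !cfg$residual) {
    res <- train_loop_gsa_fast(build_gsa_views(bundles, d), y, wts, params,
                               opt, cfg, d, perm_seeds, gsa)
  } else {
    res <- train_loop_gsa_generic(bundles, y, wts, params, opt, cfg, d,
                                  perm_seeds, gsa)
  }
  params <- res$params
  trace <- res$trace

  if (variant == "gsa") {
    gsa[c("Wq", "Wk", "Wv", "Wo", "R")] <-
      params[c("Wq", "Wk", "Wv", "Wo", "R")]
  } else {
    gcnp <- list(Wg1 = params$Wg1, Wg2 = params$Wg2)
  }
  ro[c("W1", "b1", "W2", "b2")] <- params[c("W1", "b1", "W2", "b2")]

  structure(
    list(variant = variant, d = d, gsa = if (variant == "gsa") gsa,
         gcn = if (variant == "gcn") gcnp, readout = ro, cfg = cfg,
         graph_cfg = graph_cfg, loss_trace = trace, seed = seed,
         classes = CLASSES, embedding_hash = tables$hash,
         hash = config_hash(list(cfg, graph_cfg, variant, seed))),
    class = "gv_classifier"
  )
}

#' @export
#' @method print gv_classifier
print.gv_classifier <- function(x, ...) {
  cat("<gv_classifier> variant=", x$variant, ", ", length(x$loss_trace),
      " epochs trained, final loss ",
      if (length(x$loss_trace)) signif(utils::tail(x$loss_trace, 1), 4)
      else NA, ", hash ", x$hash, "\n", sep = "")
  invisible(x)
}

#' Forward pass: virus probability for one graph
#'
#' Runs the attention stack (or the plain-GCN variant), merges the readout
#' level vectors in positional order and applies the fully connected +
#' softmax head. The two softmax outputs sum to one; the virus-class
#' probability is returned.
#'
#' @param g graph with initialized features.
#' @param fit a [train_classifier()] model.
#' @return probability in `[0, 1]`.
#' @export
classify_graph <- function(g, fit) {
  stopifnot(inherits(g, "gv_graph"), inherits(fit, "gv_classifier"))
  if (!any(g$nodes$level %in% c("900", "90"))) {
    stop("Graph lacks a readout level.", call. = FALSE)
  }
  score_bundle(graph_arrays(g), fit)
}

#' Score and call a set of records
#'
#' Records longer than 9000 bp contribute one random window (drawn with the
#' run seed), shorter ones are padded; records under 90 bp are skipped with
#' a warning. The call is virus iff score >= threshold.
#'
#' @param object a trained [train_classifier()] model.
#' @param records record tibble to score.
#' @param tables the [run_cascade()] embeddings the model was trained with.
#' @param threshold decision threshold (default 0.5).
#' @param seed seed for window extraction.
#' @param bundles optional precomputed bundles for the records.
#' @param ... unused.
#' @return tibble with columns `id`, `length`, `score`, `call`, one row per
#'   scored record in input order.
#' @export
predict.gv_classifier <- function(object, records, tables, threshold = 0.5,
                                  seed = 1L, bundles = NULL, ...) {
  stopifnot(inherits(tables, "gv_embeddings"))
  if (!identical(tables$hash, object$embedding_hash)) {
    warning("Embedding tables differ from the ones the model was trained ",
            "with.", call. = FALSE)
  }
  len <- nchar(records$seq)
  skip <- len < 90L
  if (any(skip)) {
    warning(sum(skip), " record(s) shorter than 90 bp skipped: ",
            paste(utils::head(records$id[skip], 5), collapse = ", "),
            call. = FALSE)
    records <- records[!skip, , drop = FALSE]
    len <- len[!skip]
    if (!is.null(bundles)) bundles <- bundles[!skip]
  }
  if (is.null(bundles)) {
    recs <- prepare_records(records, seed = derive_seed(seed, "window"))
    bundles <- lapply(recs$seq, make_bundle, tables = tables,
                      graph_cfg = object$graph_cfg)
  }
  scores <- vapply(bundles, score_bundle, numeric(1), fit = object,
                   USE.NAMES = FALSE)
  tibble::tibble(
    id = records$id,
    length = len,
    score = scores,
    call = ifelse(scores >= threshold, "virus", "host")
  )
}

#' Save / load a model checkpoint
#'
#' The checkpoint bundles the classifier, the embedding tables and their
#' configuration fingerprints in one versioned file.
#'
#' @param fit a [train_classifier()] model.
#' @param tables the matching [run_cascade()] embeddings.
#' @param path file path.
#' @export
write_checkpoint <- function(fit, tables, path) {
  saveRDS(list(version = 1L, fit = fit, tables = tables), path)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  ck <- readRDS(path)
  stopifnot(identical(ck$version, 1L))
  ck
}
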