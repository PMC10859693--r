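# Construction of the directed multilayer sequence graph.
#
# Nodes are the segments of the four decomposition levels. Edge types:
#   direct -- hierarchy edges between a segment and its parent segment;
#   E1     -- base-base local edges within a +/-k window;
#   E2     -- base -> 9-mer edges: the containing 9-mer plus the next 9;
#   E3     -- base -> 90-mer edges: the 6 90-mers following the containing
#             one (the containing 90-mer is already covered through E2);
#   E4     -- base -> 900 bp edges: the 3 following 900 bp segments.
# With defaults (k = 4) a 9000 bp sequence gives 10 110 nodes. Every edge
# carries a signed relative offset used by the attention's relative
# positional coding.

EDGE_TYPES <- c("direct", "E1", "E2", "E3", "E4")

#' Graph construction configuration
#'
#' @param k local-edge neighbor radius: each base links to its 2k
#'   neighboring bases (default 4).
#' @param e2_span number of 9-mer targets per base (default 10: the
#'   containing 9-mer plus the nine to its right).
#' @param e3_span number of 90-mer targets per base (default 6, starting one
#'   past the containing 90-mer).
#' @param e4_span number of 900 bp targets per base (default 3, starting one
#'   past the containing 900 bp segment).
#' @param bidirectional_segment_edges materialize the reverse direction of
#'   every direct/E2/E3/E4 edge (default `TRUE`) so information can flow
#'   both up and down the hierarchy during attention.
#' @param rel_clip clip for the signed relative offsets (default 16), which
#'   bounds the relative-position embedding table.
#' @return object of class `gv_graph_config`.
#' @export
graph_config <- function(k = 4L, e2_span = 10L, e3_span = 6L, e4_span = 3L,
                         bidirectional_segment_edges = TRUE, rel_clip = 16L) {
  stopifnot(k >= 0, e2_span >= 0, e3_span >= 0, e4_span >= 0, rel_clip >= 1)
  structure(
    list(k = as.integer(k), e2_span = as.integer(e2_span),
         e3_span = as.integer(e3_span), e4_span = as.integer(e4_span),
         bidirectional_segment_edges = isTRUE(bidirectional_segment_edges),
         rel_clip = as.integer(rel_clip)),
    class = "gv_graph_config"
  )
}

clip_rel <- function(rel, clip) pmin(pmax(rel, -clip), clip)

#' Base-base local edges (E1)
#'
#' Links every base to its 2k positional neighbors: the undirected pair set
#' \{(i, j) : 0 < |i - j| <= k\} materialized as two directed edges per
#' pair. Interior bases have degree 2k, boundary bases fewer.
#'
#' @param n_bases number of base positions.
#' @param k neighbor radius.
#' @return tibble with columns `src_pos`, `dst_pos`, `rel` (0-based base
#'   positions; `rel = dst - src`).
#' @export
local_edges <- function(n_bases, k) {
  stopifnot(n_bases >= 1, k >= 0)
  if (k == 0 || n_bases < 2) {
    return(tibble::tibble(src_pos = integer(0), dst_pos = integer(0),
                          rel = integer(0)))
  }
  src <- dst <- integer(0)
  for (d in seq_len(k)) {
    i <- seq_len(n_bases - d) - 1L
    if (!length(i)) break
    src <- c(src, i)
    dst <- c(dst, i + d)
  }
  tibble::tibble(
    src_pos = c(src, dst),
    dst_pos = c(dst, src),
    rel = c(dst - src, src - dst)
  )
}

# Forward base -> segment targets for one span rule. anchor_offset 0 means
# the containing unit is included (E2); 1 means targets start one unit past
# it (E3/E4). Returns 0-based base position, target index and offset.
base_segment_targets <- function(n_bases, unit, n_targets_from, span,
                                 anchor_offset) {
  if (span <= 0 || n_targets_from <= 0) {
    return(tibble::tibble(base = integer(0), target = integer(0),
                          rel = integer(0)))
  }
  p <- rep(seq_len(n_bases) - 1L, each = span)
  off <- rep(seq.int(anchor_offset, anchor_offset + span - 1L), n_bases)
  target <- p %/% unit + off
  keep <- target < n_targets_from
  tibble::tibble(base = p[keep], target = target[keep], rel = off[keep])
}

#' Base-to-segment edges (E2, E3, E4)
#'
#' For the base at global position p with containing segment indices
#' j9 = floor(p/9), j90 = floor(p/90), j900 = floor(p/900), the targets are
#' 9-mers j9..j9+9 (E2), 90-mers j90+1..j90+6 (E3) and 900 bp segments
#' j900+1..j900+3 (E4), each clipped at the right end of its level. Edges
#' whose base or target segment is entirely padding are dropped; in short
#' mode (no 900 bp level) E4 does not exist.
#'
#' @param decomp a [decompose_sequence()] result.
#' @param cfg a [graph_config()].
#' @return named list of tibbles `E2`, `E3`, `E4` with columns `base`
#'   (0-based position), `target` (0-based index in the target level), `rel`.
#' @export
segment_edges <- function(decomp, cfg = graph_config()) {
  stopifnot(inherits(decomp, "gv_decomp"))
  n <- decomp$length
  n9 <- length(decomp$levels$`9`)
  n90 <- length(decomp$levels$`90`)
  n900 <- length(decomp$levels$`900`)
  drop_padded <- function(df, level) {
    if (!nrow(df)) return(df)
    keep <- !decomp$pad_mask$base[df$base + 1L] &
      !decomp$pad_mask[[level]][df$target + 1L]
    df[keep, , drop = FALSE]
  }
  list(
    E2 = drop_padded(
      base_segment_targets(n, 9L, n9, cfg$e2_span, 0L), "9"),
    E3 = drop_padded(
      base_segment_targets(n, 90L, n90, cfg$e3_span, 1L), "90"),
    E4 = drop_padded(
      base_segment_targets(n, 900L, n900, cfg$e4_span, 1L), "900")
  )
}

#' Build the multilayer sequence graph
#'
#' Assembles the node table (one row per segment at every level, with a pad
#' flag) and the typed edge list: hierarchy (direct) edges, E1 local edges
#' and E2/E3/E4 segment edges, each with a clipped signed relative offset.
#' E1-E4 edges touching a fully padded node are dropped; direct edges are
#' dropped only when both endpoints are padding (padded nodes are masked out
#' of attention neighborhoods downstream in any case). Construction is fully
#' deterministic and edges are emitted sorted by (type, src, dst).
#'
#' @param decomp a [decompose_sequence()] result.
#' @param cfg a [graph_config()].
#' @return object of class `gv_graph`: list with `nodes` (tibble: `node_id`
#'   dense 0-based, `level`, `pos`, `start`, `end`, `pad`), `edges` (tibble:
#'   `src`, `dst`, `type`, `rel`), `length`, `cfg` and a `features` slot
#'   filled later by [init_node_features()].
#' @examples
#' g <- build_graph(decompose_sequence(strrep("A", 900)))
#' nrow(g$nodes)  # 1 + 10 + 100 + 900
#' @export
build_graph <- function(decomp, cfg = graph_config()) {
  stopifnot(inherits(decomp, "gv_decomp"), inherits(cfg, "gv_graph_config"))
  n <- decomp$length
  counts <- lengths(decomp$levels)
  offsets <- cumsum(c(0L, counts[-length(counts)]))
  names(offsets) <- names(counts)

  nodes <- dplyr::bind_rows(lapply(LEVEL_NAMES, function(lv) {
    m <- counts[[lv]]
    if (!m) return(NULL)
    w <- LEVEL_WIDTHS[[lv]]
    pos <- seq_len(m) - 1L
    tibble::tibble(
      node_id = offsets[[lv]] + pos,
      level = lv,
      pos = pos,
      start = pos * w,
      end = (pos + 1L) * w,
      pad = decomp$pad_mask[[lv]],
      token = decomp$levels[[lv]]
    )
  }))

  pad_of <- nodes$pad  # indexed by node_id + 1

  # --- direct (hierarchy) edges: parent -> child, offset = child index ----
  direct <- list()
  pairs <- list(c("900", "90"), c("90", "9"), c("9", "base"))
  for (pr in pairs) {
    np <- counts[[pr[1]]]
    if (!np) next
    fan <- LEVEL_WIDTHS[[pr[1]]] %/% LEVEL_WIDTHS[[pr[2]]]
    child <- seq_len(counts[[pr[2]]]) - 1L
    parent <- child %/% fan
    direct[[pr[1]]] <- tibble::tibble(
      src = offsets[[pr[1]]] + parent,
      dst = offsets[[pr[2]]] + child,
      rel = child %% fan
    )
  }
  direct <- dplyr::bind_rows(direct)
  if (nrow(direct)) {
    keep <- !(pad_of[direct$src + 1L] & pad_of[direct$dst + 1L])
    direct <- direct[keep, , drop = FALSE]
  }

  # --- E1 local edges ------------------------------------------------------
  e1 <- local_edges(n, cfg$k)
  e1 <- tibble::tibble(
    src = offsets[["base"]] + e1$src_pos,
    dst = offsets[["base"]] + e1$dst_pos,
    rel = e1$rel
  )
  if (nrow(e1)) {
    keep <- !pad_of[e1$src + 1L] & !pad_of[e1$dst + 1L]
    e1 <- e1[keep, , drop = FALSE]
  }

  # --- E2/E3/E4 segment edges ---------------------------------------------
  seg <- segment_edges(decomp, cfg)
  seg_tbl <- function(df, level) {
    if (!nrow(df)) {
      return(tibble::tibble(src = integer(0), dst = integer(0),
                            rel = integer(0)))
    }
    tibble::tibble(
      src = offsets[["base"]] + df$base,
      dst = offsets[[level]] + df$target,
      rel = df$rel
    )
  }
  e2 <- seg_tbl(seg$E2, "9")
  e3 <- seg_tbl(seg$E3, "90")
  e4 <- seg_tbl(seg$E4, "900")

  both_dir <- function(df) {
    if (!cfg$bidirectional_segment_edges || !nrow(df)) return(df)
    dplyr::bind_rows(
      df,
      tibble::tibble(src = df$dst, dst = df$src, rel = -df$rel)
    )
  }
  edges <- dplyr::bind_rows(
    dplyr::mutate(both_dir(direct), type = "direct"),
    dplyr::mutate(e1, type = "E1"),
    dplyr::mutate(both_dir(e2), type = "E2"),
    dplyr::mutate(both_dir(e3), type = "E3"),
    dplyr::mutate(both_dir(e4), type = "E4")
  )
  edges$rel <- clip_rel(edges$rel, cfg$rel_clip)
  edges$type <- factor(edges$type, levels = EDGE_TYPES)
  edges <- dplyr::arrange(edges, .data$type, .data$src, .data$dst)
  edges <- edges[, c("src", "dst", "type", "rel")]

  structure(
    list(nodes = nodes, edges = edges, length = n, cfg = cfg,
         features = NULL),
    class = "gv_graph"
  )
}

#' @export
#' @method print gv_graph
print.gv_graph <- function(x, ...) {
  cat("<gv_graph> ", x$length, " bp, ", nrow(x$nodes), " nodes, ",
      nrow(x$edges), " directed edges",
      if (!is.null(x$features)) " (features initialized)", "\n", sep = "")
  print(table(x$edges$type))
  invisible(x)
}

#' Graph summary statistics
#'
#' Exact node and per-type edge counts plus an eccentricity sample: the
#' graph is viewed as undirected and BFS distances are taken from a sample
#' of non-padded nodes, giving an empirical estimate of the diameter.
#'
#' @param g a [build_graph()] result.
#' @param sample_size number of BFS source nodes (default 10).
#' @param seed seed for the source sample.
#' @return list with `n_nodes`, `n_active_nodes`, `edge_counts` (directed,
#'   by type), `edge_pairs` (unique unordered pairs, by type),
#'   `total_directed`, `max_bfs_eccentricity`.
#' @export
graph_stats <- function(g, sample_size = 10L, seed = 1L) {
  stopifnot(inherits(g, "gv_graph"))
  ec <- table(g$edges$type)
  key <- paste(pmin(g$edges$src, g$edges$dst),
               pmax(g$edges$src, g$edges$dst), g$edges$type)
  pairs <- tapply(!duplicated(key), g$edges$type, sum)
  pairs[is.na(pairs)] <- 0

  # undirected adjacency over active nodes for the BFS sample
  active <- g$nodes$node_id[!g$nodes$pad]
  adj <- split(c(g$edges$dst, g$edges$src), c(g$edges$src, g$edges$dst))
  ecc <- integer(0)
  if (length(active)) {
    withr::with_seed(seed, {
      srcs <- sample(active, min(sample_size, length(active)))
    })
    n <- nrow(g$nodes)
    for (s in srcs) {
      dist <- rep(NA_integer_, n)
      dist[s + 1L] <- 0L
      frontier <- s
      depth <- 0L
      while (length(frontier)) {
        depth <- depth + 1L
        nxt <- unique(unlist(adj[as.character(frontier)], use.names = FALSE))
        nxt <- nxt[is.na(dist[nxt + 1L])]
        if (!length(nxt)) break
        dist[nxt + 1L] <- depth
        frontier <- nxt
      }
      ecc <- c(ecc, max(dist, na.rm = TRUE))
    }
  }
  list(
    n_nodes = nrow(g$nodes),
    n_active_nodes = sum(!g$nodes$pad),
    edge_counts = stats::setNames(as.integer(ec), names(ec)),
    edge_pairs = stats::setNames(as.integer(pairs), names(pairs)),
    total_directed = nrow(g$edges),
    max_bfs_eccentricity = if (length(ecc)) max(ecc) else NA_integer_
  )
}

#' Export a graph as plain-text node/edge tables
#'
#' Debugging/test helper: writes `<stem>.nodes.tsv` and `<stem>.edges.tsv`.
#'
#' @param g a [build_graph()] result.
#' @param stem output path stem.
#' @export
write_graph_tsv <- function(g, stem) {
  utils::write.table(g$nodes, paste0(stem, ".nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(g$edges, paste0(stem, ".edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(stem)
}
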