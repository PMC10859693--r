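test_that("a 9000 bp graph always has 10 110 nodes", {
  for (seed in 1:3) {
    g <- build_graph(decompose_sequence(random_dna(9000, seed)))
    expect_equal(nrow(g$nodes), 10110L)
    expect_equal(g$nodes$node_id, 0:10109)  # dense ids
  }
  # node count is content- and config-independent
  g <- build_graph(decompose_sequence(strrep("A", 9000)),
                   graph_config(k = 0, e2_span = 2))
  expect_equal(nrow(g$nodes), 10110L)
})

test_that("short mode: 540 bp graph has 606 nodes and no E4 edges", {
  s <- pad_to_multiple(random_dna(500, 11), 90L)
  g <- build_graph(decompose_sequence(s))
  expect_equal(nrow(g$nodes), 606L)
  expect_equal(sum(g$edges$type == "E4"), 0L)
  expect_equal(sum(g$nodes$level == "90"), 6L)
})

test_that("local edge counts follow n*k - k(k+1)/2 with boundary clipping", {
  e <- local_edges(9000, 4)
  expect_equal(nrow(e) / 2, 9000 * 4 - 4 * 5 / 2)  # 35 990 pairs
  expect_equal(nrow(local_edges(2, 4)), 2L)        # a single pair
  expect_equal(nrow(local_edges(10, 0)), 0L)
  # interior base has exactly 2k neighbors
  expect_equal(sum(e$src_pos == 100), 8L)
  expect_true(all(abs(e$rel) <= 4 & e$rel != 0))
})

test_that("segment edge targets follow the containing-unit anchoring", {
  d <- decompose_sequence(random_dna(9000, 12))
  seg <- segment_edges(d)
  p0 <- list(E2 = seg$E2$target[seg$E2$base == 0],
             E3 = seg$E3$target[seg$E3$base == 0],
             E4 = seg$E4$target[seg$E4$base == 0])
  expect_equal(p0$E2, 0:9)   # containing 9-mer plus the next nine
  expect_equal(p0$E3, 1:6)   # containing 90-mer covered via E2
  expect_equal(p0$E4, 1:3)
  # right boundary clipping
  expect_equal(seg$E2$target[seg$E2$base == 8999], 999L)
  expect_equal(sum(seg$E3$base == 8999), 0L)
  expect_equal(sum(seg$E4$base == 8999), 0L)
})

test_that("built edges equal the brute-force enumeration oracle", {
  for (case in list(list(len = 500, seed = 21), list(len = 900, seed = 22),
                    list(len = 1400, seed = 23))) {
    s <- random_dna(case$len, case$seed)
    s <- if (nchar(s) < 900) pad_to_multiple(s, 90L) else
      pad_to_multiple(s, 900L)
    g <- build_graph(decompose_sequence(s))
    expect_identical(graph_edge_set(g), oracle_edge_set(s),
                     label = paste0("edge set (", case$len, " bp)"))
  }
})

test_that("graph construction is deterministic and ordered", {
  s <- random_dna(1800, 24)
  g1 <- build_graph(decompose_sequence(s))
  g2 <- build_graph(decompose_sequence(s))
  expect_identical(g1$edges, g2$edges)
  ord <- order(g1$edges$type, g1$edges$src, g1$edges$dst)
  expect_identical(ord, seq_len(nrow(g1$edges)))
  expect_equal(anyDuplicated(g1$edges[, c("src", "dst", "type")]), 0L)
  expect_true(all(g1$edges$src != g1$edges$dst))
})

test_that("no edge joins two padded nodes; offsets respect the clip", {
  s <- pad_to_multiple(random_dna(950, 25), 9000L)
  g <- build_graph(decompose_sequence(s))
  pad <- g$nodes$pad
  expect_false(any(pad[g$edges$src + 1] & pad[g$edges$dst + 1]))
  # non-direct edges never touch padding at all
  nd <- g$edges$type != "direct"
  expect_false(any(pad[g$edges$src[nd] + 1] | pad[g$edges$dst[nd] + 1]))
  expect_true(all(abs(g$edges$rel) <= g$cfg$rel_clip))
})

test_that("hierarchy edges give every non-padded parent its full brood", {
  g <- build_graph(decompose_sequence(random_dna(9000, 26)))
  direct <- g$edges[g$edges$type == "direct", ]
  down <- direct[direct$src < direct$dst, ]  # parent ids precede children
  fan <- table(down$src)
  n900 <- sum(g$nodes$level == "900")
  n90 <- sum(g$nodes$level == "90")
  expect_true(all(fan[as.character(0:(n900 - 1))] == 10))
  expect_true(all(fan[as.character(n900:(n900 + n90 - 1))] == 10))
  expect_true(all(fan[as.character((n900 + n90):(n900 + n90 + 999))] == 9))
  # every child has exactly one parent
  expect_equal(anyDuplicated(down$dst), 0L)
})

test_that("k = 0 removes E1 edges and nothing else", {
  s <- random_dna(900, 27)
  g0 <- build_graph(decompose_sequence(s), graph_config(k = 0))
  g4 <- build_graph(decompose_sequence(s), graph_config(k = 4))
  expect_equal(sum(g0$edges$type == "E1"), 0L)
  for (tp in c("direct", "E2", "E3", "E4")) {
    expect_equal(sum(g0$edges$type == tp), sum(g4$edges$type == tp))
  }
})

test_that("graph statistics report exact counts and BFS eccentricity", {
  g <- build_graph(decompose_sequence(random_dna(9000, 28)))
  st <- graph_stats(g, sample_size = 3)
  expect_equal(st$n_nodes, 10110L)
  expect_equal(st$edge_pairs[["direct"]], 10100L)
  expect_equal(st$total_directed, nrow(g$edges))
  # ~18000 x (k + 10) with k = 4; the realized count is within a factor 2
  expect_gt(st$total_directed, 252000 / 2)
  expect_lt(st$total_directed, 252000 * 2)

  g90 <- build_graph(decompose_sequence(random_dna(90, 29)))
  expect_equal(nrow(g90$nodes), 101L)  # 1 + 9 + 90 + 1(=90-mer level top)
  st90 <- graph_stats(g90, sample_size = 20)
  expect_lte(st90$max_bfs_eccentricity, 3L)
})

test_that("graphs export as plain-text tables", {
  g <- build_graph(decompose_sequence(random_dna(180, 30)))
  stem <- withr::local_tempfile()
  write_graph_tsv(g, stem)
  nodes <- read.delim(paste0(stem, ".nodes.tsv"))
  expect_equal(nrow(nodes), nrow(g$nodes))
})
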