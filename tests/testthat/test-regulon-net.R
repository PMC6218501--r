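# Co-expression networks, tier assignment, core regulon and fragmentation.

test_that("fc_profiles orders timepoints and mirrors the DE table", {
  de <- data.frame(gene_id = c("a", "b"),
                   log2fc_1 = c(0, 1), p_1 = 1,
                   log2fc_2 = c(0, 2), p_2 = 1,
                   log2fc_3 = c(0, 3), p_3 = 1,
                   log2fc_4 = c(0, 4), p_4 = 1)
  m <- fc_profiles(de)
  expect_equal(unname(m["a", ]), c(0, 0, 0, 0))
  expect_equal(unname(m["b", ]), 1:4)
  expect_equal(fc_profiles(de[2:1, ])["b", ], m["b", ])  # row order immaterial
  de$log2fc_2[1] <- NA
  expect_message(m2 <- fc_profiles(de), "dropping")
  expect_equal(rownames(m2), "b")
})

test_that("co-expression edges follow the correlation threshold", {
  p <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(4, 3, 2, 1))
  e <- coexpression_edges(p, r_min = 0.8)
  expect_equal(nrow(e), 1)                     # only the r = 1 pair
  expect_equal(e$weight, 1)
  expect_equal(c(e$gene_u, e$gene_v), c("a", "b"))
  # anti-correlated pair never passes a positive threshold
  e2 <- coexpression_edges(rbind(a = c(1, 2, 3, 4), b = c(4, 3, 2, 1)),
                           r_min = 0.1)
  expect_equal(nrow(e2), 0)
  # constant profiles excluded with a message
  expect_message(coexpression_edges(rbind(a = c(1, 1, 1, 1),
                                          b = c(1, 2, 3, 4),
                                          c = c(1, 2, 3, 5)), r_min = 0.5),
                 "constant")
  expect_equal(nrow(coexpression_edges(p["a", , drop = FALSE],
                                       r_min = 0.5)), 0)
  expect_error(coexpression_edges(p, r_min = 1.2), "r_min")
})

test_that("edge sets equal a brute-force all-pairs correlation oracle", {
  set.seed(1)
  p <- matrix(rnorm(60 * 4), 60, 4,
              dimnames = list(sprintf("g%02d", 1:60), NULL))
  e <- coexpression_edges(p, r_min = 0.8)
  want <- character(0)
  for (i in 1:59) for (j in (i + 1):60) {
    r <- cor(p[i, ], p[j, ])
    if (r >= 0.8) want <- c(want, paste(rownames(p)[i], rownames(p)[j]))
  }
  expect_setequal(paste(e$gene_u, e$gene_v), want)
})

test_that("network gene selection is the density-by-response intersection", {
  dens <- data.frame(gene_id = c("g1", "g2", "g3"), motif = "BRRE",
                     count = c(9, 12, 12), class = c("high", "unchanged_low",
                                                     "very_high"))
  dens$class[2] <- "low"
  cls <- setNames(c("up", "up", "unchanged"), c("g1", "g2", "g3"))
  expect_equal(select_network_genes(dens, cls), "g1")
  set.seed(2)
  n <- 1000
  dens2 <- data.frame(gene_id = sprintf("g%04d", 1:n), motif = "BRRE",
                      count = sample(0:15, n, TRUE))
  dens2$class <- ifelse(dens2$count >= 11, "very_high",
                        ifelse(dens2$count >= 8, "high", "low"))
  cls2 <- setNames(sample(c("up", "down", "unchanged"), n, TRUE),
                   dens2$gene_id)
  want <- intersect(dens2$gene_id[dens2$count >= 8],
                    names(cls2)[cls2 == "up"])
  expect_setequal(select_network_genes(dens2, cls2), want)
})

test_that("tier assignment equals BFS depth capped at tertiary", {
  nodes <- paste0("n", 1:6)
  star <- data.frame(gene_u = "n1", gene_v = paste0("n", 2:6), weight = 0.9)
  net <- assemble_regulon(star, nodes, "n1")
  expect_true(all(net$tier[paste0("n", 2:6)] == "primary"))
  iso <- assemble_regulon(star[0, ], nodes, "n1")
  expect_true(all(iso$tier[paste0("n", 2:6)] == "unlinked"))
  expect_equal(unname(iso$tier["n1"]), "hub")
  expect_error(assemble_regulon(star, nodes, "zz"), "not in node set")
  set.seed(3)
  for (rep in 1:20) {
    nd <- sprintf("v%02d", 1:25)
    ed <- rand_edges(nd, p = 0.08)
    net <- assemble_regulon(ed, nd, "v01")
    d <- oracle_bfs_depth(nd, ed, "v01")
    want <- ifelse(is.infinite(d), "unlinked",
                   ifelse(d == 0, "hub", ifelse(d == 1, "primary",
                          ifelse(d == 2, "secondary", "tertiary"))))
    expect_identical(unname(net$tier[nd]), unname(want[nd]))
  }
})

test_that("tiers are invariant under node relabeling", {
  set.seed(4)
  nd <- sprintf("v%02d", 1:15)
  ed <- rand_edges(nd, p = 0.15)
  net <- assemble_regulon(ed, nd, "v01")
  ren <- setNames(sprintf("w%02d", sample(15)), nd)
  ed2 <- data.frame(gene_u = unname(ren[ed$gene_u]),
                    gene_v = unname(ren[ed$gene_v]), weight = ed$weight)
  net2 <- assemble_regulon(ed2, unname(ren[nd]), unname(ren["v01"]))
  expect_identical(unname(net2$tier[ren[nd]]), unname(net$tier[nd]))
})

test_that("core regulon is the hub plus tight direct neighbors", {
  nodes <- paste0("n", 1:6)
  ed <- data.frame(gene_u = c("n1", "n1", "n2"),
                   gene_v = c("n2", "n3", "n4"),
                   weight = c(0.95, 0.85, 0.99))
  net <- assemble_regulon(ed, nodes, "n1")
  expect_setequal(core_regulon(net, r_core = 0.8),
                  c("n1", "n2", "n3"))          # boundary: hub + primary tier
  expect_setequal(core_regulon(net, r_core = 0.9), c("n1", "n2"))
  expect_equal(core_regulon(net, r_core = 1 + 1e-9), "n1")
  # always a subset of hub + primary tier
  set.seed(5)
  for (rep in 1:20) {
    nd <- sprintf("v%02d", 1:20)
    ed <- rand_edges(nd, p = 0.12)
    net <- assemble_regulon(ed, nd, "v01")
    core <- core_regulon(net, r_core = 0.9)
    expect_true(all(core %in% c("v01", names(net$tier)[net$tier == "primary"])))
    inc <- ed[(ed$gene_u == "v01" | ed$gene_v == "v01") & ed$weight >= 0.9, ]
    expect_setequal(core, c("v01", setdiff(c(inc$gene_u, inc$gene_v), "v01")))
  }
})

test_that("fragmentation metrics match a union-find oracle", {
  nodes <- paste0("n", 1:10)
  full <- rand_edges(nodes, p = 1.0001)        # complete graph
  fr <- fragmentation(full, nodes, "n1")
  expect_equal(fr$n_components, 1)
  expect_true(fr$intact)
  expect_equal(fr$hub_coupled_fraction, 1.0)
  fr0 <- fragmentation(full[0, ], nodes, "n1")
  expect_equal(fr0$n_components, 10)
  expect_equal(fr0$hub_coupled_fraction, 0.1)
  expect_equal(fr0$hub_degree, 0)
  set.seed(6)
  for (rep in 1:25) {
    nd <- sprintf("v%02d", 1:20)
    ed <- rand_edges(nd, p = 0.07)
    fr <- fragmentation(ed, nd, "v01")
    comp <- oracle_components(nd, ed)
    expect_equal(fr$n_components, length(unique(comp)))
    expect_equal(fr$hub_coupled_fraction, mean(comp == comp["v01"]))
    expect_equal(fr$largest_component_fraction,
                 max(table(comp)) / length(nd))
  }
})

test_that("GraphML export round-trips nodes, edges and attributes", {
  td <- withr::local_tempdir()
  empty <- assemble_regulon(data.frame(gene_u = character(0),
                                       gene_v = character(0),
                                       weight = numeric(0)), "solo", "solo")
  p0 <- file.path(td, "empty.graphml")
  export_graph(empty, p0)
  expect_equal(read_graphml(p0)$nodes, "solo")
  set.seed(7)
  for (rep in 1:20) {
    nd <- sprintf("v%02d", 1:12)
    ed <- rand_edges(nd, p = 0.2)
    net <- assemble_regulon(ed, nd, "v01")
    p <- file.path(td, sprintf("net%02d.graphml", rep))
    export_graph(net, p, node_attrs = data.frame(gene_id = nd,
                                                 response = "up"))
    back <- read_graphml(p)
    expect_setequal(back$nodes, nd)
    expect_equal(back$edges[c("gene_u", "gene_v", "weight")],
                 net$edges[order(net$edges$gene_u, net$edges$gene_v),
                           c("gene_u", "gene_v", "weight")])
    expect_identical(unname(back$tier[nd]), unname(net$tier[nd]))
  }
})
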