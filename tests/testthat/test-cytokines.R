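test_that("cytokine panel ranges expand correctly", {
  expect_equal(expand_cytokine_panel("CXCL1-16"), paste0("CXCL", 1:16))
  expect_equal(expand_cytokine_panel("TNF"), "TNF")
  expect_length(expand_cytokine_panel(), 86)  # 3 + 40 + 16 + 27
  expect_equal(expand_cytokine_panel(c("IL1-3", "IL2")),
               c("IL1", "IL2", "IL3"))  # de-duplicated, order preserved
  expect_error(expand_cytokine_panel("CXCL16-1"), "malformed")
  expect_error(expand_cytokine_panel("CX CL1"), "malformed")
})

test_that("edge filtering is strict at the score threshold", {
  net <- data.frame(node1 = c("IL6", "IL6", "IL6"),
                    node2 = c("A", "B", "C"),
                    combined_score = c(0.41, 0.40, 0.39))
  kept <- filter_edges(net, min_score = 0.4)
  expect_equal(kept$node2, "A")
  empty <- net[0, ]
  expect_equal(nrow(filter_edges(empty)), 0)
})

test_that("eligibility requires five connections to significant proteins", {
  sig <- data.frame(protein_id = paste0("P", 1:6),
                    class_label = rep(c("case_associated", "control_associated"),
                                      3))
  net5 <- data.frame(node1 = "IL6", node2 = paste0("P", 1:5),
                     combined_score = 0.9)
  net4 <- net5[1:4, ]
  expect_equal(eligible_cytokines(net5, sig, cytokines = "IL6"), "IL6")
  expect_equal(eligible_cytokines(net4, sig, cytokines = "IL6"), character(0))
  # connections to non-significant proteins do not count
  netx <- data.frame(node1 = "IL6", node2 = paste0("X", 1:9),
                     combined_score = 0.9)
  expect_equal(eligible_cytokines(netx, sig, cytokines = "IL6"), character(0))
  expect_equal(eligible_cytokines(net5[0, ], sig, cytokines = "IL6"),
               character(0))
})

test_that("enrichment scores match hand enumeration on a built network", {
  h <- hand_network()
  # IL6: 2 case edges, 1 control edge; T_case = 3, T_control = 2
  enr <- enrichment_scores(h$edges, h$sig, cytokines = "IL6",
                           min_connections = 3)
  expect_equal(enr$k_case, 2)
  expect_equal(enr$k_control, 1)
  expect_equal(enr$e_case, (2 / 3) / (3 / 5))
  expect_equal(enr$e_control, (1 / 2) / (3 / 5))
  expect_equal(enr$fold_connection, (2 / 3) / (3 / 5) / ((1 / 2) / (3 / 5)))

  # edge_count weighting: add protein-protein edges, T_d counts them
  edges2 <- rbind(h$edges,
                  data.frame(node1 = c("A1", "A2"), node2 = c("A3", "C1"),
                             combined_score = c(0.8, 0.9)))
  enr2 <- enrichment_scores(edges2, h$sig, cytokines = "IL6",
                            min_connections = 3,
                            class_weighting = "edge_count")
  # T_case = 2 (A1-A3, A2-C1), T_control = 1 (A2-C1), T_total = 3
  expect_equal(unname(attr(enr2, "class_totals")), c(2, 1))
  expect_equal(enr2$e_case, (2 / 2) / (3 / 3))
  expect_equal(enr2$e_control, (1 / 1) / (3 / 3))
})

test_that("symmetric connections give fold exactly 1 and zero control gives Inf", {
  sig <- data.frame(protein_id = c("A1", "A2", "C1", "C2"),
                    class_label = c("case_associated", "case_associated",
                                    "control_associated", "control_associated"))
  sym <- data.frame(node1 = "TNF", node2 = c("A1", "A2", "C1", "C2"),
                    combined_score = 0.9)
  enr <- enrichment_scores(sym, sig, cytokines = "TNF", min_connections = 4)
  expect_equal(enr$e_case, enr$e_control)
  expect_equal(enr$fold_connection, 1)

  caseonly <- data.frame(node1 = "TNF", node2 = c("A1", "A2"),
                         combined_score = 0.9)
  enr2 <- enrichment_scores(caseonly, sig, cytokines = "TNF",
                            min_connections = 2)
  expect_equal(enr2$fold_connection, Inf)
})

test_that("swapping classes inverts the fold-connection ratio", {
  set.seed(44)
  prot <- sprintf("P%02d", 1:20)
  sig <- data.frame(protein_id = prot,
                    class_label = sample(c("case_associated",
                                           "control_associated"), 20, TRUE))
  net <- simulate_network(prot, prot[1:8], c("IL6", "TNF"), "IL6",
                          p_base = 0.5, p_planted = 0.9,
                          score_range = c(0.5, 1), seed = 3)
  swap <- sig
  swap$class_label <- ifelse(sig$class_label == "case_associated",
                             "control_associated", "case_associated")
  a <- enrichment_scores(net, sig, cytokines = c("IL6", "TNF"),
                         min_connections = 1)
  b <- enrichment_scores(net, swap, cytokines = c("IL6", "TNF"),
                         min_connections = 1)
  b <- b[match(a$cytokine, b$cytokine), ]
  expect_equal(b$fold_connection, 1 / a$fold_connection, tolerance = 1e-12)
})

test_that("adding a case edge never decreases e_case under protein_count", {
  h <- hand_network()
  before <- enrichment_scores(h$edges, h$sig, cytokines = "IL6",
                              min_connections = 1)
  more <- rbind(h$edges, data.frame(node1 = "IL6", node2 = "A3",
                                    combined_score = 0.95))
  after <- enrichment_scores(more, h$sig, cytokines = "IL6",
                             min_connections = 1)
  expect_gte(after$e_case, before$e_case)
})

test_that("planted cytokines are recovered with fold > 1 and outrank the rest", {
  prot <- sprintf("P%03d", 1:60)
  sig <- data.frame(protein_id = prot,
                    class_label = rep(c("case_associated",
                                        "control_associated"), each = 30))
  panel <- c("IL6", "TNF", "IL10", "CCL2", "CXCL8")
  net <- simulate_network(prot, case_proteins = prot[1:30],
                          cytokine_panel = panel,
                          planted_cytokines = c("IL6", "TNF", "IL10"),
                          p_base = 0.05, p_planted = 0.8,
                          score_range = c(0.5, 1), seed = 1)
  enr <- enrichment_scores(filter_edges(net), sig, cytokines = panel)
  planted <- enr[enr$cytokine %in% c("IL6", "TNF", "IL10"), ]
  others <- enr[!enr$cytokine %in% c("IL6", "TNF", "IL10"), ]
  expect_true(all(planted$fold_connection > 1))
  if (nrow(others)) {
    expect_gt(min(planted$fold_connection), max(others$fold_connection))
  }
})

test_that("identifier matching is case-insensitive with alias support", {
  sig <- data.frame(protein_id = paste0("p", 1:5),
                    class_label = rep("case_associated", 5))
  net <- data.frame(node1 = "il6", node2 = paste0("P", 1:5),
                    combined_score = 0.9)
  expect_equal(eligible_cytokines(net, sig, cytokines = "IL6"), "IL6")
  net2 <- data.frame(node1 = "TGFB1", node2 = paste0("P", 1:5),
                     combined_score = 0.9)
  expect_equal(eligible_cytokines(net2, sig, cytokines = "TGFb",
                                  aliases = c(TGFB1 = "TGFb")), "TGFb")
})

test_that("network decoration sizes by |pi| and applies the pro-precedence rule", {
  diff_tab <- data.frame(
    protein_id = c("A1", "A2", "B1"),
    pi_score = c(2.0, -1.5, 0.3),
    p_value = c(0.01, 0.02, 0.6),
    class_label = c("case_associated", "control_associated", "not_significant")
  )
  edges <- data.frame(
    node1 = c("IL6", "IL10", "IL10", "B1"),
    node2 = c("A1", "A1", "A2", "A2"),
    combined_score = c(0.9, 0.8, 0.7, 0.6)
  )
  enr <- data.frame(cytokine = c("IL6", "IL10"), k_case = c(5, 5),
                    k_control = c(1, 1), k_total = c(6, 6),
                    e_case = c(2, 1.5), e_control = c(0.5, 0.9),
                    fold_connection = c(4, 5 / 3))
  dec <- decorate_network(edges, diff_tab, enr)
  nodes <- dec$nodes
  expect_equal(nodes$size[nodes$node == "A1"], 2.0)
  expect_equal(nodes$size[nodes$node == "A2"], 1.5)
  expect_true(is.na(nodes$size[nodes$node == "B1"]))  # not significant
  # A1 touches pro (IL6) and anti (IL10): pro wins
  expect_equal(nodes$inflammation_color[nodes$node == "A1"], "pro")
  expect_equal(nodes$inflammation_color[nodes$node == "A2"], "anti")
  expect_equal(nodes$inflammation_color[nodes$node == "B1"], "none")
  expect_equal(nodes$fold_connection[nodes$node == "IL6"], 4)

  # unknown protein in the network draws a warning and NA attributes
  edges2 <- rbind(edges, data.frame(node1 = "MYST", node2 = "A1",
                                    combined_score = 0.9))
  expect_warning(dec2 <- decorate_network(edges2, diff_tab, enr), "MYST")
  expect_true(is.na(dec2$nodes$size[dec2$nodes$node == "MYST"]))
})

test_that("decorated networks export to GraphML and SIF", {
  h <- hand_network()
  diff_tab <- data.frame(protein_id = h$sig$protein_id,
                         pi_score = c(2, 1.5, 1.2, -1.3, -1.1),
                         p_value = rep(0.01, 5),
                         class_label = h$sig$class_label)
  enr <- enrichment_scores(h$edges, h$sig, cytokines = "IL6",
                           min_connections = 1)
  dec <- decorate_network(h$edges, diff_tab, enr)
  dir <- withr::local_tempdir()
  gml <- file.path(dir, "net.graphml")
  sif <- file.path(dir, "net.sif")
  attrs <- file.path(dir, "nodes.tsv")
  write_decorated_network(dec, gml, sif, attrs)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(g), nrow(dec$nodes))
  expect_equal(igraph::gsize(g), nrow(dec$edges))
  sif_lines <- readLines(sif)
  expect_length(sif_lines, nrow(dec$edges))
  back <- read.delim(attrs)
  expect_equal(nrow(back), nrow(dec$nodes))
})

test_that("default cytokine classes flag IL6/TNF pro and IL10 anti", {
  cls <- default_cytokine_classes()
  expect_equal(cls$class[cls$cytokine == "IL6"], "pro_inflammatory")
  expect_equal(cls$class[cls$cytokine == "TNF"], "pro_inflammatory")
  expect_equal(cls$class[cls$cytokine == "IL10"], "anti_inflammatory")
  expect_true(all(cls$class[!cls$cytokine %in% c("IL6", "TNF", "IL10")] ==
                    "unclassified"))
})
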