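make_complete <- function() {
  edges <- expand.grid(compound_id = c("c1", "c2", "c3"),
                       target_id = c("t1", "t2"),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  build_network(edges, groups = list(c1 = "g1", c2 = "g1", c3 = "g2"))
}

test_that("complete bipartite network has the expected structure", {
  net <- make_complete()
  expect_equal(nrow(net$edges), 6)
  st <- degree_stats(net)
  expect_true(all(st$compound_degrees == 2))
  expect_true(all(st$target_degrees == 3))
  expect_equal(st$mean_targets_per_compound, 2.00)
  # degree-sum conservation
  expect_equal(sum(st$compound_degrees), nrow(net$edges))
  expect_equal(sum(st$target_degrees), nrow(net$edges))
})

test_that("empty interaction lists give an empty network", {
  net <- build_network(data.frame(compound_id = character(),
                                  target_id = character()))
  expect_length(net$compounds, 0)
  expect_length(net$targets, 0)
  expect_error(degree_stats(net), "undefined-mean")
})

test_that("duplicate edges are collapsed and unknown compounds rejected", {
  lib <- tiny_library()
  edges <- data.frame(compound_id = c("X1", "X1", "X2"),
                      target_id = c("t1", "t1", "t1"),
                      stringsAsFactors = FALSE)
  net <- build_network(edges, library = lib)
  expect_equal(nrow(net$edges), 2)
  expect_equal(net$groups$X2, c("Herb A", "Herb B"))
  expect_error(build_network(data.frame(compound_id = "ZZ",
                                        target_id = "t"),
                             library = lib),
               "unknown compound")
  # isolated declared nodes only on request
  expect_length(build_network(edges, library = lib)$compounds, 2)
  expect_length(build_network(edges, library = lib,
                              keep_isolated = TRUE)$compounds, 3)
})

test_that("the three vascular herbs contribute 30 compounds", {
  lib <- load_fixture("table1")
  vascular <- c("Gymnadenia Conopsea", "Stigma Croci", "Myristica Semena")
  ids <- lib$compound_id[vapply(lib$herbs,
                                function(h) any(h %in% vascular),
                                logical(1))]
  # any score table over these compounds: give every compound one target
  edges <- data.frame(compound_id = ids, target_id = "T001",
                      stringsAsFactors = FALSE)
  net <- build_network(edges, library = lib)
  expect_equal(length(net$compounds), 30)
})

test_that("mean degree uses half-up rounding", {
  edges <- data.frame(
    compound_id = rep(c("a", "b", "c", "d"), times = c(1, 2, 3, 4)),
    target_id = paste0("t", 1:10), stringsAsFactors = FALSE)
  net <- build_network(edges)
  expect_equal(degree_stats(net)$mean_targets_per_compound, 2.50)
  one <- build_network(data.frame(compound_id = "a", target_id = "t"))
  expect_equal(degree_stats(one)$mean_targets_per_compound, 1.00)
})

test_that("target partition handles the degenerate overlap cases", {
  # identical target sets: everything shared
  edges <- rbind(
    data.frame(compound_id = "c1", target_id = c("t1", "t2"),
               stringsAsFactors = FALSE),
    data.frame(compound_id = "c2", target_id = c("t1", "t2"),
               stringsAsFactors = FALSE))
  net <- build_network(edges, groups = list(c1 = "g1", c2 = "g2"))
  part <- partition_targets(net, c("g1", "g2"))
  expect_setequal(part$shared, c("t1", "t2"))
  expect_length(unlist(part$specific), 0)

  # disjoint target sets: no shared, all specific
  edges2 <- data.frame(compound_id = c("c1", "c2"),
                       target_id = c("t1", "t2"),
                       stringsAsFactors = FALSE)
  net2 <- build_network(edges2, groups = list(c1 = "g1", c2 = "g2"))
  part2 <- partition_targets(net2, c("g1", "g2"))
  expect_length(part2$shared, 0)
  expect_equal(part2$specific$g1, "t1")
  expect_equal(part2$specific$g2, "t2")

  expect_error(partition_targets(net2, c("g1", "nope")), "lookup error")
})

test_that("partition equals the per-target membership oracle on random instances", {
  set.seed(23)
  for (rep in 1:10) {
    n_c <- 12; n_t <- 10
    edges <- unique(data.frame(
      compound_id = sample(paste0("c", 1:n_c), 40, replace = TRUE),
      target_id = sample(paste0("t", 1:n_t), 40, replace = TRUE),
      stringsAsFactors = FALSE))
    groups <- lapply(1:n_c, function(i) {
      sample(c("g1", "g2", "g3"), sample(1:2, 1))
    })
    names(groups) <- paste0("c", 1:n_c)
    net <- build_network(edges, groups = groups)
    part <- partition_targets(net, c("g1", "g2", "g3"))
    oracle <- partition_oracle(net, c("g1", "g2", "g3"))
    expect_setequal(part$shared, oracle$shared)
    for (g in c("g1", "g2", "g3")) {
      expect_setequal(part$specific[[g]], oracle$specific[[g]])
    }
    expect_setequal(part$other, oracle$other)
    # disjoint cover of the target side
    all_parts <- unname(c(part$shared, unlist(part$specific), part$other))
    expect_equal(sort(all_parts), sort(net$targets))
  }
})

test_that("overlap percentage reproduces the printed figures with half-up rounding", {
  expect_equal(overlap_percentage(67, 132, 2), 50.76)
  expect_equal(overlap_percentage(135, 139, 0), 97)
  expect_equal(overlap_percentage(0, 7), 0)
  expect_equal(overlap_percentage(7, 7), 100)
  expect_error(overlap_percentage(1, 0), "domain error")
  expect_error(overlap_percentage(5, 3), "domain error")
  # complementarity up to one unit in the last place
  set.seed(3)
  for (i in 1:50) {
    b <- sample(1:500, 1); a <- sample(0:b, 1)
    s <- overlap_percentage(a, b) + overlap_percentage(b - a, b)
    expect_lte(abs(s - 100), 0.01 + 1e-9)
  }
})

test_that("round_half_up rounds ties away from zero", {
  expect_equal(round_half_up(2.5), 3)
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(7.775, 2), 7.78)
  expect_equal(round_half_up(-2.5), -3)
})

test_that("exports produce parseable SIF, edge-TSV and GraphML", {
  net <- make_complete()
  sif <- withr::local_tempfile(fileext = ".sif")
  export_network(net, "sif", sif)
  lines <- readLines(sif)
  expect_length(lines, 6)
  expect_true(all(grepl("\tct\t", lines, fixed = TRUE)))

  two <- build_network(data.frame(compound_id = c("a", "b"),
                                  target_id = c("t1", "t2"),
                                  stringsAsFactors = FALSE))
  sif2 <- withr::local_tempfile(fileext = ".sif")
  export_network(two, "sif", sif2)
  expect_length(readLines(sif2), 2)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_network(net, "edge-tsv", tsv)
  back <- build_network(read_edge_table(tsv), groups = net$groups)
  expect_equal(sort(paste(back$edges$compound_id, back$edges$target_id)),
               sort(paste(net$edges$compound_id, net$edges$target_id)))

  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, "graphml", gml)
  doc <- xml2::read_xml(gml)
  ns <- xml2::xml_ns(doc)
  expect_length(xml2::xml_find_all(doc, ".//d1:node", ns), 5)
  expect_length(xml2::xml_find_all(doc, ".//d1:edge", ns), 6)

  expect_error(export_network(net, "dot", withr::local_tempfile()),
               "usage error")
})
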