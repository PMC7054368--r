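test_that("built-in twin-cycle models have the canonical structure", {
  tc <- builtinModel("TC")
  expect_length(nodeNames(tc), 8)
  expect_equal(nrow(edgeTable(tc)), 13)
  expect_length(exogenousNodes(tc), 0)  # all endogenous (cyclic system)
  expect_equal(freeParamCount(tc), 21)  # 13 edges + 8 disturbances
  expect_equal(modelDF(tc), 15L)
  expect_true(hasCycle(tc))             # IS -> FI -> LF -> IS feedback
  ed <- edgeTable(tc)
  expect_equal(ed$to[ed$label == "is1"], "IS")
  expect_equal(ed$from[ed$label == "is1"], "LF")
  expect_equal(sum(ed$from == "TG"), 1)           # TG only feeds PF
  expect_equal(ed$to[ed$from == "TG"], "PF")

  tcpa <- builtinModel("TC-PA")
  expect_length(nodeNames(tcpa), 9)
  expect_equal(nrow(edgeTable(tcpa)), 21)
  expect_identical(exogenousNodes(tcpa), "PA")
  epa <- edgeTable(tcpa)
  expect_equal(sum(epa$from == "PA"), 8)  # out-degree 8
  expect_equal(sum(epa$to == "PA"), 0)    # in-degree 0
  expect_equal(modelDF(tcpa), 15L)        # 45 - 29 free - 1 fixed moment
  expect_equal(modelDF(builtinModel("TC-PA", fixedExogenous = FALSE)), 15L)
  expect_error(builtinModel("XYZ"), "TC, TC-PA")
})

test_that("model validity rejects malformed structures", {
  ed <- data.frame(label = c("a", "b"), from = c("x", "x"), to = c("y", "y"))
  expect_error(pathModel(ed), "duplicate edge")
  ed2 <- data.frame(label = "a", from = "x", to = "y")
  expect_error(pathModel(ed2, nodes = c("x", "y", "z"),
                         exogenous = character(0)),
               "no inbound edge")
  expect_error(pathModel(data.frame(label = "a", from = "x", to = "q"),
                         nodes = c("x", "y")), "unknown node")
})

test_that("model specs parse, round-trip and serialise to YAML/JSON", {
  m <- builtinModel("TC-PA")
  m2 <- parseModelSpec(writeModelSpec(m))
  expect_equal(nodeNames(m2), nodeNames(m))
  expect_equal(exogenousNodes(m2), exogenousNodes(m))
  expect_equal(edgeTable(m2), edgeTable(m))

  expect_error(parseModelSpec(c("y <- x [a]", "y <- x [b]")),
               "duplicate edge")
  expect_error(parseModelSpec("nonsense line"), "cannot parse")

  # YAML and JSON documents
  yml <- tempfile(fileext = ".yaml")
  writeLines(c("nodes:", "  - name: PA", "    role: exogenous",
               "  - name: IS", "edges:",
               "  - {label: is2, from: PA, to: IS}"), yml)
  my <- parseModelSpec(yml)
  expect_identical(exogenousNodes(my), "PA")
  jsn <- tempfile(fileext = ".json")
  jsonlite::write_json(
    list(nodes = list(list(name = "PA", role = "exogenous"),
                      list(name = "IS")),
         edges = list(list(label = "is2", from = "PA", to = "IS"))),
    jsn, auto_unbox = TRUE)
  mj <- parseModelSpec(jsn)
  expect_equal(edgeTable(mj), edgeTable(my))
  dot <- exportDOT(m)
  expect_match(dot, "PA -> IS \\[label=\"is2\"\\]")
})

test_that("path enumeration finds the canonical mediation pathways", {
  m <- builtinModel("TC-PA")
  paths <- enumerateDirectedPaths(m, "PA", "FG", maxLength = 5)
  strs <- vapply(paths, function(p) paste(p$nodes, collapse = "->"),
                 character(1))
  for (want in c("PA->IS->FG", "PA->GS->FG", "PA->IS->GS->FG",
                 "PA->FI->LF->IS->FG"))
    expect_true(want %in% strs, label = want)
  # every consecutive node pair is a model edge, paths are simple
  ed <- edgeTable(m)
  for (p in enumerateDirectedPaths(m, "PA", "PG")) {
    expect_false(anyDuplicated(p$nodes) > 0)
    for (i in seq_len(length(p$nodes) - 1))
      expect_true(any(ed$from == p$nodes[i] & ed$to == p$nodes[i + 1]))
    expect_equal(length(p$labels), length(p$nodes) - 1)
  }
  # deterministic lexicographic order
  strs2 <- vapply(enumerateDirectedPaths(m, "PA", "FG", 5),
                  function(p) paste(p$nodes, collapse = "->"), character(1))
  expect_identical(strs, strs2)
  expect_identical(strs, sort(strs))
  # a sink nothing points to yields no paths
  m2 <- pathModel(data.frame(label = c("a", "b"), from = c("x", "x"),
                             to = c("y", "z")))
  expect_length(enumerateDirectedPaths(m2, "y", "x"), 0)
  expect_error(enumerateDirectedPaths(m, "PA", "QQ"), "not in model")
  expect_error(enumerateDirectedPaths(m, "PA", "PA"), "differ")
})

test_that("path counts match an exhaustive igraph enumeration", {
  skip_if_not_installed("igraph")
  m <- builtinModel("TC-PA")
  g <- igraph::graph_from_data_frame(edgeTable(m)[, c("from", "to")])
  for (sink in c("FG", "PG", "GS")) {
    mine <- enumerateDirectedPaths(m, "PA", sink)
    ref <- igraph::all_simple_paths(g, "PA", sink, mode = "out")
    expect_equal(length(mine), length(ref))
    refStr <- sort(vapply(ref, function(p)
      paste(names(p), collapse = "->"), character(1)))
    mineStr <- sort(vapply(mine, function(p)
      paste(p$nodes, collapse = "->"), character(1)))
    expect_identical(mineStr, refStr)
  }
})
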