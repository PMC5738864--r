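test_that("edge canonicalization collapses doubly-listed tables", {
  pairs <- data.frame(from = c("a", "b", "b", "c"),
                      to = c("b", "a", "c", "b"),
                      stringsAsFactors = FALSE)
  expect_identical(nrow(collapsePairs(pairs)), 2L)
  net <- makeGeneNetwork(data.frame(from = c("a", "b", "a"),
                                    to = c("b", "a", "a"), weight = 1))
  expect_identical(nrow(networkEdges(net)), 1L)   # dup + self-loop gone
})

test_that("richness filter handles the toy-graph suite", {
  # path a-b-c: b has degree 2, so all three survive the default rule
  path <- toyNetwork("a", "b", "b", "c")
  out <- richnessFilter(path)
  expect_setequal(geneIds(out), c("a", "b", "c"))
  expect_identical(nrow(networkEdges(out)), 2L)
  # isolated pair: both endpoints degree 1, removed
  pair <- toyNetwork("a", "b")
  expect_identical(length(geneIds(richnessFilter(pair))), 0L)
  expect_identical(nrow(networkEdges(richnessFilter(pair))), 0L)
  # star K(1,5): hub degree 5, all leaves reach it
  star <- toyNetwork("h", "l1", "h", "l2", "h", "l3", "h", "l4", "h", "l5")
  out <- richnessFilter(star)
  expect_setequal(geneIds(out), c("h", paste0("l", 1:5)))
  expect_identical(nrow(networkEdges(out)), 5L)
  # two components: a path survives, an isolated pair does not
  mix <- toyNetwork("a", "b", "b", "c", "x", "y")
  out <- richnessFilter(mix)
  expect_setequal(geneIds(out), c("a", "b", "c"))
})

test_that("richness filter output is a subgraph and relabel-equivariant", {
  set.seed(20)
  for (i in 1:10) {
    p <- 12
    m <- matrix(0, p, p)
    idx <- which(upper.tri(m))
    on <- sample(idx, 14)
    labels <- sprintf("n%02d", 1:p)
    edges <- data.frame(
      from = labels[row(m)[on]], to = labels[col(m)[on]], weight = 1,
      stringsAsFactors = FALSE)
    net <- makeGeneNetwork(edges)
    out <- richnessFilter(net)
    expect_true(all(geneIds(out) %in% geneIds(net)))
    key <- function(n) paste(networkEdges(n)$from, networkEdges(n)$to)
    expect_true(all(key(out) %in% key(net)))
    # relabeling nodes commutes with filtering
    perm <- setNames(sprintf("m%02d", sample(p)), labels)
    relabel <- function(n) {
      e <- networkEdges(n)
      makeGeneNetwork(data.frame(from = unname(perm[e$from]),
                                 to = unname(perm[e$to]),
                                 weight = e$weight,
                                 stringsAsFactors = FALSE))
    }
    a <- richnessFilter(relabel(net))
    b <- relabel(out)
    expect_setequal(geneIds(a), geneIds(b))
    expect_setequal(key(a), key(b))
  }
})

test_that("node intersection is commutative and idempotent", {
  a <- toyNetwork("a", "b", "b", "c")
  b <- toyNetwork("b", "c", "c", "d")
  expect_identical(intersectNodes(a, b), intersectNodes(b, a))
  expect_identical(intersectNodes(a, a), sort(geneIds(a)))
  expect_identical(intersectNodes(a, b), c("b", "c"))
  disjoint <- toyNetwork("x", "y", "y", "z")
  expect_identical(intersectNodes(a, disjoint), character(0))
})

test_that("hub ranking orders by degree with deterministic ties", {
  star <- toyNetwork("h", "l1", "h", "l2", "h", "l3", "h", "l4", "h", "l5")
  hr <- hubRank(star)
  expect_identical(hr$probe_id[1], "h")
  expect_identical(hr$degree[1], 5L)
  expect_identical(hr$rank, 1:6)
  expect_identical(hr$probe_id[-1], paste0("l", 1:5))  # tie-break by id
  empty <- makeGeneNetwork(data.frame(from = character(),
                                      to = character()))
  expect_identical(nrow(hubRank(empty)), 0L)
})

test_that("network export round-trips in both formats", {
  net <- toyNetwork("a", "b", "b", "c")
  for (fmt in c("tsv", "graphml")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    exportNetwork(net, path, format = fmt)
    back <- readNetwork(path, format = fmt)
    expect_identical(networkEdges(back)[, c("from", "to", "method")],
                     networkEdges(net)[, c("from", "to", "method")])
    expect_setequal(geneIds(back), geneIds(net))
  }
  expect_error(exportNetwork(net, tempfile(), format = "dot"))
})

test_that("empty networks export to a valid GraphML document", {
  empty <- makeGeneNetwork(data.frame(from = character(),
                                      to = character()))
  path <- withr::local_tempfile(fileext = ".graphml")
  exportNetwork(empty, path, format = "graphml")
  doc <- xml2::read_xml(path)
  expect_identical(xml2::xml_name(doc), "graphml")
  back <- readNetwork(path, format = "graphml")
  expect_identical(nrow(networkEdges(back)), 0L)
})

test_that("GraphML edge elements match the published link count", {
  net <- sonReferenceNetwork("glasso")
  path <- withr::local_tempfile(fileext = ".graphml")
  exportNetwork(net, path, format = "graphml")
  doc <- xml2::read_xml(path)
  edges <- xml2::xml_find_all(doc, ".//*[local-name() = 'edge']")
  expect_identical(length(edges), 48L)
})

test_that("published pair tables collapse to the stated link counts", {
  glasso <- readPairTable(extfile("glasso_pairs.tsv"))
  expect_identical(nrow(glasso), 96L)
  expect_identical(nrow(collapsePairs(glasso)), 48L)
  pearson <- readPairTable(extfile("pearson_pairs.tsv"))
  expect_identical(nrow(pearson), 64L)
  expect_identical(nrow(collapsePairs(pearson)), 32L)
})

test_that("published networks reproduce gene counts, filter and hub", {
  glasso <- sonReferenceNetwork("glasso")
  pearson <- sonReferenceNetwork("pearson")
  expect_identical(length(geneIds(glasso)), 28L)
  expect_identical(nrow(networkEdges(glasso)), 48L)
  expect_identical(length(geneIds(pearson)), 47L)
  expect_identical(nrow(networkEdges(pearson)), 32L)
  # strict fan-out filter reproduces the published subnetworks
  gf <- richnessFilter(glasso, mode = "strict")
  pf <- richnessFilter(pearson, mode = "strict")
  expect_identical(length(geneIds(gf)), 14L)
  expect_identical(length(geneIds(pf)), 7L)
  # exactly one gene satisfies the criterion in both networks: Caprin2
  shared <- intersectNodes(gf, pf)
  expect_identical(shared, "1373260_at")
  ann <- readAnnotation(extfile("glasso_genes.tsv"))
  expect_identical(annotationSymbols(ann, shared), "Caprin2")
  # the most active nodal gene of the glasso network is Caprin2
  hr <- hubRank(glasso)
  expect_identical(hr$probe_id[1], "1373260_at")
  expect_identical(hr$symbol[1], "Caprin2")
})
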