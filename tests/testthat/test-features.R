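test_that("domain ranking returns signed, ordered, tie-broken lists", {
  rk <- rankDomains(c(0.3, -0.2, 0.5), familyIds = c("F1", "F2", "F3"),
                    n = 2)
  expect_equal(rk@indicative$family_id, c("F3", "F1"))
  expect_equal(rk@indicative$weight, c(0.5, 0.3))
  expect_equal(rk@indicative$rank, 1:2)
  expect_equal(rk@counterIndicative$family_id, "F2")
  expect_equal(rk@counterIndicative$weight, -0.2)

  # all-zero discriminant -> both lists empty
  z <- rankDomains(rep(0, 4), familyIds = paste0("F", 1:4))
  expect_equal(nrow(z@indicative), 0)
  expect_equal(nrow(z@counterIndicative), 0)

  # ties broken by lower family index
  t1 <- rankDomains(c(0.5, 0.5, -0.5, -0.5), paste0("F", 1:4), n = 1)
  expect_equal(t1@indicative$family_id, "F1")
  expect_equal(t1@counterIndicative$family_id, "F3")

  expect_error(rankDomains(c(1, 2), paste0("F", 1:2), n = 0),
               class = "pdValueError")
})

test_that("re-sorting both ranked lists by |weight| matches the full ordering", {
  set.seed(41)
  for (r in 1:5) {
    w <- round(rnorm(40), 3)
    ids <- sprintf("SF%05d", 1:40)
    rk <- rankDomains(w, ids, n = 10)
    got <- rbind(rk@indicative[, c("family_id", "weight")],
                 rk@counterIndicative[, c("family_id", "weight")])
    got <- got[order(-abs(got$weight), got$family_id), ]
    # brute-force: top entries of the full |w| ordering, restricted to the
    # families both lists could reach (rank <= 10 within their sign)
    keep <- got$family_id
    full <- data.frame(family_id = ids, weight = w)
    full <- full[full$family_id %in% keep, ]
    full <- full[order(-abs(full$weight), full$family_id), ]
    expect_equal(got$family_id, full$family_id)
    expect_equal(got$weight, full$weight)
    # no excluded family outranks an included one within its sign
    minPos <- min(c(Inf, rk@indicative$weight))
    maxNeg <- max(c(-Inf, rk@counterIndicative$weight))
    out <- setdiff(ids, keep)
    expect_true(all(w[match(out, ids)] <= minPos))
    expect_true(all(w[match(out, ids)] >= maxNeg))
  }
})

test_that("phylogenetic profiles threshold at count > 0", {
  m <- matrix(c(0, 2, 7,
                0, 0, 0,
                1, 1, 0), nrow = 3, byrow = TRUE,
              dimnames = list(c("FA", "FB", "FC"), c("o1", "o2", "o3")))
  cs <- DomainCountSet(m)
  pp <- phyloProfiles(cs, c("FA", "FB"))
  expect_equal(unname(pp["FA", ]), c(0, 1, 1))
  expect_equal(unname(pp["FB", ]), c(0, 0, 0))  # absent family kept
  # invariant under count scaling
  expect_equal(phyloProfiles(DomainCountSet(m * 9), c("FA", "FC")),
               phyloProfiles(cs, c("FA", "FC")))
  expect_error(phyloProfiles(cs, "FX"), class = "pdLookupError")
})

test_that("correlation distance handles anti-correlation and constants", {
  expect_equal(correlationDistance(c(1, 0, 1, 0), c(1, 0, 1, 0)), 0)
  expect_equal(correlationDistance(c(1, 0, 1, 0), c(0, 1, 0, 1)), 2)
  # hand-computed Pearson r = 0
  expect_equal(correlationDistance(c(1, 1, 0, 0), c(1, 0, 1, 0)), 1)
  # constant profile -> defined as 1
  expect_equal(correlationDistance(c(1, 1, 1), c(1, 0, 1)), 1)
  expect_equal(correlationDistance(c(0, 0, 0), c(0, 0, 0)), 1)
  # symmetry
  set.seed(43)
  for (r in 1:10) {
    p <- rbinom(8, 1, 0.5)
    q <- rbinom(8, 1, 0.5)
    expect_equal(correlationDistance(p, q), correlationDistance(q, p))
  }
  expect_error(correlationDistance(c(1, 0), c(1, 0, 1)),
               class = "pdValueError")
})

test_that("UPGMA reproduces the hand-computed 3-leaf tree", {
  D <- matrix(0, 3, 3, dimnames = rep(list(c("A", "B", "C")), 2))
  D["A", "B"] <- D["B", "A"] <- 0.2
  D["A", "C"] <- D["C", "A"] <- 0.6
  D["B", "C"] <- D["C", "B"] <- 0.8
  tr <- upgmaTree(D)
  expect_equal(tr@heights, c(0.2, 0.7))  # (0.6 + 0.8) / 2
  expect_equal(sort(tr@merges[1, ]), c(-2L, -1L))

  # 2 leaves: single merge at their distance
  D2 <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = rep(list(c("A", "B")), 2))
  tr2 <- upgmaTree(D2)
  expect_equal(tr2@heights, 0.4)

  expect_error(upgmaTree(matrix(c(0, Inf, Inf, 0), 2)),
               class = "pdValueError")
})

test_that("UPGMA agrees exactly with the naive O(n^3) oracle", {
  for (s in 1:20) {
    n <- sample(4:12, 1)
    D <- randomDistMatrix(n, seed = 500 + s)
    tr <- upgmaTree(D)
    ref <- naiveUPGMA(D)
    expect_equal(tr@heights, ref$height, tolerance = 1e-12)
    got <- t(apply(tr@merges, 1, sort))
    expect_identical(got, ref$merge)
    # ultrametricity: heights non-decreasing along any root path
    for (k in seq_len(nrow(tr@merges))) {
      for (child in tr@merges[k, ]) {
        if (child > 0) expect_gte(tr@heights[k], tr@heights[child])
      }
    }
  }
})

test_that("cluster coloring cuts at a fraction of the maximum height", {
  D <- matrix(0, 3, 3, dimnames = rep(list(c("A", "B", "C")), 2))
  D["A", "B"] <- D["B", "A"] <- 0.2
  D["A", "C"] <- D["C", "A"] <- 0.6
  D["B", "C"] <- D["C", "B"] <- 0.8
  tr <- upgmaTree(D)
  cl <- colorClusters(tr, 0.7)  # cut at 0.49: {A,B} colored, C singleton
  expect_equal(cl$cluster[cl$family_id == "A"],
               cl$cluster[cl$family_id == "B"])
  expect_false(cl$cluster[cl$family_id == "C"] ==
                 cl$cluster[cl$family_id == "A"])
  expect_true(is.na(cl$color[cl$family_id == "C"]))
  expect_false(any(is.na(cl$color[cl$family_id != "C"])))
  # threshold 1 -> one cluster; threshold ~0 -> all singletons
  expect_equal(length(unique(colorClusters(tr, 1)$cluster)), 1)
  tiny <- colorClusters(tr, 1e-9)
  expect_equal(length(unique(tiny$cluster)), 3)
  expect_true(all(is.na(tiny$color)))
})

test_that("raising the color threshold never splits a cluster", {
  D <- randomDistMatrix(10, seed = 77)
  tr <- upgmaTree(D)
  prev <- colorClusters(tr, 0.2)$cluster
  for (th in c(0.4, 0.6, 0.8, 1)) {
    cur <- colorClusters(tr, th)$cluster
    # refinement: same prev-cluster implies same cur-cluster
    for (g in unique(prev)) {
      expect_equal(length(unique(cur[prev == g])), 1)
    }
    prev <- cur
  }
})

test_that("phylogroup counts consider only organisms carrying the family", {
  m <- matrix(c(1, 2, 0,
                0, 0, 0,
                0, 0, 3), nrow = 3, byrow = TRUE,
              dimnames = list(c("FA", "FB", "FC"), c("o1", "o2", "o3")))
  cs <- DomainCountSet(m)
  gm <- c(o1 = "Firmicutes", o2 = "Firmicutes", o3 = "Proteobacteria")
  expect_equal(countPhylogroups(cs, "FA", gm), 1)
  expect_equal(countPhylogroups(cs, "FB", gm), 0)
  expect_equal(countPhylogroups(cs, "FC", gm), 1)
  gm2 <- c(o1 = "Firmicutes", o2 = "Proteobacteria", o3 = "Actinobacteria")
  expect_equal(countPhylogroups(cs, "FA", gm2), 2)
  expect_error(countPhylogroups(cs, "FA", gm[1:2]), class = "pdLookupError")
})

test_that("Newick export matches the expected text and parses back", {
  skip_if_not_installed("ape")
  D2 <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = rep(list(c("A", "B")), 2))
  txt2 <- exportNewick(upgmaTree(D2))
  ph2 <- ape::read.tree(text = txt2)
  expect_setequal(ph2$tip.label, c("A", "B"))
  expect_equal(unname(ph2$edge.length), c(0.4, 0.4))

  D <- matrix(0, 3, 3, dimnames = rep(list(c("A", "B", "C")), 2))
  D["A", "B"] <- D["B", "A"] <- 0.2
  D["A", "C"] <- D["C", "A"] <- 0.6
  D["B", "C"] <- D["C", "B"] <- 0.8
  txt3 <- exportNewick(upgmaTree(D))
  ph3 <- ape::read.tree(text = txt3)
  # leaf depths equal the root height (ultrametric), AB split at 0.2
  depths <- ape::node.depth.edgelength(ph3)[1:3]
  expect_equal(unname(depths), rep(0.7, 3), tolerance = 1e-9)
  coph <- ape::cophenetic.phylo(ph3)
  expect_equal(coph["A", "B"], 0.4, tolerance = 1e-9)   # 2 * 0.2
  expect_equal(coph["A", "C"], 1.4, tolerance = 1e-9)   # 2 * 0.7

  # parse-back preserves topology and heights on random trees
  for (s in 1:5) {
    D <- randomDistMatrix(8, seed = 900 + s)
    tr <- upgmaTree(D)
    ph <- ape::read.tree(text = exportNewick(tr))
    expect_equal(sort(ph$tip.label), sort(tr@labels))
    got <- ape::cophenetic.phylo(ph)
    ref <- 2 * upgmaCophenetic(tr)
    expect_equal(got[rownames(ref), colnames(ref)], ref, tolerance = 1e-9)
  }
})
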