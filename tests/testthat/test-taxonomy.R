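test_that("a minimal taxdump loads and structural defects are caught", {
    d <- withr::local_tempdir()
    p <- writeToyDump(d, rbind(c(1, 1, "no rank"),
                               c(2759, 1, "superkingdom"),
                               c(3702, 2759, "species")))
    tree <- loadTaxdump(p$nodes, p$names)
    expect_s4_class(tree, "TaxonomyTree")
    expect_equal(nTaxa(tree), 3L)
    expect_equal(tree@rootTaxid, 1L)
    expect_equal(taxName(tree, 3702L), "n3702")

    ## cycle 5 <-> 6
    p2 <- writeToyDump(file.path(d, "cyc"),
                       rbind(c(1, 1, "no rank"), c(5, 6, "genus"),
                             c(6, 5, "genus")))
    expect_error(loadTaxdump(p2$nodes, p2$names), "cyclic.*[56]")

    ## parent absent
    p3 <- writeToyDump(file.path(d, "orph"),
                       rbind(c(1, 1, "no rank"), c(7, 99, "genus")))
    expect_error(loadTaxdump(p3$nodes, p3$names), "absent")

    ## no root
    p4 <- writeToyDump(file.path(d, "noroot"),
                       rbind(c(4, 5, "genus"), c(5, 4, "genus")))
    expect_error(loadTaxdump(p4$nodes, p4$names), "root")
})

test_that("a generated 200-node taxdump round-trips its edge list", {
    d <- withr::local_tempdir()
    td <- makeTaxdump(d, depth = 4, branching = 3, nModels = 10, seed = 11)
    tree <- loadTaxdump(td$nodesPath, td$namesPath, td$mergedPath,
                        td$delnodesPath)
    expect_setequal(taxIds(tree), td$edges$taxid)
    m <- match(td$edges$taxid, taxIds(tree))
    expect_equal(tree@parentTaxid[m], td$edges$parent)
    expect_equal(tree@rank[m], td$edges$rank)
    ## only scientific-name entries populate names
    expect_false(any(grepl("alias", tree@sciName)))
    ## merged/deleted dumps picked up
    expect_equal(unname(tree@merged[["99999"]]), td$eukSpecies[1L])
    expect_equal(tree@deleted, 88888L)
})

test_that("lineage walks root-first and matches a recursive parent walk", {
    tree <- toyTree()
    expect_equal(lineage(tree, 1L), 1L)
    expect_equal(lineage(tree, 3702L), c(1L, 131567L, 2759L, 3699L, 3702L))
    expect_error(lineage(tree, 999L), "unknown taxid")

    recWalk <- function(t) {
        p <- tree@parentTaxid[match(t, tree@taxid)]
        if (p == t) t else c(recWalk(p), t)
    }
    for (t in taxIds(tree))
        expect_equal(lineage(tree, t), recWalk(t))
})

test_that("lca matches the lineage-intersection oracle and its algebra", {
    tree <- toyTree()
    expect_equal(lca(tree, 3702L), 3702L)           # singleton
    expect_equal(lca(tree, c(3702L, 3699L)), 3699L) # nested
    expect_equal(lca(tree, c(3702L, 3703L)), 3699L)
    expect_equal(lca(tree, c(3702L, 562L)), 131567L)
    expect_equal(lca(tree, c(3702L, 11250L)), 1L)
    expect_error(lca(tree, integer(0)), "non-empty")

    set.seed(42)
    rt <- randomTaxonomy(60L)
    for (i in 1:50) {
        pair <- sample(taxIds(rt), 2L)
        expect_equal(lca(rt, pair), lcaOracle(rt, pair))
        expect_equal(lca(rt, pair), lca(rt, rev(pair)))  # commutative
    }
    ## associativity over set union + ancestor-of-all property
    for (i in 1:20) {
        s <- sample(taxIds(rt), 4L)
        expect_equal(lca(rt, s),
                     lca(rt, c(lca(rt, s[1:2]), lca(rt, s[3:4]))))
        expect_true(all(vapply(s, function(t)
            lca(rt, s) %in% lineage(rt, t), logical(1))))
    }
})

test_that("superkingdom binning follows the anchor lineage", {
    tree <- toyTree()
    cfg <- pipelineConfig()
    expect_equal(superkingdomOf(tree, 3702L, cfg), "Eukaryote")
    expect_equal(superkingdomOf(tree, 2759L, cfg), "Eukaryote")  # anchor
    expect_equal(superkingdomOf(tree, 562L, cfg), "Prokaryote")
    expect_equal(superkingdomOf(tree, 2287L, cfg), "Prokaryote")
    expect_equal(superkingdomOf(tree, 11250L, cfg), "Viruses")
    expect_equal(superkingdomOf(tree, 1L, cfg), "Undetermined")
    expect_equal(superkingdomOf(tree, 131567L, cfg), "Undetermined")
    expect_equal(superkingdomOf(tree, 12908L, cfg), "Undetermined")
    ## constant along any lineage suffix below an anchor
    lin <- lineage(tree, 3702L)
    below <- lin[which(lin == 2759L):length(lin)]
    expect_true(all(superkingdomOf(tree, below, cfg) == "Eukaryote"))
})

test_that("resolveTaxids remaps merged ids and drops deleted/unknown", {
    d <- withr::local_tempdir()
    td <- makeTaxdump(d, depth = 3, branching = 2, nModels = 2, seed = 3)
    tree <- loadTaxdump(td$nodesPath, td$namesPath, td$mergedPath,
                        td$delnodesPath)
    keepId <- td$eukSpecies[2L]
    expect_equal(resolveTaxids(tree, c(99999L, keepId)),
                 c(td$eukSpecies[1L], keepId))
    expect_warning(out <- resolveTaxids(tree, c(88888L, keepId)),
                   "deleted")
    expect_equal(out, keepId)
    expect_warning(out2 <- resolveTaxids(tree, c(77777L, keepId)),
                   "absent")
    expect_equal(out2, keepId)
})
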