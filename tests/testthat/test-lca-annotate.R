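hitRow <- function(q, taxids, bitscore, evalue = 1e-9)
    data.frame(qseqid = q, sseqid = "s", pident = 90, length = 100,
               evalue = evalue, bitscore = bitscore,
               staxids = I(list(as.integer(taxids))))

test_that("the E-value gate and bitscore margin act in order", {
    cfg <- pipelineConfig()
    one <- hitRow("q", 3702, 100, evalue = 1e-9)
    expect_equal(nrow(filterHits(one, cfg)), 1L)   # best hit kept

    ## enumerated against the threshold formula: 0.9 * 100 = 90.0
    hits <- do.call(rbind, list(hitRow("q", 1, 100), hitRow("q", 2, 91),
                                hitRow("q", 3, 89)))
    kept <- filterHits(hits, cfg)
    expect_equal(kept$bitscore, c(100, 91))        # boundary inclusive

    expect_equal(nrow(filterHits(hitRow("q", 1, 100, evalue = 1e-5),
                                 cfg)), 0L)        # E-value gate
    ## a bad-E high scorer cannot set the margin baseline
    mix <- rbind(hitRow("q", 1, 500, evalue = 1e-3),
                 hitRow("q", 2, 100), hitRow("q", 3, 91))
    expect_equal(filterHits(mix, cfg)$bitscore, c(100, 91))
    ## empty in -> empty out
    expect_equal(nrow(filterHits(hits[0, ], cfg)), 0L)
})

test_that("shrinking the margin never adds hits and nests the LCA", {
    tree <- toyTree()
    set.seed(4)
    for (i in 1:25) {
        n <- sample(2:8, 1)
        hits <- do.call(rbind, lapply(seq_len(n), function(j)
            hitRow("q", sample(c(3702, 3703, 4001, 4002, 562), 1),
                   runif(1, 50, 100))))
        wide <- filterHits(hits, pipelineConfig(scoreMargin = 0.3))
        narrow <- filterHits(hits, pipelineConfig(scoreMargin = 0.05))
        expect_true(all(narrow$bitscore %in% wide$bitscore))
        lcaW <- lca(tree, unlist(wide$staxids))
        lcaN <- lca(tree, unlist(narrow$staxids))
        expect_true(lcaW %in% lineage(tree, lcaN))  # descendant-or-self
    }
})

test_that("proteins are annotated by pooled-subject LCA with subtypes", {
    tree <- toyTree()
    ## singleton LCA: fungal-like species -> Eukaryote at that species
    ann <- annotateProteins("p_1.g1", hitRow("p_1.g1", 3702, 100), tree)
    expect_equal(ann$lca_taxid, 3702L)
    expect_equal(ann$bin, "Eukaryote")
    expect_equal(ann$subtype, "none")

    ## two species sharing a genus-like parent -> that parent, Eukaryote
    two <- rbind(hitRow("p_1.g1", 3702, 100), hitRow("p_1.g1", 3703, 95))
    ann <- annotateProteins("p_1.g1", two, tree)
    expect_equal(ann$lca_taxid, lca(tree, c(3702L, 3703L)))
    expect_equal(ann$bin, "Eukaryote")

    ## multi-taxid subjects are flattened before the LCA
    multi <- hitRow("p_1.g1", c(3702, 3703), 100)
    expect_equal(annotateProteins("p_1.g1", multi, tree)$lca_taxid, 3699L)

    ## no hits at all -> Undetermined/no_hit
    ann <- annotateProteins("p_1.g1", NULL, tree)
    expect_equal(ann$bin, "Undetermined")
    expect_equal(ann$subtype, "no_hit")
    expect_true(is.na(ann$lca_taxid))

    ## LCA on an untraceable branch
    ann <- annotateProteins("p_1.g1", hitRow("p_1.g1", 12908, 100), tree)
    expect_equal(ann$subtype, "untraceable")

    ## eukaryote + bacterium -> LCA above every anchor
    cross <- rbind(hitRow("p_1.g1", 3702, 100), hitRow("p_1.g1", 562, 95))
    ann <- annotateProteins("p_1.g1", cross, tree)
    expect_equal(ann$lca_taxid, 131567L)
    expect_equal(ann$subtype, "above_superkingdom")

    ## unresolvable subjects -> untraceable with warning
    expect_warning(
        ann <- annotateProteins("p_1.g1", hitRow("p_1.g1", 987654, 100),
                                tree),
        "untraceable|absent")
    expect_equal(ann$subtype, "untraceable")

    ## hit order within a query never changes the result
    perm <- cross[2:1, ]
    expect_equal(annotateProteins("p_1.g1", perm, tree)$lca_taxid,
                 131567L)
})

test_that("every protein lands in exactly one bin and metadata is parsed", {
    tree <- toyTree()
    ids <- sprintf("ctg%d_330001.g%d", rep(1:4, each = 3), 1:3)
    hits <- do.call(rbind, lapply(ids[1:8], function(p)
        hitRow(p, sample(c(3702, 3703, 562, 11250), 1),
               runif(1, 80, 120))))
    ann <- annotateProteins(ids, hits, tree)
    expect_equal(nrow(ann), length(ids))
    expect_true(all(table(ann$protein_id) == 1L))
    expect_true(all(ann$bin %in% c("Eukaryote", "Prokaryote", "Viruses",
                                   "Undetermined")))
    ## bin == Undetermined <=> subtype != none
    expect_equal(ann$bin == "Undetermined", ann$subtype != "none")
    expect_equal(ann$contig_id[1], "ctg1")
    expect_equal(ann$metagenome_id[1], "330001")

    summ <- summarizeSuperkingdoms(ann)
    expect_equal(summ$Total[summ$bin == "Total"], length(ids))
    expect_equal(sum(summ$Total[summ$bin != "Total"]), length(ids))
})

test_that("superkingdom percentages reproduce planted and printed splits", {
    ## planted 60/30/5/5 split
    ann <- data.frame(
        bin = rep(c("Eukaryote", "Prokaryote", "Viruses", "Undetermined"),
                  c(60, 30, 5, 5)),
        batch = "b")
    summ <- summarizeSuperkingdoms(ann)
    expect_equal(summ$pct, c(60, 30, 5, 5, 100))
    ## rounded percentages sum to 100 +- 0.2
    expect_lt(abs(sum(summ$pct[summ$bin != "Total"]) - 100), 0.2)

    ## single Eukaryote protein -> 100%
    one <- summarizeSuperkingdoms(data.frame(bin = "Eukaryote",
                                             batch = "b"))
    expect_equal(one$pct[one$bin == "Eukaryote"], 100)
})

test_that("rank distribution reports the species-level fraction", {
    tree <- toyTree()
    ann <- data.frame(lca_taxid = c(3702L, 3703L, 4001L,
                                    rep(3699L, 4), rep(4000L, 3)))
    rd <- rankDistribution(ann, tree)
    expect_equal(rd$fraction[rd$rank == "species"], 0.3)
    expect_equal(rd$fraction[rd$rank == "order"], 0.7)
    expect_equal(sum(rd$n), 10L)

    allSp <- rankDistribution(data.frame(lca_taxid = c(3702L, 4001L)),
                              tree)
    expect_equal(allSp$fraction[allSp$rank == "species"], 1.0)
})

test_that("hit tables round-trip through the tabular reader", {
    d <- withr::local_tempdir()
    f <- file.path(d, "hits.tsv")
    writeLines(c("p1\tref1\t95.0\t120\t1e-30\t200.0\t3702",
                 "p1\tref2\t90.0\t110\t1e-20\t185.0\t3702;3703",
                 "p2\tref3\t88.0\t100\t1e-10\t90.0\t562"), f)
    hits <- readHitTable(f)
    expect_equal(nrow(hits), 3L)
    expect_equal(hits$staxids[[2]], c(3702L, 3703L))
    expect_equal(hits$bitscore, c(200, 185, 90))
    expect_error(readHitTable(f, columns = c("qseqid", "evalue")),
                 "must include")
})
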