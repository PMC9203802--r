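test_that("length summaries keep exact integer bookkeeping", {
    ls <- lengthSummary(10L)
    expect_equal(ls$mean_aa, 10)
    expect_equal(ls$median_aa, 10)

    sym <- lengthSummary(c(100L, 200L, 300L))
    expect_equal(sym$skewness, 0)

    set.seed(2)
    x <- sample(50:500, 1000, replace = TRUE)
    ls <- lengthSummary(x)
    expect_equal(ls$mean_aa * ls$n, ls$total_aa)
    expect_error(lengthSummary(integer(0)), "n >= 1")
})

test_that("the published per-protein mean reproduces from its counts", {
    ## 271,456 proteins totalling 37,520,032 aa -> 138 aa/protein
    lens <- rep(138L, 271456L)
    lens[1] <- lens[1] + (37520032 - sum(as.numeric(lens)))
    ls <- lengthSummary(lens)
    expect_equal(ls$total_aa, 37520032)
    expect_equal(ls$mean_aa_rounded, 138)
})

test_that("the unequal-variance t statistic matches the closed form", {
    a <- c(0, 0, 1, 1); b <- c(1, 1, 2, 2)
    res <- welchT(a, b)
    expect_equal(round(res$t, 3), -2.449)  # hand Welch formula
    expect_lt(res$p, 0.1)
    ## identical groups -> t == 0; reorder invariance
    expect_equal(welchT(c(1, 2, 3), c(3, 2, 1))$t, 0)
    expect_equal(welchT(sample(a), sample(b))$t, res$t)
    ## sign convention: positive when mean(a) > mean(b)
    expect_gt(welchT(b, a)$t, 0)
    expect_error(welchT(c(1, 1), c(1, 1)), "constant")
})

test_that("longer re-predicted proteins are detected at reduced n", {
    set.seed(77)
    aug <- rlnorm(10000, log(405), 0.5)
    pro <- rlnorm(10000, log(138), 0.5)
    res <- welchT(aug, pro)
    expect_gt(res$t, 0)
    expect_lt(res$p, 1e-4)
})

test_that("intron spans derive from exon arithmetic", {
    ## exons (1,400) and (501,1000): span 1000, exonic 900, fraction 0.10
    ex <- data.frame(gene_id = "g1", contig_id = "c1",
                     start = c(1L, 501L), end = c(400L, 1000L))
    st <- intronStats(ex)
    expect_equal(st$per_gene$gene_span, 1000L)
    expect_equal(st$per_gene$intron_span, 100L)
    expect_equal(st$per_gene$intron_fraction, 0.10)

    ## single-exon genes carry no introns and are excluded from the mean
    ex2 <- rbind(ex, data.frame(gene_id = "g2", contig_id = "c1",
                                start = 1L, end = 300L))
    st2 <- intronStats(ex2)
    expect_equal(st2$n_genes, 2L)
    expect_equal(st2$n_genes_with_introns, 1L)
    expect_equal(st2$mean_intron_fraction, 0.10)
    expect_true(all(st2$per_gene$intron_fraction >= 0 &
                    st2$per_gene$intron_fraction < 1))

    bad <- data.frame(gene_id = "g", contig_id = "c",
                      start = c(1L, 300L), end = c(400L, 600L))
    expect_error(intronStats(bad), "overlap")
})

test_that("generated gene structures recover the planted intron fraction", {
    d <- withr::local_tempdir()
    spec <- communitySpec(nContigs = 800L, eukContigFraction = 0.5,
                          intronRate = 0.5, writeFasta = FALSE,
                          seed = 31L)
    td <- makeTaxdump(file.path(d, "tax"), seed = 31L)
    com <- makeCommunity(spec, td, d)
    exons <- readGeneStructures(com$predictionGff)
    st <- intronStats(exons)
    expect_equal(st$n_genes, nrow(com$proteins))
    expect_equal(st$n_genes_with_introns, sum(com$proteins$has_intron))
    expect_lt(abs(st$mean_intron_fraction - 0.17), 0.005)
})

test_that("both BUSCO dialects parse and validate", {
    d <- withr::local_tempdir()
    short <- file.path(d, "short.txt")
    ## printed reference row: complete 100 = single 12.9 + dup 87.1
    writeLines(c("# BUSCO version is: 4.0.2",
                 "\tC:100.0%[S:12.9%,D:87.1%],F:0.0%,M:0.0%,n:255"),
               short)
    s <- parseBuscoTable(short, "mg1", "mix")
    expect_equal(s$complete_pct, 100)
    expect_equal(s$single_pct + s$duplicated_pct, s$complete_pct)
    expect_equal(s$n_markers, 255L)

    allMissing <- file.path(d, "miss.txt")
    writeLines("\tC:0.0%[S:0.0%,D:0.0%],F:0.0%,M:100.0%,n:255",
               allMissing)
    m <- parseBuscoTable(allMissing)
    expect_equal(m$complete_pct, 0)
    expect_equal(m$missing_pct, 100)

    full <- file.path(d, "full.tsv")
    writeLines(c("# Busco id\tStatus\tSequence",
                 "b1\tComplete\ts1", "b2\tDuplicated\ts2",
                 "b2\tDuplicated\ts3", "b3\tFragmented\ts4",
                 "b4\tMissing\t"), full)
    f <- parseBuscoTable(full, "mg2")
    expect_equal(f$n_markers, 4L)
    expect_equal(f$complete_pct, 50)   # b1 single + b2 duplicated
    expect_equal(f$fragmented_pct, 25)
    expect_equal(f$missing_pct, 25)

    inconsistent <- file.path(d, "inc.txt")
    writeLines("\tC:50.0%[S:10.0%,D:20.0%],F:25.0%,M:25.0%,n:255",
               inconsistent)
    expect_warning(parseBuscoTable(inconsistent), "S \\+ D")
})

test_that("paired BUSCO comparison counts improvements correctly", {
    mk <- function(mg, comp, frag) data.frame(
        metagenome_id = mg, method = "x", complete_pct = comp,
        single_pct = comp, duplicated_pct = 0,
        fragmented_pct = frag, missing_pct = 100 - comp - frag,
        n_markers = 255L)
    a <- mk(c("m1", "m2"), c(90, 80), c(5, 10))
    b <- mk(c("m1", "m2"), c(80, 80), c(10, 10))
    res <- compareBusco(a, b)
    expect_equal(res$n_improved, 1L)
    expect_equal(res$mean_improvement, 10)
    expect_equal(res$n_a_ge_b, 2L)
    expect_false(res$no_difference)

    ident <- compareBusco(a, a)
    expect_true(ident$no_difference)
    expect_equal(ident$n_improved, 0L)
    expect_true(is.na(ident$wilcox_complete_p))

    ## pairing is by metagenome id, not row order
    res2 <- compareBusco(a, b[2:1, ])
    expect_equal(res2$mean_improvement, res$mean_improvement)
    expect_error(compareBusco(a, mk(c("m1", "m9"), c(1, 2), c(0, 0))),
                 "pairing")
})

test_that("cluster bookkeeping counts representatives and subsets FASTA", {
    d <- withr::local_tempdir()
    tsv <- file.path(d, "cl.tsv")
    writeLines(c("r1\tr1", "r1\tm2", "r1\tm3", "r4\tr4"), tsv)
    prot <- Biostrings::AAStringSet(c(r1 = "MKV", m2 = "MKL", m3 = "MKI",
                                      r4 = "MAA"))
    cs <- clusterSummary(tsv, prot)
    expect_equal(cs$n_clusters, 2L)
    expect_setequal(cs$representatives, c("r1", "r4"))
    expect_equal(sort(names(cs$representative_seqs)), c("r1", "r4"))
    expect_equal(nrow(cs$membership), cs$n_members + 0L)
    ## representatives are members; sizes sum to member count
    expect_true(all(cs$representatives %in% cs$membership$member_id))

    ## five singletons -> five representatives
    writeLines(sprintf("p%d\tp%d", 1:5, 1:5), tsv)
    expect_equal(clusterSummary(tsv)$n_clusters, 5L)

    ## representative never listed as its own member -> error
    writeLines(c("r1\tm2"), tsv)
    expect_error(clusterSummary(tsv), "own member")

    ## unknown member -> warning
    writeLines(c("r1\tr1", "r1\tzz"), tsv)
    expect_warning(clusterSummary(tsv, prot), "absent")
})

test_that("planted 2x redundancy yields half as many clusters", {
    d <- withr::local_tempdir()
    spec <- communitySpec(nContigs = 300L, eukContigFraction = 0.5,
                          writeFasta = FALSE, seed = 13L)
    td <- makeTaxdump(file.path(d, "tax"), seed = 13L)
    com <- makeCommunity(spec, td, d)
    prot <- Biostrings::readAAStringSet(com$proteinFasta)
    cs <- clusterSummary(com$clusterTsv, prot)
    expect_equal(cs$n_clusters, ceiling(length(prot) / 2))
    expect_equal(cs$n_members, length(prot))
})
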