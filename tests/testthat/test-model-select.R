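## Fig.-3-like toy phylogeny: a malvid polytomy in which only two orders
## carry a model species, plus a mammal clade with a single model
malvidTree <- function() {
    df <- rbind(
        c(1, 1, "no rank"), c(131567, 1, "no rank"),
        c(2759, 131567, "superkingdom"),
        c(35000, 2759, "clade"),         # malvids
        c(3699, 35000, "order"),         # Brassicales
        c(3702, 3699, "species"),        # A. thaliana (model)
        c(370201, 3702, "strain"),
        c(41938, 35000, "order"),        # Malvales
        c(3641, 41938, "species"),       # T. cacao (model)
        c(41937, 35000, "order"),        # a third malvid order
        c(43000, 41937, "species"),
        c(40674, 2759, "class"),         # Mammalia
        c(9989, 40674, "order"),
        c(10090, 9989, "species"),       # no model below Mammalia but one
        c(9606, 40674, "species"))       # H. sapiens (model)
    new("TaxonomyTree", taxid = as.integer(df[, 1]),
        parentTaxid = as.integer(df[, 2]), rank = df[, 3],
        sciName = as.character(df[, 1]), rootTaxid = 1L)
}

malvidCatalog <- function()
    modelCatalog(c("Arabidopsis thaliana", "Theobroma cacao",
                   "Homo sapiens"),
                 c(3702L, 3641L, 9606L))

test_that("subtree model sets match the exhaustive descendant scan", {
    tree <- malvidTree()
    cat3 <- malvidCatalog()
    sets <- modelsInSubtree(tree, cat3)
    expect_equal(sets[["3702"]], "Arabidopsis thaliana")  # model leaf
    expect_length(sets[["1"]], 3L)                        # conservation
    expect_equal(sets[["35000"]],
                 c("Arabidopsis thaliana", "Theobroma cacao"))
    expect_equal(sets[["41937"]], character(0))
    expect_error(modelsInSubtree(tree, modelCatalog("ghost", 424242L)),
                 "ghost")

    set.seed(8)
    for (i in 1:10) {
        rt <- randomTaxonomy(300L)
        planted <- sample(3:300, 10L)
        cat10 <- modelCatalog(sprintf("m%02d", 1:10), planted)
        sets <- modelsInSubtree(rt, cat10)
        for (node in sample(taxIds(rt), 25L))
            expect_equal(sets[[as.character(node)]],
                         modelsBelowBrute(rt, cat10, node))
    }
})

test_that("pass 1 resolves sole-representative clades and flags polytomies", {
    tree <- malvidTree()
    sets <- modelsInSubtree(tree, malvidCatalog())

    r <- assignPass1(3699L, tree, sets)   # Brassicales: sole model below
    expect_equal(r$model, "Arabidopsis thaliana")
    expect_equal(r$pass, 1L)
    expect_length(r$candidates, 0L)

    r <- assignPass1(10090L, tree, sets)  # any mammal -> the sole model
    expect_equal(r$model, "Homo sapiens")

    r <- assignPass1(3702L, tree, sets)   # a model species itself
    expect_equal(r$model, "Arabidopsis thaliana")

    r <- assignPass1(370201L, tree, sets) # strain below the model
    expect_equal(r$model, "Arabidopsis thaliana")

    r <- assignPass1(43000L, tree, sets)  # third malvid order: ambiguous
    expect_equal(r$model, "AMBIGUOUS")
    expect_equal(r$candidates,
                 c("Arabidopsis thaliana", "Theobroma cacao"))

    r <- assignPass1(2759L, tree, sets)   # at the anchor: all models
    expect_equal(r$model, "AMBIGUOUS")
    expect_length(r$candidates, 3L)

    expect_error(assignPass1(131567L, tree, sets), "Eukaryota")
})

test_that("pass 2 follows per-batch pass-1 frequency with documented ties", {
    amb <- data.frame(contig_id = c("x", "y", "z"),
                      batch = c("T1", "PA", "T3"),
                      stringsAsFactors = FALSE)
    amb$candidates <- list(c("Theobroma cacao", "Arabidopsis thaliana"),
                           c("Theobroma cacao", "Arabidopsis thaliana"),
                           c("Theobroma cacao", "Arabidopsis thaliana"))
    freq <- data.frame(
        batch = c("T1", "T1", "PA", "PA"),
        model_name = rep(c("Theobroma cacao", "Arabidopsis thaliana"), 2),
        n = c(5L, 2L, 1L, 7L))
    got <- assignPass2(amb, freq)
    expect_equal(got[1], "Theobroma cacao")       # cacao dominates T1
    expect_equal(got[2], "Arabidopsis thaliana")  # thaliana dominates PA
    ## T3 has no pass-1 counts: global counts (cacao 6 vs thaliana 9)
    expect_equal(got[3], "Arabidopsis thaliana")

    ## exact tie -> lexicographically smaller model name
    tie <- data.frame(contig_id = "t", batch = "b")
    tie$candidates <- list(c("B_model", "A_model"))
    expect_equal(assignPass2(tie, data.frame(batch = "b",
                                             model_name = c("A_model",
                                                            "B_model"),
                                             n = c(5L, 5L))), "A_model")
    ## all-zero everywhere -> lexicographic
    expect_equal(assignPass2(tie, data.frame(batch = character(0),
                                             model_name = character(0),
                                             n = integer(0))), "A_model")
})

test_that("the full two-pass assignment matches a hand-derived table", {
    tree <- malvidTree()
    contigs <- data.frame(
        contig_id = sprintf("c%d", 1:8),
        taxid = c(3699L, 3641L, 3641L, 43000L,   # T1
                  3702L, 3702L, 43000L, 10090L), # PA
        batch = rep(c("T1", "PA"), each = 4))
    res <- assignModels(contigs, tree, malvidCatalog())
    a <- res$assignments
    expect_equal(a$model_name,
                 c("Arabidopsis thaliana", "Theobroma cacao",
                   "Theobroma cacao", "Theobroma cacao",
                   "Arabidopsis thaliana", "Arabidopsis thaliana",
                   "Arabidopsis thaliana", "Homo sapiens"))
    expect_equal(a$pass, c(1L, 1L, 1L, 2L, 1L, 1L, 2L, 1L))
    ## pass-2 choices recorded with their candidate sets
    expect_equal(a$candidates[4],
                 "Arabidopsis thaliana;Theobroma cacao")
    expect_true(all(vapply(which(a$pass == 2L), function(i)
        a$model_name[i] %in% strsplit(a$candidates[i], ";")[[1]],
        logical(1))))
    ## every contig got exactly one model
    expect_false(any(a$model_name == "AMBIGUOUS"))

    ## determinism: shuffled input gives identical per-contig assignments
    perm <- contigs[sample(nrow(contigs)), ]
    res2 <- assignModels(perm, tree, malvidCatalog())
    m <- match(a$contig_id, res2$assignments$contig_id)
    expect_equal(res2$assignments$model_name[m], a$model_name)
})

test_that("ancestor-or-self pass 1 equals literal leaf-to-root labelling", {
    set.seed(99)
    for (i in 1:60) {
        rt <- randomTaxonomy(sample(20:60, 1))
        nm <- sample(2:4, 1)
        planted <- sample(3:nTaxa(rt), nm)
        cat <- modelCatalog(sprintf("m%d", seq_len(nm)), planted)
        sets <- modelsInSubtree(rt, cat)
        cfg <- randomConfig()
        for (tx in sample(setdiff(taxIds(rt), 1L), 5L)) {
            mine <- assignPass1(tx, rt, sets, cfg)
            lit <- literalPass1(rt, cat, tx)
            expect_equal(mine$model, lit$model)
            expect_equal(mine$candidates, lit$candidates)
        }
    }
})
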