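## Shared fixtures and independent oracles.  The oracles deliberately use
## brute-force formulations (lineage intersection, exhaustive descendant
## scans, literal leaf-to-root region labelling) so they stay independent
## of the package's bottom-up implementations.

## hand-built toy taxonomy: root / cellular organisms layout with a small
## eukaryotic clade, two bacterial species, one virus, untraceable nodes
toyTree <- function() {
    df <- rbind(
        c(1, 1, "no rank", "root"),
        c(131567, 1, "no rank", "cellular organisms"),
        c(2, 131567, "superkingdom", "Bacteria"),
        c(2157, 131567, "superkingdom", "Archaea"),
        c(2759, 131567, "superkingdom", "Eukaryota"),
        c(10239, 1, "superkingdom", "Viruses"),
        c(12908, 1, "no rank", "unclassified sequences"),
        c(32644, 1, "no rank", "other sequences"),
        c(3699, 2759, "order", "Brassicales-like order"),
        c(3702, 3699, "species", "model plant"),
        c(3703, 3699, "species", "sister plant"),
        c(4000, 2759, "order", "second order"),
        c(4001, 4000, "species", "species A"),
        c(4002, 4000, "species", "species B"),
        c(562, 2, "species", "coli-like"),
        c(1280, 2, "species", "second bacterium"),
        c(2287, 2157, "species", "an archaeon"),
        c(11250, 10239, "species", "a virus"))
    new("TaxonomyTree",
        taxid = as.integer(df[, 1]), parentTaxid = as.integer(df[, 2]),
        rank = df[, 3], sciName = df[, 4], rootTaxid = 1L)
}

## random taxonomy: node 1 root, node 2 the Eukaryota anchor, all others
## attached uniformly below node 2 (so every non-root node is eukaryotic)
randomTaxonomy <- function(nNodes) {
    stopifnot(nNodes >= 3L)
    pickParent <- function(i) {            # avoid sample()'s scalar rule
        pool <- 2:(i - 1L)
        pool[sample.int(length(pool), 1L)]
    }
    parent <- c(1L, 1L, vapply(3:nNodes, pickParent, integer(1)))
    ranks <- c("no rank", "superkingdom",
               sample(c("phylum", "class", "order", "family", "genus",
                        "species"), nNodes - 2L, replace = TRUE))
    new("TaxonomyTree", taxid = seq_len(nNodes), parentTaxid = parent,
        rank = ranks, sciName = sprintf("node %d", seq_len(nNodes)),
        rootTaxid = 1L)
}

randomConfig <- function() {
    ## anchors for randomTaxonomy(): node 2 is Eukaryota; the other
    ## anchors point outside the tree on purpose (never matched)
    pipelineConfig(superkingdomAnchors = c(Bacteria = 900001L,
                                           Archaea = 900002L,
                                           Eukaryota = 2L,
                                           Viruses = 900003L))
}

## deepest node common to every member's lineage, via set intersection
lcaOracle <- function(tree, taxids) {
    lins <- lapply(taxids, function(t) lineage(tree, t))
    common <- Reduce(intersect, lins)
    depths <- vapply(common, function(t) length(lineage(tree, t)),
                     integer(1))
    common[which.max(depths)]
}

## models whose taxid lies in the subtree of `node`, by exhaustive scan
modelsBelowBrute <- function(tree, catalog, node) {
    below <- vapply(catalog@modelTaxid, function(mt)
        node %in% lineage(tree, mt), logical(1))
    sort(catalog@modelName[below])
}

## literal leaf-to-root labelling: from each model species walk towards
## the root, labelling nodes with that model until a node whose subtree
## holds a second model is met; a query walks up to the first labelled
## node (resolved) or the first multi-model node (ambiguous)
literalPass1 <- function(tree, catalog, taxid) {
    labels <- character(0)
    for (j in seq_along(catalog@modelName)) {
        cur <- catalog@modelTaxid[j]
        repeat {
            others <- any(vapply(
                seq_along(catalog@modelTaxid)[-j], function(k)
                    cur %in% lineage(tree, catalog@modelTaxid[k]),
                logical(1)))
            if (others) break
            labels[as.character(cur)] <- catalog@modelName[j]
            if (cur == tree@rootTaxid) break
            cur <- tree@parentTaxid[match(cur, tree@taxid)]
        }
    }
    cur <- taxid
    repeat {
        key <- as.character(cur)
        if (!is.na(labels[key]))
            return(list(model = unname(labels[key]),
                        candidates = character(0)))
        mb <- modelsBelowBrute(tree, catalog, cur)
        if (length(mb) > 1L)
            return(list(model = "AMBIGUOUS", candidates = mb))
        if (cur == tree@rootTaxid)
            stop("no model above ", taxid)
        cur <- tree@parentTaxid[match(cur, tree@taxid)]
    }
}

## minimal taxdump writer for parser tests
writeToyDump <- function(dir, nodes, names = NULL) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    np <- file.path(dir, "nodes.dmp")
    writeLines(apply(nodes, 1, function(r)
        paste0(paste(r, collapse = "\t|\t"), "\t|")), np)
    mp <- file.path(dir, "names.dmp")
    if (is.null(names))
        names <- cbind(nodes[, 1], paste0("n", nodes[, 1]), "",
                       "scientific name")
    writeLines(apply(names, 1, function(r)
        paste0(paste(r, collapse = "\t|\t"), "\t|")), mp)
    list(nodes = np, names = mp)
}
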