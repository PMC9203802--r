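## Taxonomy parsing and queries: lineage, LCA, superkingdom binning.
## The taxdump dialect is pipe-and-tab delimited with fields closed by "\t|".

.splitDmp <- function(lines) {
    lines <- sub("\t\\|$", "", lines)
    strsplit(lines, "\t\\|\t", fixed = FALSE)
}

#' Load an NCBI-taxdump-dialect taxonomy
#'
#' Parses `nodes.dmp` (taxid | parent taxid | rank | ...) and `names.dmp`
#' (taxid | name | unique name | name class); only `scientific name`
#' entries populate node names, other name classes are ignored.  The
#' result is validated structurally: exactly one self-parented root, every
#' parent present, no cycles.
#'
#' Optionally `merged.dmp` (old taxid | new taxid) and `delnodes.dmp`
#' (taxid) are loaded so that identifiers from a drifted protein-library
#' release can be remapped or dropped via [resolveTaxids()].
#'
#' @param nodesPath,namesPath Paths to the nodes and names files.
#' @param mergedPath,delnodesPath Optional paths to merged/deleted dumps.
#' @return A [TaxonomyTree-class] object.
#' @examples
#' td <- makeTaxdump(tempfile("tax"), depth = 3, branching = 2, seed = 1)
#' tree <- loadTaxdump(td$nodesPath, td$namesPath)
#' tree
#' @export
loadTaxdump <- function(nodesPath, namesPath,
                        mergedPath = NULL, delnodesPath = NULL) {
    for (p in c(nodesPath, namesPath))
        if (!file.exists(p)) stop("taxdump file not found: ", p)
    nf <- .splitDmp(readLines(nodesPath))
    nf <- nf[lengths(nf) >= 3L]
    if (!length(nf)) stop("no parseable node records in ", nodesPath)
    taxid <- as.integer(vapply(nf, `[[`, "", 1L))
    parent <- as.integer(vapply(nf, `[[`, "", 2L))
    rank <- vapply(nf, `[[`, "", 3L)

    sciName <- rep("", length(taxid))
    names(sciName) <- taxid
    mf <- .splitDmp(readLines(namesPath))
    mf <- mf[lengths(mf) >= 4L]
    if (length(mf)) {
        cls <- vapply(mf, `[[`, "", 4L)
        sci <- mf[cls == "scientific name"]
        if (length(sci)) {
            id <- vapply(sci, `[[`, "", 1L)
            keep <- id %in% names(sciName)
            sciName[id[keep]] <- vapply(sci, `[[`, "", 2L)[keep]
        }
    }

    merged <- integer(0)
    if (!is.null(mergedPath) && file.exists(mergedPath)) {
        gf <- .splitDmp(readLines(mergedPath))
        gf <- gf[lengths(gf) >= 2L]
        if (length(gf)) {
            merged <- as.integer(vapply(gf, `[[`, "", 2L))
            names(merged) <- vapply(gf, `[[`, "", 1L)
        }
    }
    deleted <- integer(0)
    if (!is.null(delnodesPath) && file.exists(delnodesPath)) {
        df <- .splitDmp(readLines(delnodesPath))
        df <- df[lengths(df) >= 1L]
        deleted <- as.integer(vapply(df, `[[`, "", 1L))
    }

    roots <- taxid[taxid == parent]
    if (length(roots) == 0L)
        stop("taxonomy has no root (no self-parented node)")
    new("TaxonomyTree", taxid = taxid, parentTaxid = parent, rank = rank,
        sciName = unname(sciName), rootTaxid = roots[1L],
        merged = merged, deleted = deleted)
}

.taxIdx <- function(tree, taxids) {
    idx <- match(taxids, tree@taxid)
    if (anyNA(idx))
        stop("unknown taxid: ", taxids[which(is.na(idx))[1L]])
    idx
}

#' @rdname TaxonomyTree-class
#' @param object,tree A `TaxonomyTree`.
#' @export
setGeneric("nTaxa", function(tree) standardGeneric("nTaxa"))
#' @rdname TaxonomyTree-class
#' @export
setMethod("nTaxa", "TaxonomyTree", function(tree) length(tree@taxid))

#' @rdname TaxonomyTree-class
#' @export
setGeneric("taxIds", function(tree) standardGeneric("taxIds"))
#' @rdname TaxonomyTree-class
#' @export
setMethod("taxIds", "TaxonomyTree", function(tree) tree@taxid)

#' @rdname TaxonomyTree-class
#' @param taxids Integer vector of node identifiers.
#' @export
setGeneric("taxRank", function(tree, taxids) standardGeneric("taxRank"))
#' @rdname TaxonomyTree-class
#' @export
setMethod("taxRank", "TaxonomyTree", function(tree, taxids)
    tree@rank[.taxIdx(tree, taxids)])

#' @rdname TaxonomyTree-class
#' @export
setGeneric("taxName", function(tree, taxids) standardGeneric("taxName"))
#' @rdname TaxonomyTree-class
#' @export
setMethod("taxName", "TaxonomyTree", function(tree, taxids)
    tree@sciName[.taxIdx(tree, taxids)])

setMethod("show", "TaxonomyTree", function(object) {
    cat("TaxonomyTree with", length(object@taxid), "nodes\n")
    cat("  root:", object@rootTaxid,
        sprintf("(%s)\n", object@sciName[match(object@rootTaxid,
                                               object@taxid)]))
    cat("  ranks:", paste(utils::head(sort(unique(object@rank)), 8L),
                          collapse = ", "), "\n")
    if (length(object@merged))
        cat("  merged remappings:", length(object@merged), "\n")
    if (length(object@deleted))
        cat("  deleted taxids:", length(object@deleted), "\n")
})

#' Root-to-node lineage
#'
#' Walks parent links from `taxid` to the root and returns the path
#' root-first, ending at `taxid` itself.
#'
#' @param tree A [TaxonomyTree-class].
#' @param taxid A single taxid present in the tree.
#' @return Integer vector of taxids, root first.
#' @export
lineage <- function(tree, taxid) {
    i <- .taxIdx(tree, taxid)
    pidx <- match(tree@parentTaxid, tree@taxid)
    path <- integer(0)
    repeat {
        path <- c(tree@taxid[i], path)
        if (tree@taxid[i] == tree@rootTaxid) break
        i <- pidx[i]
    }
    path
}

#' Last common ancestor of a taxid set
#'
#' The deepest node present in the lineage of every member; singletons are
#' their own LCA and the result is independent of input order.
#'
#' @param tree A [TaxonomyTree-class].
#' @param taxids Non-empty integer vector, all present in the tree.
#' @return A single taxid.
#' @export
lca <- function(tree, taxids) {
    taxids <- unique(as.integer(taxids))
    if (length(taxids) == 0L || anyNA(taxids))
        stop("lca() needs a non-empty set of taxids")
    Reduce(function(a, b) {
        la <- lineage(tree, a)
        lb <- lineage(tree, b)
        k <- min(length(la), length(lb))
        common <- which(la[seq_len(k)] == lb[seq_len(k)])
        la[max(common)]
    }, taxids)
}

#' Superkingdom bin of taxonomy nodes
#'
#' Bins each taxid by which anchor its lineage passes through: Eukaryota
#' descendants (or the anchor itself) are "Eukaryote"; Bacteria and
#' Archaea descendants are pooled as "Prokaryote"; Viruses descendants are
#' "Viruses"; anything above the anchors (the root, a cellular-organisms
#' level, or an untraceable branch) is "Undetermined".
#'
#' @param tree A [TaxonomyTree-class].
#' @param taxids Integer vector of taxids present in the tree.
#' @param config A [PipelineConfig-class] providing the anchor taxids.
#' @return Character vector of bins, one per input taxid.
#' @export
superkingdomOf <- function(tree, taxids, config = pipelineConfig()) {
    anchors <- config@superkingdomAnchors
    vapply(as.integer(taxids), function(tx) {
        lin <- lineage(tree, tx)
        if (anchors[["Eukaryota"]] %in% lin) "Eukaryote"
        else if (anchors[["Bacteria"]] %in% lin ||
                 anchors[["Archaea"]] %in% lin) "Prokaryote"
        else if (anchors[["Viruses"]] %in% lin) "Viruses"
        else "Undetermined"
    }, character(1))
}

#' Test descent from an anchor node
#'
#' @param tree A [TaxonomyTree-class].
#' @param taxids Integer vector of taxids present in the tree.
#' @param ancestor A single taxid; each input is tested for having
#'   `ancestor` on its lineage (self included).
#' @return Logical vector.
#' @export
isDescendant <- function(tree, taxids, ancestor) {
    ancestor <- as.integer(ancestor)
    vapply(as.integer(taxids), function(tx) ancestor %in% lineage(tree, tx),
           logical(1))
}

#' Reconcile external taxids with the loaded taxonomy
#'
#' Remaps merged identifiers, drops deleted identifiers and (with a
#' warning) identifiers absent from the tree altogether.  Used before LCA
#' computation so hit tables built against a different taxonomy release
#' never abort the annotation.
#'
#' @param tree A [TaxonomyTree-class].
#' @param taxids Integer vector.
#' @return Integer vector of taxids guaranteed present in the tree
#'   (possibly shorter than the input).
#' @export
resolveTaxids <- function(tree, taxids) {
    taxids <- as.integer(taxids)
    hit <- match(as.character(taxids), names(tree@merged))
    remapped <- !is.na(hit)
    taxids[remapped] <- tree@merged[hit[remapped]]
    del <- taxids %in% tree@deleted
    if (any(del)) {
        warning("dropping ", sum(del), " deleted taxid(s): ",
                paste(utils::head(unique(taxids[del]), 5L), collapse = ", "))
        taxids <- taxids[!del]
    }
    known <- taxids %in% tree@taxid
    if (any(!known)) {
        warning("dropping ", sum(!known), " taxid(s) absent from taxonomy: ",
                paste(utils::head(unique(taxids[!known]), 5L),
                      collapse = ", "))
        taxids <- taxids[known]
    }
    taxids
}
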