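#' @import methods
NULL

#' Rooted NCBI-style taxonomy
#'
#' Parallel-vector representation of a rooted taxonomy in the NCBI taxdump
#' dialect.  Node `i` has identifier `taxid[i]`, parent `parentTaxid[i]`
#' (the root is its own parent), a controlled-vocabulary `rank[i]` and a
#' scientific name `sciName[i]`.  Optional remappings of merged identifiers
#' and the set of deleted identifiers are carried along so homology hits
#' against a drifted protein library can be reconciled with the loaded dump.
#'
#' @slot taxid Integer vector of node identifiers (all >= 1, unique).
#' @slot parentTaxid Integer vector, parallel to `taxid`.
#' @slot rank Character vector of ranks (e.g. "species", "no rank").
#' @slot sciName Character vector of scientific names.
#' @slot rootTaxid The single root identifier (canonically 1).
#' @slot merged Named integer vector mapping old taxid (name) to new taxid.
#' @slot deleted Integer vector of withdrawn taxids.
#'
#' @seealso [loadTaxdump()], [lineage()], [lca()], [superkingdomOf()]
#' @exportClass TaxonomyTree
setClass("TaxonomyTree",
    representation(
        taxid = "integer",
        parentTaxid = "integer",
        rank = "character",
        sciName = "character",
        rootTaxid = "integer",
        merged = "integer",
        deleted = "integer"
    ),
    prototype(merged = integer(0), deleted = integer(0))
)

.validTaxonomyTree <- function(object) {
    n <- length(object@taxid)
    if (length(object@parentTaxid) != n || length(object@rank) != n ||
        length(object@sciName) != n)
        return("taxid, parentTaxid, rank and sciName must have equal length")
    if (n == 0L)
        return("taxonomy must contain at least one node")
    if (anyDuplicated(object@taxid))
        return(sprintf("duplicated taxid: %d",
                       object@taxid[duplicated(object@taxid)][1L]))
    if (any(object@taxid < 1L))
        return("all taxids must be >= 1")
    if (any(!nzchar(object@rank)))
        return("ranks must be non-empty strings")
    roots <- object@taxid[object@taxid == object@parentTaxid]
    if (length(roots) != 1L)
        return(sprintf("expected exactly one root (parent == self), found %d",
                       length(roots)))
    if (length(object@rootTaxid) != 1L || roots != object@rootTaxid)
        return("rootTaxid does not match the unique self-parented node")
    pidx <- match(object@parentTaxid, object@taxid)
    if (anyNA(pidx)) {
        bad <- object@taxid[which(is.na(pidx))[1L]]
        return(sprintf("parent of taxid %d is absent from the taxonomy", bad))
    }
    ## cycle check by pointer doubling: after ceil(log2 n) + 1 doublings the
    ## jump table is parent^(2^k) with 2^k >= n, so every acyclic walk has
    ## been absorbed by the (self-parented) root
    jump <- pidx
    rootIdx <- match(object@rootTaxid, object@taxid)
    for (i in seq_len(ceiling(log2(max(n, 2L))) + 1L)) jump <- jump[jump]
    if (any(jump != rootIdx)) {
        bad <- object@taxid[which(jump != rootIdx)[1L]]
        return(sprintf("cyclic parent links involving taxid %d", bad))
    }
    TRUE
}
setValidity("TaxonomyTree", .validTaxonomyTree)

#' Pipeline thresholds in one place
#'
#' Every numeric decision threshold used along the pipeline, with the
#' published defaults: contigs are retained when at least 1 kb long *or*
#' carrying at least three initial gene calls; homology hits are kept under
#' E <= 1e-6 and within 10% of the best bitscore; a contig is confirmed
#' eukaryotic when at least 50% of its predicted proteins receive a
#' eukaryotic LCA; taxids 12908 ("unclassified sequences") and 32644
#' ("other sequences") convey no usable lineage; protein clustering
#' bookkeeping assumes 99% identity / 90% target coverage input.
#'
#' @slot minContigLen Minimum contig length in bp (default 1000).
#' @slot minGeneCount Minimum initial gene-call count (default 3).
#' @slot evalueMax E-value cutoff for homology hits (default 1e-6).
#' @slot scoreMargin Fractional bitscore margin from the best hit
#'   (default 0.10; hits with bitscore >= (1 - margin) * best are kept).
#' @slot eukFractionMin Minimum eukaryotic protein fraction confirming a
#'   contig (default 0.5, inclusive).
#' @slot untraceableTaxids Taxids treated as untraceable, together with
#'   their descendants (default 12908, 32644).
#' @slot orphanSubtypes Which Undetermined subtypes count as orphans
#'   (subset of "no_hit", "untraceable"; default both).
#' @slot superkingdomAnchors Named integer vector of anchor taxids for
#'   Bacteria, Archaea, Eukaryota and Viruses.
#' @slot clusterMinIdentity Clustering identity threshold (default 0.99).
#' @slot clusterMinTargetCov Clustering target coverage (default 0.90).
#'
#' @seealso [pipelineConfig()], [loadConfig()]
#' @exportClass PipelineConfig
setClass("PipelineConfig",
    representation(
        minContigLen = "integer",
        minGeneCount = "integer",
        evalueMax = "numeric",
        scoreMargin = "numeric",
        eukFractionMin = "numeric",
        untraceableTaxids = "integer",
        orphanSubtypes = "character",
        superkingdomAnchors = "integer",
        clusterMinIdentity = "numeric",
        clusterMinTargetCov = "numeric"
    )
)

.validPipelineConfig <- function(object) {
    chkFrac <- function(x, key) {
        if (length(x) != 1L || is.na(x) || x < 0 || x > 1)
            sprintf("%s must be a single value in [0, 1]", key)
        else NULL
    }
    msgs <- c(
        if (length(object@minContigLen) != 1L || object@minContigLen < 1L)
            "minContigLen must be a positive integer",
        if (length(object@minGeneCount) != 1L || object@minGeneCount < 1L)
            "minGeneCount must be a positive integer",
        if (length(object@evalueMax) != 1L || object@evalueMax <= 0)
            "evalueMax must be positive",
        chkFrac(object@scoreMargin, "scoreMargin"),
        chkFrac(object@eukFractionMin, "eukFractionMin"),
        chkFrac(object@clusterMinIdentity, "clusterMinIdentity"),
        chkFrac(object@clusterMinTargetCov, "clusterMinTargetCov"),
        if (!all(object@orphanSubtypes %in% c("no_hit", "untraceable")))
            "orphanSubtypes must be a subset of {no_hit, untraceable}",
        if (!all(c("Bacteria", "Archaea", "Eukaryota", "Viruses") %in%
                 names(object@superkingdomAnchors)))
            "superkingdomAnchors needs Bacteria, Archaea, Eukaryota, Viruses"
    )
    if (length(msgs)) msgs else TRUE
}
setValidity("PipelineConfig", .validPipelineConfig)

#' Catalog of ab initio gene-model species
#'
#' The species for which the eukaryotic gene predictor ships trained
#' ab initio parameter sets, each anchored to a taxonomy node.  The
#' published catalog has 73 species; any non-empty catalog is accepted.
#'
#' @slot modelName Character vector of model species names (unique).
#' @slot modelTaxid Integer vector of their taxids (unique).
#' @slot kingdom Optional character vector of coarse kingdom labels used
#'   for distribution reports ("" when unknown).
#'
#' @seealso [modelCatalog()], [assignModels()]
#' @exportClass ModelCatalog
setClass("ModelCatalog",
    representation(
        modelName = "character",
        modelTaxid = "integer",
        kingdom = "character"
    )
)

.validModelCatalog <- function(object) {
    n <- length(object@modelName)
    if (n < 1L)
        return("catalog must contain at least one model")
    if (length(object@modelTaxid) != n || length(object@kingdom) != n)
        return("modelName, modelTaxid and kingdom must have equal length")
    if (anyDuplicated(object@modelName))
        return("model names must be unique")
    if (anyDuplicated(object@modelTaxid))
        return("model taxids must be unique")
    TRUE
}
setValidity("ModelCatalog", .validModelCatalog)
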