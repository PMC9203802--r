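## Two-pass assignment of ab initio gene-model species to eukaryotic
## contigs.  Pass 1 resolves a contig wherever its lowest model-bearing
## ancestor carries exactly one catalog model (equivalent to labelling the
## unambiguous region above each model leaf-to-root until a bifurcation
## towards another model).  Pass 2 resolves the remaining contigs to the
## candidate most frequently assigned in pass 1 within the contig's own
## dataset batch.

#' Construct a gene-model catalog
#'
#' @param modelName Character vector of model species names.
#' @param modelTaxid Integer vector of their taxids.
#' @param kingdom Optional coarse kingdom labels for reporting.
#' @return A [ModelCatalog-class].
#' @export
modelCatalog <- function(modelName, modelTaxid,
                         kingdom = rep("", length(modelName))) {
    new("ModelCatalog", modelName = as.character(modelName),
        modelTaxid = as.integer(modelTaxid),
        kingdom = as.character(kingdom))
}

#' Read a model catalog from TSV
#'
#' Columns: model_name, taxid, and optionally kingdom; with header.
#'
#' @param path TSV path.
#' @return A [ModelCatalog-class].
#' @export
readModelCatalog <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("model_name", "taxid") %in% names(df)))
        stop("model catalog needs columns model_name and taxid")
    modelCatalog(df$model_name, df$taxid,
                 if (!is.null(df$kingdom)) df$kingdom
                 else rep("", nrow(df)))
}

setMethod("show", "ModelCatalog", function(object) {
    cat("ModelCatalog with", length(object@modelName), "model species\n")
    k <- length(object@modelName)
    shown <- utils::head(paste0(object@modelName, " (", object@modelTaxid,
                                ")"), 5L)
    cat(" ", paste(shown, collapse = ", "),
        if (k > 5L) sprintf("... and %d more", k - 5L) else "", "\n")
})

#' Models present in each node's subtree
#'
#' Computed bottom-up in a single pass over nodes ordered by decreasing
#' depth: each node's set is its own planted models plus the union of its
#' children's sets.
#'
#' @param tree A [TaxonomyTree-class].
#' @param catalog A [ModelCatalog-class]; every model taxid must be in the
#'   tree.
#' @return Named list (taxid as name) of sorted character vectors of
#'   model names; nodes with no model below them map to `character(0)`.
#' @export
modelsInSubtree <- function(tree, catalog) {
    mi <- match(catalog@modelTaxid, taxIds(tree))
    if (anyNA(mi))
        stop("model taxid absent from taxonomy: ",
             catalog@modelName[which(is.na(mi))[1L]],
             " (", catalog@modelTaxid[which(is.na(mi))[1L]], ")")
    n <- nTaxa(tree)
    pidx <- match(tree@parentTaxid, tree@taxid)
    ## depth by pointer walk (root depth 0)
    depth <- integer(n)
    cur <- seq_len(n)
    repeat {
        atRoot <- cur == match(tree@rootTaxid, tree@taxid)
        if (all(atRoot)) break
        depth[!atRoot] <- depth[!atRoot] + 1L
        cur <- pidx[cur]
    }
    sets <- vector("list", n)
    for (i in seq_len(n)) sets[[i]] <- character(0)
    for (j in seq_along(mi)) sets[[mi[j]]] <- catalog@modelName[j]
    for (i in order(depth, decreasing = TRUE)) {
        p <- pidx[i]
        if (p != i)
            sets[[p]] <- union(sets[[p]], sets[[i]])
    }
    sets <- lapply(sets, sort)
    names(sets) <- as.character(taxIds(tree))
    sets
}

#' First-pass model assignment for one classifier taxid
#'
#' Finds the lowest ancestor-or-self of `contigTaxid` whose subtree
#' contains at least one catalog model.  If that set is a singleton the
#' contig is resolved at pass 1; otherwise it is `AMBIGUOUS` with the set
#' recorded as candidates for pass 2.
#'
#' @param contigTaxid A single taxid under the Eukaryota anchor.
#' @param tree A [TaxonomyTree-class].
#' @param subtreeModels Result of [modelsInSubtree()].
#' @param config A [PipelineConfig-class].
#' @return A list with `model` (model name or `"AMBIGUOUS"`), `candidates`
#'   (character vector; empty when resolved) and `pass` (1L or NA).
#' @export
assignPass1 <- function(contigTaxid, tree, subtreeModels,
                        config = pipelineConfig()) {
    anchor <- config@superkingdomAnchors[["Eukaryota"]]
    lin <- lineage(tree, contigTaxid)
    if (!(anchor %in% lin))
        stop("no model reachable: taxid ", contigTaxid,
             " is not under the Eukaryota anchor")
    for (tx in rev(lin)) {
        ms <- subtreeModels[[as.character(tx)]]
        if (length(ms) == 1L)
            return(list(model = ms, candidates = character(0), pass = 1L))
        if (length(ms) > 1L)
            return(list(model = "AMBIGUOUS", candidates = ms,
                        pass = NA_integer_))
    }
    stop("no model reachable above taxid ", contigTaxid,
         ": catalog and taxonomy are inconsistent")
}

#' Second-pass resolution of ambiguous assignments
#'
#' Each ambiguous contig takes the candidate with the highest pass-1
#' count in its own batch; ties break lexicographically on the model
#' name; when every candidate has zero pass-1 assignments in the batch,
#' global (all-batch) pass-1 counts are used, then the lexicographic rule.
#'
#' @param ambiguous Data.frame with columns `contig_id`, `batch` and
#'   `candidates` (list column or ";"-separated string).
#' @param pass1Freq Data.frame with columns `batch`, `model_name`, `n`
#'   (pass-1 assignment counts).
#' @return Character vector of chosen model names, parallel to
#'   `ambiguous` rows.
#' @export
assignPass2 <- function(ambiguous, pass1Freq) {
    getCand <- function(x)
        if (is.character(x) && length(x) == 1L)
            strsplit(x, ";", fixed = TRUE)[[1L]] else as.character(x)
    vapply(seq_len(nrow(ambiguous)), function(i) {
        cand <- sort(getCand(ambiguous$candidates[[i]]))
        if (!length(cand)) stop("internal error: empty candidate set for ",
                                ambiguous$contig_id[i])
        b <- ambiguous$batch[i]
        inBatch <- pass1Freq[pass1Freq$batch == b, , drop = FALSE]
        counts <- inBatch$n[match(cand, inBatch$model_name)]
        counts[is.na(counts)] <- 0L
        if (all(counts == 0L)) {
            glob <- tapply(pass1Freq$n, pass1Freq$model_name, sum)
            counts <- as.integer(glob[cand])
            counts[is.na(counts)] <- 0L
        }
        cand[which.max(counts)]  # which.max takes the first = lexicographic
    }, character(1))
}

#' Assign a gene model to every eukaryotic contig
#'
#' Runs pass 1 over all contigs, tallies per-batch pass-1 frequencies,
#' then resolves the ambiguous remainder in a single second pass.  The
#' result is deterministic and independent of contig order.
#'
#' @param contigs Data.frame with columns `contig_id`, `taxid`, and
#'   optionally `metagenome_id` and `batch`.
#' @param tree A [TaxonomyTree-class].
#' @param catalog A [ModelCatalog-class].
#' @param config A [PipelineConfig-class].
#' @return A list with `assignments` (data.frame: contig_id,
#'   metagenome_id, batch, model_name, pass, candidates ";"-joined) and
#'   `report` (counts per batch x model, with kingdom when the catalog
#'   carries one).
#' @export
assignModels <- function(contigs, tree, catalog, config = pipelineConfig()) {
    if (!all(c("contig_id", "taxid") %in% names(contigs)))
        stop("contig table needs columns contig_id and taxid")
    if (is.null(contigs$batch)) contigs$batch <- "all"
    if (is.null(contigs$metagenome_id)) contigs$metagenome_id <- ""
    subtreeModels <- modelsInSubtree(tree, catalog)

    uniqTax <- unique(contigs$taxid)
    p1 <- lapply(uniqTax, assignPass1, tree = tree,
                 subtreeModels = subtreeModels, config = config)
    names(p1) <- as.character(uniqTax)
    byTax <- p1[as.character(contigs$taxid)]

    model <- vapply(byTax, `[[`, "", "model")
    pass <- vapply(byTax, function(x) x$pass, integer(1))
    candStr <- vapply(byTax, function(x)
        paste(x$candidates, collapse = ";"), "")
    out <- data.frame(contig_id = contigs$contig_id,
                      metagenome_id = contigs$metagenome_id,
                      batch = contigs$batch,
                      model_name = model, pass = pass,
                      candidates = candStr, stringsAsFactors = FALSE)

    amb <- out$model_name == "AMBIGUOUS"
    if (any(amb)) {
        resolved <- out[!amb, , drop = FALSE]
        freq <- as.data.frame(table(batch = resolved$batch,
                                    model_name = resolved$model_name),
                              stringsAsFactors = FALSE)
        names(freq)[3L] <- "n"
        out$model_name[amb] <- assignPass2(out[amb, , drop = FALSE], freq)
        out$pass[amb] <- 2L
    }

    rep <- as.data.frame(table(batch = out$batch,
                               model_name = out$model_name),
                         stringsAsFactors = FALSE)
    names(rep)[3L] <- "n"
    rep <- rep[rep$n > 0L, , drop = FALSE]
    if (any(nzchar(catalog@kingdom)))
        rep$kingdom <- catalog@kingdom[match(rep$model_name,
                                             catalog@modelName)]
    rownames(rep) <- NULL
    list(assignments = out, report = rep)
}
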