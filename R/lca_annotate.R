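## Score-margin LCA annotation of predicted proteins from tabular homology
## hits: E-value gate, 10%-of-best-bitscore margin, LCA over pooled subject
## taxids, and superkingdom binning with Undetermined subtypes.

.BINS <- c("Eukaryote", "Prokaryote", "Viruses", "Undetermined")

#' Read a tabular homology-hit file
#'
#' Tab-separated hits in the aligner's outfmt-6-like layout.  The column
#' order is configurable; `staxids` may hold several semicolon-separated
#' subject taxids.
#'
#' @param path Path to the hit table (no header).
#' @param columns Character vector naming the columns in file order;
#'   must include `qseqid`, `evalue`, `bitscore` and `staxids`.
#' @return A data.frame with one row per hit; `staxids` is a list column
#'   of integer vectors.
#' @export
readHitTable <- function(path,
                         columns = c("qseqid", "sseqid", "pident", "length",
                                     "evalue", "bitscore", "staxids")) {
    need <- c("qseqid", "evalue", "bitscore", "staxids")
    if (!all(need %in% columns))
        stop("columns must include ", paste(need, collapse = ", "))
    df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < length(columns))
        stop("hit table has ", ncol(df), " columns, expected >= ",
             length(columns))
    df <- df[, seq_along(columns)]
    names(df) <- columns
    df$staxids <- lapply(strsplit(as.character(df$staxids), ";",
                                  fixed = TRUE), as.integer)
    df
}

#' Filter the hits of one query
#'
#' Drops hits with `evalue > evalueMax`; among the survivors, keeps those
#' whose bitscore is within the configured margin of the best, i.e.
#' `bitscore >= (1 - scoreMargin) * max(bitscore)`, boundary inclusive.
#' The E-value gate is applied first, so a high-scoring hit with a bad
#' E-value can never set the margin baseline; the best surviving hit is
#' always retained.
#'
#' @param hits Data.frame of hits sharing one `qseqid`, with `evalue` and
#'   `bitscore` columns.
#' @param config A [PipelineConfig-class].
#' @return The retained subset of `hits` (possibly empty).
#' @export
filterHits <- function(hits, config = pipelineConfig()) {
    keep <- hits$evalue <= config@evalueMax
    hits <- hits[keep, , drop = FALSE]
    if (!nrow(hits)) return(hits)
    best <- max(hits$bitscore)
    hits[hits$bitscore >= (1 - config@scoreMargin) * best, , drop = FALSE]
}

.annotateOne <- function(proteinId, hits, tree, config) {
    und <- function(subtype)
        list(lca_taxid = NA_integer_, bin = "Undetermined",
             subtype = subtype)
    if (is.null(hits) || !nrow(hits)) return(und("no_hit"))
    kept <- filterHits(hits, config)
    if (!nrow(kept)) return(und("no_hit"))
    pooled <- unique(unlist(kept$staxids))
    pooled <- suppressWarnings(resolveTaxids(tree, pooled))
    if (!length(pooled)) {
        warning("protein ", proteinId,
                ": no subject taxid resolvable, marked untraceable")
        return(und("untraceable"))
    }
    anc <- lca(tree, pooled)
    lin <- lineage(tree, anc)
    if (any(config@untraceableTaxids %in% lin))
        return(list(lca_taxid = anc, bin = "Undetermined",
                    subtype = "untraceable"))
    bin <- superkingdomOf(tree, anc, config)
    if (bin == "Undetermined")
        return(list(lca_taxid = anc, bin = "Undetermined",
                    subtype = "above_superkingdom"))
    list(lca_taxid = anc, bin = bin, subtype = "none")
}

#' Annotate predicted proteins by score-margin LCA
#'
#' For every protein: hits are filtered by [filterHits()]; the subject
#' taxids of the retained hits are pooled (multi-taxid subjects
#' flattened) and reduced to their last common ancestor; the LCA is
#' binned into a superkingdom.  Proteins with no retained hits are
#' `Undetermined/no_hit`; LCAs on an untraceable branch (e.g.
#' "unclassified sequences") are `Undetermined/untraceable`; LCAs above
#' every superkingdom anchor are `Undetermined/above_superkingdom`.
#'
#' @param proteinIds Character vector of all predicted protein ids;
#'   proteins absent from the hit table become `no_hit`.
#' @param hits Data.frame from [readHitTable()] (rows for any query not
#'   listed in `proteinIds` are ignored).
#' @param tree A [TaxonomyTree-class].
#' @param config A [PipelineConfig-class].
#' @param proteinMeta Optional data.frame (`protein_id`, `contig_id`,
#'   `metagenome_id`, `batch`); when absent, contig and metagenome are
#'   recovered from the `contigName_metagenomeID.geneID` id pattern where
#'   possible.
#' @return A data.frame: `protein_id`, `contig_id`, `metagenome_id`,
#'   `batch`, `lca_taxid` (NA for no-hit), `lca_rank`, `bin`, `subtype`.
#' @export
annotateProteins <- function(proteinIds, hits, tree,
                             config = pipelineConfig(),
                             proteinMeta = NULL) {
    proteinIds <- unique(as.character(proteinIds))
    byQuery <- if (!is.null(hits) && nrow(hits))
        split(hits, hits$qseqid) else list()
    ann <- lapply(proteinIds, function(p)
        .annotateOne(p, byQuery[[p]], tree, config))
    lcaTax <- vapply(ann, `[[`, integer(1), "lca_taxid")
    out <- data.frame(
        protein_id = proteinIds,
        lca_taxid = lcaTax,
        lca_rank = ifelse(is.na(lcaTax), NA_character_,
                          tree@rank[match(lcaTax, tree@taxid)]),
        bin = vapply(ann, `[[`, "", "bin"),
        subtype = vapply(ann, `[[`, "", "subtype"),
        stringsAsFactors = FALSE)
    if (!is.null(proteinMeta)) {
        m <- match(out$protein_id, proteinMeta$protein_id)
        out$contig_id <- proteinMeta$contig_id[m]
        out$metagenome_id <- proteinMeta$metagenome_id[m]
        out$batch <- if (!is.null(proteinMeta$batch))
            proteinMeta$batch[m] else "all"
    } else {
        parsed <- lapply(out$protein_id, function(p)
            tryCatch(parseProteinId(p), error = function(e)
                list(contig = NA_character_, metagenome = NA_character_,
                     gene = NA_character_)))
        out$contig_id <- vapply(parsed, `[[`, "", "contig")
        out$metagenome_id <- vapply(parsed, `[[`, "", "metagenome")
        out$batch <- "all"
    }
    out[, c("protein_id", "contig_id", "metagenome_id", "batch",
            "lca_taxid", "lca_rank", "bin", "subtype")]
}

#' Superkingdom summary table
#'
#' Counts annotated proteins per superkingdom bin and batch, with row
#' totals and the percentage of the grand total (one decimal), in the
#' shape of a published superkingdom classification table.
#'
#' @param annotations Data.frame from [annotateProteins()] (needs `bin`
#'   and `batch`), or any data.frame with those columns.  When an `n`
#'   column is present each row is taken as a pre-aggregated count
#'   instead of a single protein, so published corpus-scale tables can
#'   be recomputed from their printed per-batch counts.
#' @return Data.frame with one row per bin plus a `Total` row; columns
#'   per batch, `Total` and `pct`.
#' @export
summarizeSuperkingdoms <- function(annotations) {
    w <- if (is.null(annotations$n)) rep(1, nrow(annotations)) else
        as.numeric(annotations$n)
    batches <- unique(annotations$batch)
    rows <- lapply(c(.BINS, "Total"), function(b) {
        sel <- if (b == "Total") rep(TRUE, nrow(annotations)) else
            annotations$bin == b
        cnt <- vapply(batches, function(bt)
            sum(w[sel & annotations$batch == bt]), numeric(1))
        df <- as.data.frame(as.list(cnt))
        names(df) <- batches
        df$Total <- sum(cnt)
        cbind(data.frame(bin = b, stringsAsFactors = FALSE), df)
    })
    out <- do.call(rbind, rows)
    grand <- out$Total[out$bin == "Total"]
    out$pct <- if (grand > 0) round(100 * out$Total / grand, 1) else 0
    out
}

#' Distribution of LCA taxonomic ranks
#'
#' Tallies the rank of each protein's LCA node: the fraction still
#' annotated at species level (versus deeper, more ancestral ranks)
#' measures how often multiple equally-good hits pushed the annotation
#' up the taxonomy.
#'
#' @param annotations Data.frame with an `lca_taxid` column (NAs, i.e.
#'   no-hit proteins, are excluded).
#' @param tree A [TaxonomyTree-class].
#' @return Data.frame `rank`, `n`, `fraction`, sorted by decreasing `n`.
#' @export
rankDistribution <- function(annotations, tree) {
    tx <- annotations$lca_taxid[!is.na(annotations$lca_taxid)]
    if (!length(tx))
        return(data.frame(rank = character(0), n = integer(0),
                          fraction = numeric(0)))
    rk <- taxRank(tree, tx)
    tab <- sort(table(rk), decreasing = TRUE)
    data.frame(rank = names(tab), n = as.integer(tab),
               fraction = as.numeric(tab) / length(tx),
               stringsAsFactors = FALSE)
}

#' Write the protein taxonomy table
#'
#' TSV with one row per protein: id, LCA taxid, lineage string (root
#' excluded, ";"-joined scientific names), bin and subtype — the shape of
#' a published per-protein taxonomy table.
#'
#' @param annotations Data.frame from [annotateProteins()].
#' @param tree A [TaxonomyTree-class].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writeProteinTaxonomy <- function(annotations, tree, path) {
    lin <- vapply(annotations$lca_taxid, function(tx) {
        if (is.na(tx)) return("")
        l <- lineage(tree, tx)
        paste(taxName(tree, l[-1L]), collapse = ";")
    }, character(1))
    out <- data.frame(protein_id = annotations$protein_id,
                      lca_taxid = annotations$lca_taxid,
                      lineage = lin,
                      bin = annotations$bin,
                      subtype = annotations$subtype,
                      stringsAsFactors = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
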