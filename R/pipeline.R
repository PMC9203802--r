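## Stage orchestration over a working directory.  Each stage reads the
## standard files its external producers would leave there, writes its
## outputs atomically, and appends one row to a funnel report mirroring
## the pipeline's contig/protein/metagenome counts at each step.

.STAGES <- c("simulate", "qc", "select", "models", "annotate", "confirm",
             "orphans", "compare")

.STAGE_DEPS <- list(
    simulate = character(0),
    qc = c("contig_lengths.tsv", "jgi_genes.gff"),
    select = c("out/kept_contigs.txt", "kraken.out", "taxdump/nodes.dmp",
               "taxdump/names.dmp"),
    models = c("out/euk_contigs.tsv", "model_catalog.tsv",
               "taxdump/nodes.dmp"),
    annotate = c("proteins.faa", "hits.tsv", "taxdump/nodes.dmp"),
    confirm = c("out/annotations.tsv"),
    orphans = c("out/annotations.tsv", "out/confirmed_contigs.txt",
                "proteins.faa"),
    compare = c("prediction.gff", "proteins.faa"))

.writeAtomic <- function(lines, path) {
    tmp <- paste0(path, ".tmp")
    writeLines(lines, tmp)
    file.rename(tmp, path)
    invisible(path)
}

.writeTableAtomic <- function(df, path, col.names = TRUE) {
    tmp <- paste0(path, ".tmp")
    utils::write.table(df, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = col.names)
    file.rename(tmp, path)
    invisible(path)
}

.funnelAppend <- function(dir, stage, contigsIn, contigsOut,
                          proteinsIn, proteinsOut, mgIn, mgOut) {
    path <- file.path(dir, "out", "funnel.tsv")
    row <- data.frame(stage = stage, contigs_in = contigsIn,
                      contigs_out = contigsOut, proteins_in = proteinsIn,
                      proteins_out = proteinsOut, metagenomes_in = mgIn,
                      metagenomes_out = mgOut, stringsAsFactors = FALSE)
    old <- if (file.exists(path))
        utils::read.delim(path, stringsAsFactors = FALSE) else NULL
    if (!is.null(old)) old <- old[old$stage != stage, , drop = FALSE]
    out <- rbind(old, row)
    out <- out[order(match(out$stage, .STAGES)), , drop = FALSE]
    .writeTableAtomic(out, path)
}

.loadContigMeta <- function(dir) {
    metaPath <- file.path(dir, "contig_meta.tsv")
    if (file.exists(metaPath))
        utils::read.delim(metaPath, stringsAsFactors = FALSE,
                          colClasses = c(metagenome_id = "character"))
    else NULL
}

.loadTree <- function(dir) {
    loadTaxdump(file.path(dir, "taxdump", "nodes.dmp"),
                file.path(dir, "taxdump", "names.dmp"),
                file.path(dir, "taxdump", "merged.dmp"),
                file.path(dir, "taxdump", "delnodes.dmp"))
}

#' Run one pipeline stage
#'
#' Stages form the DAG `qc -> select -> models` and (after an external
#' gene-prediction run) `annotate -> confirm -> orphans`, with `compare`
#' consuming prediction and BUSCO outputs and `simulate` generating a
#' full synthetic working directory.  A stage whose inputs are missing
#' raises a dependency error naming the stage and the missing file.
#' Outputs are written atomically under `<dir>/out/` and rerunning a
#' stage on unchanged inputs reproduces byte-identical outputs.
#'
#' @param stage One of "simulate", "qc", "select", "models", "annotate",
#'   "confirm", "orphans", "compare".
#' @param dir Working directory holding the stage inputs.
#' @param config A [PipelineConfig-class].
#' @param spec A [communitySpec()] (simulate stage only).
#' @return Invisibly, a list of the stage's main outputs.
#' @export
runStage <- function(stage, dir, config = pipelineConfig(),
                     spec = communitySpec()) {
    stage <- match.arg(stage, .STAGES)
    need <- file.path(dir, .STAGE_DEPS[[stage]])
    missing <- need[!file.exists(need)]
    if (length(missing))
        stop("dependency error: stage '", stage, "' requires ",
             paste(basename(missing), collapse = ", "),
             " -- run the upstream stage first")
    dir.create(file.path(dir, "out"), showWarnings = FALSE,
               recursive = TRUE)
    switch(stage,
        simulate = .stageSimulate(dir, spec),
        qc = .stageQc(dir, config),
        select = .stageSelect(dir, config),
        models = .stageModels(dir, config),
        annotate = .stageAnnotate(dir, config),
        confirm = .stageConfirm(dir, config),
        orphans = .stageOrphans(dir, config),
        compare = .stageCompare(dir, config))
}

.stageSimulate <- function(dir, spec) {
    td <- makeTaxdump(file.path(dir, "taxdump"), seed = spec$seed)
    com <- makeCommunity(spec, td, dir)
    .writeTableAtomic(data.frame(model_name = names(td$modelTaxids),
                                 taxid = td$modelTaxids),
                      file.path(dir, "model_catalog.tsv"))
    .writeTableAtomic(com$contigs[, c("contig_id", "metagenome_id",
                                      "batch")],
                      file.path(dir, "contig_meta.tsv"))
    makeBuscoTables(file.path(dir, "busco"), nMetagenomes = 50L,
                    seed = spec$seed)
    invisible(list(taxdump = td, community = com))
}

.stageQc <- function(dir, config) {
    lens <- readContigLengths(file.path(dir, "contig_lengths.tsv"))
    counts <- readGeneCounts(file.path(dir, "jgi_genes.gff"))
    meta <- .loadContigMeta(dir)
    contigs <- data.frame(contig_id = names(lens),
                          length_bp = as.integer(lens),
                          stringsAsFactors = FALSE)
    contigs$gene_count <- ifelse(is.na(counts[contigs$contig_id]), 0L,
                                 counts[contigs$contig_id])
    if (!is.null(meta)) {
        m <- match(contigs$contig_id, meta$contig_id)
        contigs$metagenome_id <- meta$metagenome_id[m]
        contigs$batch <- meta$batch[m]
    } else {
        contigs$metagenome_id <- "unknown"
        contigs$batch <- "all"
    }
    res <- filterContigs(contigs, config)
    .writeAtomic(res$kept$contig_id,
                 file.path(dir, "out", "kept_contigs.txt"))
    .writeTableAtomic(res$funnel, file.path(dir, "out", "qc_funnel.tsv"))
    tot <- res$funnel[res$funnel$batch == "Total", ]
    .funnelAppend(dir, "qc", tot$contigs_in, tot$contigs_kept, NA, NA,
                  tot$metagenomes_in, tot$metagenomes_surviving)
    invisible(res)
}

.stageSelect <- function(dir, config) {
    kept <- readLines(file.path(dir, "out", "kept_contigs.txt"))
    rec <- parseKrakenOutput(file.path(dir, "kraken.out"))
    rec <- rec[rec$seq_id %in% kept, , drop = FALSE]
    tree <- .loadTree(dir)
    sel <- selectEukaryotic(rec, tree, config)
    eukTab <- rec[rec$seq_id %in% sel$seq_ids, c("seq_id", "taxid")]
    names(eukTab) <- c("contig_id", "taxid")
    .writeTableAtomic(eukTab, file.path(dir, "out", "euk_contigs.tsv"))
    meta <- .loadContigMeta(dir)
    mgOf <- function(ids) if (is.null(meta)) NA_integer_ else
        length(unique(meta$metagenome_id[meta$contig_id %in% ids]))
    .funnelAppend(dir, "select", length(kept), nrow(eukTab), NA, NA,
                  mgOf(kept), mgOf(eukTab$contig_id))
    invisible(sel)
}

.stageModels <- function(dir, config) {
    euk <- utils::read.delim(file.path(dir, "out", "euk_contigs.tsv"),
                             stringsAsFactors = FALSE)
    catalog <- readModelCatalog(file.path(dir, "model_catalog.tsv"))
    tree <- .loadTree(dir)
    meta <- .loadContigMeta(dir)
    if (!is.null(meta)) {
        m <- match(euk$contig_id, meta$contig_id)
        euk$metagenome_id <- meta$metagenome_id[m]
        euk$batch <- meta$batch[m]
    }
    res <- assignModels(euk, tree, catalog, config)
    .writeTableAtomic(res$assignments,
                      file.path(dir, "out", "model_assignments.tsv"))
    .writeTableAtomic(res$report,
                      file.path(dir, "out", "model_report.tsv"))
    .funnelAppend(dir, "models", nrow(euk), nrow(res$assignments), NA, NA,
                  NA, NA)
    invisible(res)
}

.stageAnnotate <- function(dir, config) {
    prot <- Biostrings::readAAStringSet(file.path(dir, "proteins.faa"))
    hits <- readHitTable(file.path(dir, "hits.tsv"))
    tree <- .loadTree(dir)
    ann <- annotateProteins(names(prot), hits, tree, config)
    meta <- .loadContigMeta(dir)
    if (!is.null(meta)) {
        m <- match(ann$contig_id, meta$contig_id)
        ann$batch <- ifelse(is.na(m), ann$batch, meta$batch[m])
    }
    .writeTableAtomic(ann, file.path(dir, "out", "annotations.tsv"))
    .writeTableAtomic(summarizeSuperkingdoms(ann),
                      file.path(dir, "out", "superkingdom_summary.tsv"))
    writeProteinTaxonomy(ann, tree,
                         file.path(dir, "out", "protein_taxonomy.tsv"))
    .funnelAppend(dir, "annotate", NA, NA, length(prot), nrow(ann),
                  length(unique(ann$metagenome_id)),
                  length(unique(ann$metagenome_id)))
    invisible(ann)
}

.readAnnotations <- function(dir) {
    utils::read.delim(file.path(dir, "out", "annotations.tsv"),
                      stringsAsFactors = FALSE,
                      colClasses = c(metagenome_id = "character"))
}

.stageConfirm <- function(dir, config) {
    ann <- .readAnnotations(dir)
    summ <- contigEukFraction(ann)
    conf <- confirmedContigs(summ, config)
    .writeTableAtomic(summ, file.path(dir, "out", "contig_summaries.tsv"))
    .writeAtomic(conf, file.path(dir, "out", "confirmed_contigs.txt"))
    .funnelAppend(dir, "confirm", nrow(summ), length(conf),
                  nrow(ann), sum(ann$contig_id %in% conf),
                  length(unique(summ$metagenome_id)),
                  length(unique(summ$metagenome_id[summ$contig_id %in%
                                                   conf])))
    invisible(list(summaries = summ, confirmed = conf))
}

.stageOrphans <- function(dir, config) {
    ann <- .readAnnotations(dir)
    conf <- readLines(file.path(dir, "out", "confirmed_contigs.txt"))
    res <- extractOrphans(ann, conf, config)
    .writeTableAtomic(res$orphans, file.path(dir, "out", "orphans.tsv"))
    prot <- Biostrings::readAAStringSet(file.path(dir, "proteins.faa"))
    sub <- prot[names(prot) %in% res$orphans$protein_id]
    tmp <- file.path(dir, "out", "orphans.faa.tmp")
    Biostrings::writeXStringSet(sub, tmp)
    file.rename(tmp, file.path(dir, "out", "orphans.faa"))
    .funnelAppend(dir, "orphans", NA, NA, nrow(ann), nrow(res$orphans),
                  NA, length(unique(res$orphans$metagenome_id)))
    invisible(res)
}

.stageCompare <- function(dir, config) {
    prot <- Biostrings::readAAStringSet(file.path(dir, "proteins.faa"))
    ls <- lengthSummary(Biostrings::width(prot))
    exons <- readGeneStructures(file.path(dir, "prediction.gff"))
    is <- intronStats(exons)
    kv <- list(n_proteins = ls$n, total_aa = ls$total_aa,
               mean_aa = ls$mean_aa, median_aa = ls$median_aa,
               skewness = ls$skewness,
               n_genes_with_introns = is$n_genes_with_introns,
               n_contigs_with_intron_genes =
                   is$n_contigs_with_intron_genes,
               mean_intron_fraction = is$mean_intron_fraction,
               length_test = "Welch unequal-variance t")
    buscoDir <- file.path(dir, "busco")
    cmp <- NULL
    if (dir.exists(file.path(buscoDir, "methodA"))) {
        readAll <- function(sub, method) do.call(rbind, lapply(
            list.files(file.path(buscoDir, sub), full.names = TRUE),
            function(p) parseBuscoTable(
                p, sub("\\.txt$", "", basename(p)), method)))
        cmp <- compareBusco(readAll("methodA", "reannotation"),
                            readAll("methodB", "initial"))
        kv <- c(kv, cmp[c("n_pairs", "n_improved", "mean_improvement",
                          "wilcox_complete_p", "wilcox_fragmented_p")])
    }
    if (file.exists(file.path(dir, "clusters.tsv"))) {
        cs <- clusterSummary(file.path(dir, "clusters.tsv"), prot)
        kv <- c(kv, list(n_clusters = cs$n_clusters,
                         n_cluster_members = cs$n_members))
    }
    .writeTableAtomic(data.frame(metric = names(kv),
                                 value = vapply(kv, function(v)
                                     paste(format(v), collapse = ";"),
                                     ""), stringsAsFactors = FALSE),
                      file.path(dir, "out", "compare_report.tsv"))
    invisible(c(kv, list(busco = cmp, intron = is)))
}

#' Run the full pipeline on a working directory
#'
#' Executes `qc`, `select`, `models`, `annotate`, `confirm`, `orphans`
#' and `compare` in order (the external classifier, gene predictor and
#' aligner are integration points: their output files must already be in
#' `dir`, e.g. from [runStage()]'s `simulate`).
#'
#' @param dir Working directory.
#' @param config A [PipelineConfig-class].
#' @return Invisibly, the funnel report data.frame.
#' @export
runPipeline <- function(dir, config = pipelineConfig()) {
    for (s in c("qc", "select", "models", "annotate", "confirm",
                "orphans", "compare"))
        runStage(s, dir, config)
    invisible(utils::read.delim(file.path(dir, "out", "funnel.tsv"),
                                stringsAsFactors = FALSE))
}
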