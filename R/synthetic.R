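## Deterministic synthetic fixtures: a mini taxonomy in taxdump dialect, a
## contig community with every downstream file format, and paired BUSCO
## tables -- all with ground-truth labels so recovery is checkable.
## Every output is a deterministic function of (spec, seed).

#' Specification of a synthetic soil community
#'
#' Bundles every knob of the generator.  The defaults emulate the
#' filtered study corpus: lognormal contig lengths with median ~1,350 bp
#' and mean ~1,985 bp, batch weights proportional to the three dataset
#' sizes (884 / 3,601 / 2,387 metagenomes), 82% of contigs classified,
#' protein homology sources in the published superkingdom proportions
#' (47.6% prokaryote / 8.6% eukaryote / 0.1% viruses, the undetermined
#' remainder split 67/33 between untraceable and no-hit), an intron in
#' 29% of genes spanning 17% of the gene length on average, and two
#' predicted proteins per contig on average.
#'
#' Fractions are honoured exactly: label counts are allocated by largest
#' remainder before being shuffled over contigs/proteins, so a planted
#' fraction of 0.25 is recovered as exactly 0.25.
#'
#' @param nContigs Number of contigs entering QC.
#' @param batches,batchWeights Dataset labels and their mixture weights.
#' @param nMetagenomes Number of metagenome ids contigs are spread over.
#' @param eukContigFraction Fraction of contigs classified eukaryotic.
#' @param classifiedFraction Fraction of contigs classified at all.
#' @param binFractions Named fractions of protein homology sources:
#'   Eukaryote, Prokaryote, Viruses, untraceable, no_hit (sum to 1).
#' @param contigLenMeanlog,contigLenSdlog Lognormal length parameters.
#' @param qcMixture Optional named fractions `long`, `short_geney`,
#'   `short` forcing an exact QC-class mixture instead of the lognormal
#'   draw (empty = lognormal).
#' @param genesPerContigLambda Poisson mean of initial gene calls.
#' @param proteinsPerContigLambda Mean predicted proteins per eukaryotic
#'   contig (>= 1; one protein is guaranteed).
#' @param proteinLenMeanlog,proteinLenSdlog Lognormal protein length (aa).
#' @param intronRate Fraction of genes carrying an intron.
#' @param intronFractionMean,intronFractionConc Beta mean/concentration of
#'   the per-gene intron span fraction.
#' @param hitsPerProtein Homology hits generated per hit-bearing protein.
#' @param bitscoreBest,bitscoreDecay Best bitscore and geometric decay of
#'   successive hits (decay 0.97 keeps several hits inside a 10% margin).
#' @param writeFasta Whether to write contig DNA (lengths are always
#'   written as a TSV as well).
#' @param seed Integer seed fixing all randomness.
#' @return A list of class `CommunitySpec`.
#' @export
communitySpec <- function(nContigs = 2000L,
                          batches = c("Plant-associated", "Terrestrial 1",
                                      "Terrestrial 2"),
                          batchWeights = c(884, 3601, 2387),
                          nMetagenomes = 50L,
                          eukContigFraction = 0.25,
                          classifiedFraction = 0.82,
                          binFractions = c(Eukaryote = 0.086,
                                           Prokaryote = 0.476,
                                           Viruses = 0.001,
                                           untraceable = 0.293,
                                           no_hit = 0.144),
                          contigLenMeanlog = log(1350),
                          contigLenSdlog = 0.878,
                          qcMixture = numeric(0),
                          genesPerContigLambda = 1,
                          proteinsPerContigLambda = 2,
                          proteinLenMeanlog = log(300),
                          proteinLenSdlog = 0.5,
                          intronRate = 0.29,
                          intronFractionMean = 0.17,
                          intronFractionConc = 100,
                          hitsPerProtein = 5L,
                          bitscoreBest = 200,
                          bitscoreDecay = 0.97,
                          writeFasta = TRUE,
                          seed = 1L) {
    stopifnot(nContigs >= 1L, length(batches) == length(batchWeights),
              abs(sum(binFractions) - 1) < 1e-8,
              all(binFractions >= 0),
              all(c("Eukaryote", "Prokaryote", "Viruses", "untraceable",
                    "no_hit") %in% names(binFractions)))
    if (length(qcMixture) &&
        (!setequal(names(qcMixture), c("long", "short_geney", "short")) ||
         abs(sum(qcMixture) - 1) > 1e-8))
        stop("qcMixture must be fractions long/short_geney/short summing",
             " to 1")
    structure(as.list(environment()), class = "CommunitySpec")
}

#' @export
print.CommunitySpec <- function(x, ...) {
    cat("CommunitySpec:", x$nContigs, "contigs,",
        length(x$batches), "batches, seed", x$seed, "\n")
    cat("  euk contig fraction:", x$eukContigFraction,
        "| protein sources:",
        paste(names(x$binFractions), x$binFractions, sep = "=",
              collapse = " "), "\n")
    invisible(x)
}

## exact integer allocation of n over fractions (largest remainder)
.allocate <- function(n, fractions) {
    raw <- n * fractions
    base <- floor(raw)
    left <- n - sum(base)
    if (left > 0) {
        extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
        base[extra] <- base[extra] + 1
    }
    as.integer(base)
}

.dmpLine <- function(...) paste0(paste(..., sep = "\t|\t"), "\t|")

#' Generate a loadable mini taxonomy in taxdump dialect
#'
#' Builds a rooted taxonomy with real-world anchor taxids (root 1,
#' "cellular organisms" 131567, Bacteria 2, Archaea 2157, Eukaryota 2759,
#' Viruses 10239, untraceable 12908/32644), a complete `branching`-ary
#' subtree of the given `depth` under Eukaryota whose leaves are species,
#' small prokaryotic and viral species pools, and `nModels` gene-model
#' species planted at random eukaryotic leaves.  Also emits a small
#' merged.dmp/delnodes.dmp pair and the ground-truth edge list.
#'
#' @param dir Output directory (created if needed).
#' @param depth Levels below the Eukaryota anchor (>= 2).
#' @param branching Children per internal eukaryotic node (>= 2).
#' @param nModels Number of model species to plant (<= number of leaves).
#' @param seed Integer seed.
#' @return List: `nodesPath`, `namesPath`, `mergedPath`, `delnodesPath`,
#'   `edges` (data.frame taxid/parent/rank), `modelTaxids` (named
#'   integer), `eukSpecies`, `eukGenera`, `prokSpecies` (split by
#'   Bacteria/Archaea), `virSpecies`, `nEukNodes` (anchor + descendants),
#'   `anchors`.
#' @export
makeTaxdump <- function(dir, depth = 4L, branching = 3L, nModels = 10L,
                        seed = 1L) {
    if (depth < 2L || branching < 2L)
        stop("infeasible taxonomy shape: need depth >= 2 and branching",
             " >= 2")
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    set.seed(as.integer(seed))

    taxid <- integer(0); parent <- integer(0); rank <- character(0)
    nm <- character(0)
    addNode <- function(id, par, rk, name) {
        taxid <<- c(taxid, id); parent <<- c(parent, par)
        rank <<- c(rank, rk); nm <<- c(nm, name)
        id
    }
    addNode(1L, 1L, "no rank", "root")
    addNode(131567L, 1L, "no rank", "cellular organisms")
    addNode(2L, 131567L, "superkingdom", "Bacteria")
    addNode(2157L, 131567L, "superkingdom", "Archaea")
    addNode(2759L, 131567L, "superkingdom", "Eukaryota")
    addNode(10239L, 1L, "superkingdom", "Viruses")
    addNode(12908L, 1L, "no rank", "unclassified sequences")
    addNode(32644L, 1L, "no rank", "other sequences")

    nextId <- 100000L
    fresh <- function() { nextId <<- nextId + 1L; nextId }
    ladder <- c("kingdom", "phylum", "class", "order", "family", "genus",
                "species")
    ranks <- if (depth <= length(ladder))
        utils::tail(ladder, depth) else
        c(rep("clade", depth - length(ladder)), ladder)

    level <- list(2759L)
    for (d in seq_len(depth)) {
        nxt <- integer(0)
        for (p in level[[1L]]) {
            for (k in seq_len(branching)) {
                id <- fresh()
                addNode(id, p, ranks[d],
                        sprintf("Euk %s %d", ranks[d], id))
                nxt <- c(nxt, id)
            }
        }
        level[[1L]] <- nxt
        if (d == depth - 1L) eukGenera <- nxt
        if (d == depth) eukSpecies <- nxt
    }

    prokSpecies <- list(Bacteria = integer(0), Archaea = integer(0))
    for (sk in c("Bacteria", "Archaea")) {
        skId <- if (sk == "Bacteria") 2L else 2157L
        for (g in 1:2) {
            gid <- addNode(fresh(), skId, "genus",
                           sprintf("%s genus %d", sk, g))
            for (s in 1:3)
                prokSpecies[[sk]] <- c(prokSpecies[[sk]],
                    addNode(fresh(), gid, "species",
                            sprintf("%s species %d.%d", sk, g, s)))
        }
    }
    virSpecies <- vapply(1:3, function(s)
        addNode(fresh(), 10239L, "species",
                sprintf("Virus species %d", s)), integer(1))

    if (nModels > length(eukSpecies))
        stop("infeasible shape: ", nModels, " models but only ",
             length(eukSpecies), " eukaryotic leaves")
    modelTaxids <- sort(sample(eukSpecies, nModels))
    names(modelTaxids) <- sprintf("model_%03d", seq_len(nModels))

    nodesPath <- file.path(dir, "nodes.dmp")
    namesPath <- file.path(dir, "names.dmp")
    writeLines(.dmpLine(taxid, parent, rank), nodesPath)
    ## names.dmp with a non-scientific name class the loader must ignore
    nameLines <- c(.dmpLine(taxid, nm, "", "scientific name"),
                   .dmpLine(taxid[1:3], paste("alias of", nm[1:3]), "",
                            "synonym"))
    writeLines(nameLines, namesPath)

    mergedPath <- file.path(dir, "merged.dmp")
    delnodesPath <- file.path(dir, "delnodes.dmp")
    writeLines(.dmpLine(99999L, eukSpecies[1L]), mergedPath)
    writeLines(.dmpLine(88888L), delnodesPath)

    list(nodesPath = nodesPath, namesPath = namesPath,
         mergedPath = mergedPath, delnodesPath = delnodesPath,
         edges = data.frame(taxid = taxid, parent = parent, rank = rank,
                            stringsAsFactors = FALSE),
         modelTaxids = modelTaxids,
         eukSpecies = eukSpecies, eukGenera = eukGenera,
         prokSpecies = prokSpecies, virSpecies = virSpecies,
         nEukNodes = (branching^(depth + 1L) - 1L) %/% (branching - 1L),
         anchors = c(Bacteria = 2L, Archaea = 2157L, Eukaryota = 2759L,
                     Viruses = 10239L))
}

.randSeq <- function(len, alphabet) {
    vapply(len, function(l)
        paste(sample(alphabet, l, replace = TRUE), collapse = ""),
        character(1))
}

#' Generate a full synthetic community
#'
#' Emits, into `dir`, every file the pipeline consumes -- contig FASTA
#' (optional) and length TSV, initial gene-call GFF, per-sequence
#' classifier output for the QC-surviving contigs, eukaryote gene
#' prediction GFF and protein FASTA, tabular homology hits, and a cluster
#' membership TSV -- plus ground-truth tables for contigs and proteins.
#'
#' Homology hits of a eukaryote-source protein are drawn from a single
#' eukaryotic genus (so the LCA stays below Eukaryota); prokaryote
#' sources from a single bacterial or archaeal genus; virus sources from
#' viral species; untraceable proteins hit an untraceable taxid; no-hit
#' proteins are absent from the table.  Bitscores decay geometrically
#' from the best hit, E-values all pass the default gate.
#'
#' @param spec A [communitySpec()].
#' @param taxdump Result of [makeTaxdump()].
#' @param dir Output directory.
#' @return List of paths (`contigFasta`, `contigLengths`, `jgiGff`,
#'   `krakenOut`, `predictionGff`, `proteinFasta`, `hitsTsv`,
#'   `clusterTsv`, `contigTruth`, `proteinTruth`) plus the in-memory
#'   truth data.frames `contigs` and `proteins`.
#' @export
makeCommunity <- function(spec, taxdump, dir) {
    stopifnot(inherits(spec, "CommunitySpec"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    set.seed(spec$seed)
    n <- spec$nContigs

    ## each metagenome belongs to exactly one batch; contigs inherit it
    mgIds <- sprintf("33%08d", seq_len(spec$nMetagenomes))
    mgBatch <- sample(rep(spec$batches,
                          .allocate(spec$nMetagenomes,
                                    spec$batchWeights /
                                        sum(spec$batchWeights))))
    mgOf <- sample.int(spec$nMetagenomes, n, replace = TRUE)
    metag <- mgIds[mgOf]
    batch <- mgBatch[mgOf]
    cid <- sprintf("ctg%05d", seq_len(n))

    if (length(spec$qcMixture)) {
        cls <- sample(rep(c("long", "short_geney", "short"),
                          .allocate(n, spec$qcMixture[c("long",
                              "short_geney", "short")])))
        len <- ifelse(cls == "long",
                      1000L + stats::rpois(n, 900),
                      100L + stats::rpois(n, 300))
        len <- pmin(len, 999L + 10000L * (cls == "long"))
        len[cls == "long"] <- pmax(len[cls == "long"], 1000L)
        genes <- ifelse(cls == "short_geney", 3L + stats::rpois(n, 1),
                        stats::rpois(n, 1))
        genes[cls != "short_geney"] <- pmin(genes[cls != "short_geney"],
                                            2L)
    } else {
        len <- pmax(100L, as.integer(round(stats::rlnorm(
            n, spec$contigLenMeanlog, spec$contigLenSdlog))))
        genes <- stats::rpois(n, spec$genesPerContigLambda)
    }
    qcPass <- len >= 1000L | genes >= 3L

    ## eukaryotic / classified labels over the QC survivors, exact counts
    kept <- which(qcPass)
    nk <- length(kept)
    nEuk <- .allocate(nk, c(spec$eukContigFraction,
                            1 - spec$eukContigFraction))[1L]
    nClassified <- max(.allocate(nk, c(spec$classifiedFraction,
                                       1 - spec$classifiedFraction))[1L],
                       nEuk)
    lab <- rep("unclassified", nk)
    pick <- sample.int(nk)
    lab[pick[seq_len(nEuk)]] <- "euk"
    if (nClassified > nEuk)
        lab[pick[(nEuk + 1L):nClassified]] <- "prok"
    contigTaxid <- rep(0L, nk)
    contigTaxid[lab == "euk"] <- sample(c(taxdump$eukSpecies,
                                          taxdump$eukGenera),
                                        sum(lab == "euk"), replace = TRUE)
    contigTaxid[lab == "prok"] <- sample(unlist(taxdump$prokSpecies),
                                         sum(lab == "prok"),
                                         replace = TRUE)

    contigs <- data.frame(contig_id = cid, metagenome_id = metag,
                          batch = batch, length_bp = len,
                          gene_count = genes, qc_pass = qcPass,
                          stringsAsFactors = FALSE)
    contigs$classified <- FALSE
    contigs$taxid <- 0L
    contigs$is_euk <- FALSE
    contigs$classified[kept] <- lab != "unclassified"
    contigs$taxid[kept] <- contigTaxid
    contigs$is_euk[kept] <- lab == "euk"

    ## ---- files: contigs + initial gene calls -------------------------
    paths <- list()
    paths$contigLengths <- file.path(dir, "contig_lengths.tsv")
    utils::write.table(contigs[, c("contig_id", "length_bp")],
                       paths$contigLengths, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    if (spec$writeFasta) {
        seqs <- Biostrings::DNAStringSet(.randSeq(len,
                                                  c("A", "C", "G", "T")))
        names(seqs) <- cid
        paths$contigFasta <- file.path(dir, "contigs.fna")
        Biostrings::writeXStringSet(seqs, paths$contigFasta)
    }
    paths$jgiGff <- file.path(dir, "jgi_genes.gff")
    gffLines <- c("##gff-version 3")
    for (i in which(genes > 0L)) {
        g <- genes[i]
        st <- pmin(1L + (seq_len(g) - 1L) * 120L, pmax(len[i] - 90L, 1L))
        gffLines <- c(gffLines, sprintf(
            "%s\tjgi\tCDS\t%d\t%d\t.\t+\t0\tID=%s.c%d",
            cid[i], st, st + 89L, cid[i], seq_len(g)))
    }
    writeLines(gffLines, paths$jgiGff)

    ## ---- classifier output for QC survivors --------------------------
    paths$krakenOut <- file.path(dir, "kraken.out")
    kl <- sprintf("%s\t%s\t%d\t%d\t%s",
                  ifelse(lab == "unclassified", "U", "C"),
                  cid[kept], contigTaxid, len[kept],
                  ifelse(lab == "unclassified", "0:50",
                         paste0(contigTaxid, ":50")))
    writeLines(kl, paths$krakenOut)

    ## ---- gene prediction on eukaryotic contigs -----------------------
    eukIdx <- which(contigs$is_euk)
    nProt <- 1L + stats::rpois(length(eukIdx),
                               max(spec$proteinsPerContigLambda - 1, 0))
    protContig <- rep(eukIdx, nProt)
    protGene <- sequence(nProt)
    pid <- as.character(mapply(makeProteinId, cid[protContig],
                               metag[protContig],
                               sprintf("g%d", protGene),
                               USE.NAMES = FALSE))
    np <- length(pid)
    protLen <- pmax(30L, as.integer(round(stats::rlnorm(
        np, spec$proteinLenMeanlog, spec$proteinLenSdlog))))

    hasIntron <- stats::runif(np) < spec$intronRate
    a <- spec$intronFractionMean * spec$intronFractionConc
    b <- (1 - spec$intronFractionMean) * spec$intronFractionConc
    intronFrac <- ifelse(hasIntron, stats::rbeta(np, a, b), 0)
    exonic <- 3L * protLen + 3L
    intronSpan <- as.integer(round(intronFrac / (1 - intronFrac) * exonic))
    intronSpan[!hasIntron] <- 0L

    paths$predictionGff <- file.path(dir, "prediction.gff")
    pg <- vector("list", np + 1L)
    pg[[1L]] <- "##gff-version 3"
    offset <- integer(n)  # running coordinate per contig
    for (j in seq_len(np)) {
        ci <- protContig[j]
        st <- offset[ci] + 1L
        span <- exonic[j] + intronSpan[j]
        if (intronSpan[j] > 0L) {
            cut <- exonic[j] %/% 2L
            ex <- rbind(c(st, st + cut - 1L),
                        c(st + cut + intronSpan[j],
                          st + span - 1L))
        } else ex <- rbind(c(st, st + span - 1L))
        pg[[j + 1L]] <- c(
            sprintf("%s\tpredictor\tgene\t%d\t%d\t.\t+\t.\tID=%s",
                    cid[ci], st, st + span - 1L, pid[j]),
            sprintf("%s\tpredictor\tCDS\t%d\t%d\t.\t+\t0\tParent=%s",
                    cid[ci], ex[, 1L], ex[, 2L], pid[j]))
        offset[ci] <- st + span + 50L
    }
    writeLines(unlist(pg), paths$predictionGff)

    aa <- Biostrings::AAStringSet(.randSeq(protLen,
        strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]))
    names(aa) <- pid
    paths$proteinFasta <- file.path(dir, "proteins.faa")
    Biostrings::writeXStringSet(aa, paths$proteinFasta)

    ## ---- homology hits with exact source-label allocation ------------
    labNames <- c("Eukaryote", "Prokaryote", "Viruses", "untraceable",
                  "no_hit")
    counts <- .allocate(np, spec$binFractions[labNames])
    srcLab <- sample(rep(labNames, counts))
    k <- spec$hitsPerProtein
    scores <- spec$bitscoreBest * spec$bitscoreDecay^(seq_len(k) - 1L)
    spPar <- taxdump$edges$parent[match(taxdump$eukSpecies,
                                        taxdump$edges$taxid)]
    hitLines <- vector("list", np)
    for (j in seq_len(np)) {
        subj <- switch(srcLab[j],
            no_hit = NULL,
            untraceable = sample(c(12908L, 32644L), 1L),
            Eukaryote = {
                ## all subjects inside one genus: LCA stays eukaryotic
                g <- sample(taxdump$eukGenera, 1L)
                sample(c(g, taxdump$eukSpecies[spPar == g]), k,
                       replace = TRUE)
            },
            Prokaryote = {
                pool <- taxdump$prokSpecies[[sample(c("Bacteria",
                                                      "Archaea"), 1L)]]
                sample(pool, k, replace = TRUE)
            },
            Viruses = sample(taxdump$virSpecies, k, replace = TRUE))
        if (is.null(subj)) next
        kk <- length(subj)
        hitLines[[j]] <- sprintf(
            "%s\tref%06d\t%.1f\t%d\t%.1e\t%.1f\t%s",
            pid[j], sample.int(999999L, kk), 90 + stats::runif(kk) * 9,
            protLen[j], 10^-(20 + seq_len(kk)), scores[seq_len(kk)],
            subj)
    }
    paths$hitsTsv <- file.path(dir, "hits.tsv")
    writeLines(as.character(unlist(hitLines)), paths$hitsTsv)

    ## ---- cluster membership (planted redundancy 2x) ------------------
    paths$clusterTsv <- file.path(dir, "clusters.tsv")
    reps <- pid[seq_len(ceiling(np / 2)) * 2L - 1L]
    memb <- data.frame(rep = reps[ceiling(seq_len(np) / 2)],
                       member = pid, stringsAsFactors = FALSE)
    utils::write.table(memb, paths$clusterTsv, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)

    ## ---- truth tables -------------------------------------------------
    proteins <- data.frame(protein_id = pid,
                           contig_id = cid[protContig],
                           metagenome_id = metag[protContig],
                           batch = batch[protContig],
                           length_aa = protLen,
                           source = srcLab,
                           has_intron = hasIntron,
                           intron_fraction = intronSpan /
                               (exonic + intronSpan),
                           stringsAsFactors = FALSE)
    eukFracByContig <- tapply(proteins$source == "Eukaryote",
                              proteins$contig_id, mean)
    proteins$contig_euk_fraction <-
        as.numeric(eukFracByContig[proteins$contig_id])
    proteins$is_orphan <- proteins$source %in%
        c("no_hit", "untraceable") & proteins$contig_euk_fraction >= 0.5

    paths$contigTruth <- file.path(dir, "truth_contigs.tsv")
    paths$proteinTruth <- file.path(dir, "truth_proteins.tsv")
    utils::write.table(contigs, paths$contigTruth, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(proteins, paths$proteinTruth, sep = "\t",
                       quote = FALSE, row.names = FALSE)

    c(paths, list(contigs = contigs, proteins = proteins))
}

#' Generate paired BUSCO summaries with a planted completeness shift
#'
#' Writes per-metagenome short-summary files for two methods where method
#' A's completeness is method B's plus `shift` (plus noise), and
#' fragmentation correspondingly lower.  All percentages are one-decimal
#' consistent (S + D = C, C + F + M = 100).
#'
#' @param dir Output directory (subdirs `methodA/`, `methodB/`).
#' @param nMetagenomes Number of paired summaries.
#' @param shift Planted mean completeness improvement (percentage
#'   points).
#' @param baselineRange Uniform range of method B completeness, chosen so
#'   the shifted score never truncates at 100.
#' @param noiseSd Gaussian noise on the shift.
#' @param nMarkers Marker count written into each summary (default 255).
#' @param seed Integer seed.
#' @return List: `dirA`, `dirB`, `pathsA`, `pathsB`, `truth` (data.frame
#'   with per-metagenome planted values and the realised shift).
#' @export
makeBuscoTables <- function(dir, nMetagenomes = 500L, shift = 11.9,
                            baselineRange = c(10, 70), noiseSd = 2,
                            nMarkers = 255L, seed = 1L) {
    set.seed(as.integer(seed))
    dirA <- file.path(dir, "methodA"); dirB <- file.path(dir, "methodB")
    dir.create(dirA, showWarnings = FALSE, recursive = TRUE)
    dir.create(dirB, showWarnings = FALSE, recursive = TRUE)
    mg <- sprintf("33%08d", seq_len(nMetagenomes))
    cB <- round(stats::runif(nMetagenomes, baselineRange[1L],
                             baselineRange[2L]), 1)
    d <- round(shift + stats::rnorm(nMetagenomes, 0, noiseSd), 1)
    cA <- pmin(round(cB + d, 1), 100)

    writeOne <- function(path, complete, fragShare) {
        single <- round(complete * stats::runif(1, 0.3, 0.9), 1)
        dup <- round(complete - single, 1)
        frag <- round((100 - complete) * fragShare, 1)
        miss <- round(100 - complete - frag, 1)
        writeLines(c(
            "# BUSCO short summary (synthetic)",
            sprintf("\tC:%.1f%%[S:%.1f%%,D:%.1f%%],F:%.1f%%,M:%.1f%%,n:%d",
                    complete, single, dup, frag, miss, nMarkers)), path)
        path
    }
    pathsA <- vapply(seq_len(nMetagenomes), function(i)
        writeOne(file.path(dirA, paste0(mg[i], ".txt")), cA[i],
                 stats::runif(1, 0.2, 0.5)), character(1))
    pathsB <- vapply(seq_len(nMetagenomes), function(i)
        writeOne(file.path(dirB, paste0(mg[i], ".txt")), cB[i],
                 stats::runif(1, 0.4, 0.8)), character(1))
    list(dirA = dirA, dirB = dirB, pathsA = pathsA, pathsB = pathsB,
         truth = data.frame(metagenome_id = mg, complete_a = cA,
                            complete_b = cB, shift = cA - cB,
                            stringsAsFactors = FALSE))
}
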