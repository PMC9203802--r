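## Contig-level confirmation of eukaryotic origin (majority-of-proteins
## rule), orphan extraction, and the protein id nomenclature.

#' Per-contig eukaryotic protein fractions
#'
#' For every contig carrying at least one predicted protein: the number
#' of proteins, how many received a eukaryotic LCA, how many stayed
#' Undetermined, and the eukaryotic fraction (denominator: all predicted
#' proteins on the contig).
#'
#' @param annotations Data.frame from [annotateProteins()] (needs
#'   `contig_id`, `metagenome_id`, `bin`).
#' @return Data.frame: `contig_id`, `metagenome_id`, `n_proteins`,
#'   `n_eukaryote`, `n_undetermined`, `euk_fraction`.
#' @export
contigEukFraction <- function(annotations) {
    if (!nrow(annotations))
        stop("contigEukFraction() needs at least one annotated protein")
    sp <- split(seq_len(nrow(annotations)), annotations$contig_id)
    rows <- lapply(names(sp), function(cid) {
        i <- sp[[cid]]
        n <- length(i)
        ne <- sum(annotations$bin[i] == "Eukaryote")
        data.frame(contig_id = cid,
                   metagenome_id = annotations$metagenome_id[i[1L]],
                   n_proteins = n, n_eukaryote = ne,
                   n_undetermined = sum(annotations$bin[i] ==
                                        "Undetermined"),
                   euk_fraction = ne / n, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Contigs confirmed as eukaryotic
#'
#' A contig is confirmed when its eukaryotic protein fraction reaches
#' `eukFractionMin` (inclusive: "at least 50%" keeps a contig at exactly
#' one half).
#'
#' @param summaries Data.frame from [contigEukFraction()].
#' @param config A [PipelineConfig-class].
#' @return Character vector of confirmed contig ids.
#' @export
confirmedContigs <- function(summaries, config = pipelineConfig()) {
    summaries$contig_id[summaries$euk_fraction >= config@eukFractionMin]
}

#' Extract orphan proteins
#'
#' Orphans are proteins with no traceable homology — Undetermined
#' annotations whose subtype is in `orphanSubtypes` — sitting on a
#' confirmed (majority-eukaryotic) contig.  Proteins binned into any
#' superkingdom are never orphans.
#'
#' @param annotations Data.frame from [annotateProteins()].
#' @param confirmed Character vector from [confirmedContigs()].
#' @param config A [PipelineConfig-class].
#' @return A list with `orphans` (the qualifying annotation rows) and
#'   `bySubtype` (named counts over the configured subtypes), so either
#'   the strict no-hit or the extended definition is recoverable.
#' @export
extractOrphans <- function(annotations, confirmed,
                           config = pipelineConfig()) {
    sel <- annotations$bin == "Undetermined" &
        annotations$subtype %in% config@orphanSubtypes &
        annotations$contig_id %in% confirmed
    orphans <- annotations[sel, , drop = FALSE]
    bySubtype <- vapply(config@orphanSubtypes, function(s)
        sum(orphans$subtype == s), integer(1))
    list(orphans = orphans, bySubtype = bySubtype)
}

#' Mint a protein identifier
#'
#' Deterministic `contigName_metagenomeID.geneID` concatenation,
#' invertible by rightmost-separator parsing: the metagenome id must not
#' contain `_` or `.`, and the gene id must not contain `.` or `_`; the
#' contig name may contain `_` but not `.`.
#'
#' @param contigName,metagenomeId,geneId Non-empty id components.
#' @return The protein id string.
#' @examples
#' makeProteinId("ctg42", "3300031471", "g5")  # "ctg42_3300031471.g5"
#' @seealso [parseProteinId()]
#' @export
makeProteinId <- function(contigName, metagenomeId, geneId) {
    if (!nzchar(contigName) || !nzchar(metagenomeId) || !nzchar(geneId))
        stop("protein id components must be non-empty")
    if (grepl(".", contigName, fixed = TRUE))
        stop("contig name must not contain '.': ", contigName)
    if (grepl("[_.]", metagenomeId))
        stop("metagenome id must not contain '_' or '.': ", metagenomeId)
    if (grepl("[_.]", geneId))
        stop("gene id must not contain '_' or '.': ", geneId)
    paste0(contigName, "_", metagenomeId, ".", geneId)
}

#' Parse a protein identifier
#'
#' Inverts [makeProteinId()] by splitting at the rightmost `.` (gene id)
#' and then the rightmost `_` (metagenome id).
#'
#' @param proteinId A `contigName_metagenomeID.geneID` string.
#' @return List with `contig`, `metagenome`, `gene`.
#' @export
parseProteinId <- function(proteinId) {
    dot <- regexpr("\\.[^.]*$", proteinId)
    if (dot < 2L) stop("malformed protein id (no gene id): ", proteinId)
    gene <- substring(proteinId, dot + 1L)
    rest <- substring(proteinId, 1L, dot - 1L)
    us <- regexpr("_[^_]*$", rest)
    if (us < 2L) stop("malformed protein id (no metagenome id): ",
                      proteinId)
    out <- list(contig = substring(rest, 1L, us - 1L),
                metagenome = substring(rest, us + 1L),
                gene = gene)
    if (!nzchar(out$contig) || !nzchar(out$metagenome) || !nzchar(out$gene))
        stop("malformed protein id: ", proteinId)
    out
}
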