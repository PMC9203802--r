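## Contig quality control: the length-or-gene-count retention rule and the
## per-batch funnel bookkeeping (contigs and metagenomes surviving).

#' Contig retention rule
#'
#' A contig is retained when it is at least `minContigLen` bp long *or*
#' carries at least `minGeneCount` initial (prokaryotic-caller) gene
#' calls; both bounds are inclusive.  Vectorised over contigs.
#'
#' @param lengthBp Integer vector of contig lengths in bp.
#' @param geneCount Integer vector of initial gene-call counts (a contig
#'   absent from the gene-call file counts 0 genes).
#' @param config A [PipelineConfig-class].
#' @return Logical vector.
#' @examples
#' passesQC(c(999L, 1000L, 500L), c(2L, 0L, 3L))  # FALSE TRUE TRUE
#' @export
passesQC <- function(lengthBp, geneCount, config = pipelineConfig()) {
    stopifnot(length(lengthBp) == length(geneCount))
    lengthBp >= config@minContigLen | geneCount >= config@minGeneCount
}

#' Filter a contig table and report the funnel
#'
#' Applies [passesQC()] to every contig and reports, per batch, how many
#' contigs and metagenomes enter and survive (a metagenome survives iff at
#' least one of its contigs is kept).
#'
#' @param contigs A data.frame with columns `contig_id`, `metagenome_id`,
#'   `length_bp`, `gene_count`, and optionally `batch` (a single
#'   unlabelled batch is assumed when absent).
#' @param config A [PipelineConfig-class].
#' @return A list with `kept` (the surviving rows, plus a `passed_qc`
#'   column on the full input under `contigs`) and `funnel`, a data.frame
#'   with one row per batch plus a `Total` row: contigs in/kept, survival
#'   percentage, metagenomes in/surviving.
#' @export
filterContigs <- function(contigs, config = pipelineConfig()) {
    required <- c("contig_id", "metagenome_id", "length_bp", "gene_count")
    miss <- setdiff(required, names(contigs))
    if (length(miss))
        stop("contig table lacks column(s): ", paste(miss, collapse = ", "))
    if (is.null(contigs$batch)) contigs$batch <- "all"
    ok <- if (nrow(contigs))
        passesQC(contigs$length_bp, contigs$gene_count, config)
    else logical(0)
    contigs$passed_qc <- ok

    batches <- unique(contigs$batch)
    rows <- lapply(c(batches, "Total"), function(b) {
        sel <- if (b == "Total") rep(TRUE, nrow(contigs)) else
            contigs$batch == b
        nIn <- sum(sel)
        nKept <- sum(sel & ok)
        mgIn <- length(unique(contigs$metagenome_id[sel]))
        mgOut <- length(unique(contigs$metagenome_id[sel & ok]))
        data.frame(batch = b, contigs_in = nIn, contigs_kept = nKept,
                   survival_pct = if (nIn) round(100 * nKept / nIn, 1)
                                  else 0,
                   metagenomes_in = mgIn, metagenomes_surviving = mgOut,
                   stringsAsFactors = FALSE)
    })
    list(kept = contigs[ok, , drop = FALSE],
         contigs = contigs,
         funnel = do.call(rbind, rows))
}

#' Count initial gene calls per contig from a GFF
#'
#' Counts `CDS` (or `gene`) features per seqid in a GFF3-like file.
#' Malformed lines (fewer than 8 tab-separated fields) are skipped with a
#' warning and tallied in the `skipped` attribute.  Contigs with no
#' features simply do not appear; treat absence as count 0.
#'
#' @param gffPath Path to the gene-call GFF.
#' @param featureTypes Feature types counted (default `CDS` and `gene`;
#'   when both occur for the same locus only `CDS` rows are counted to
#'   avoid double counting).
#' @return Named integer vector, contig id to gene count, with attribute
#'   `skipped` (number of malformed lines).
#' @export
readGeneCounts <- function(gffPath, featureTypes = c("CDS", "gene")) {
    if (!file.exists(gffPath)) stop("GFF not found: ", gffPath)
    lines <- readLines(gffPath)
    lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- lengths(fields) < 8L
    if (any(bad))
        warning("skipped ", sum(bad), " malformed GFF line(s) in ", gffPath)
    fields <- fields[!bad]
    if (!length(fields)) {
        out <- integer(0)
        attr(out, "skipped") <- sum(bad)
        return(out)
    }
    seqid <- vapply(fields, `[[`, "", 1L)
    type <- vapply(fields, `[[`, "", 3L)
    use <- if ("CDS" %in% type && "CDS" %in% featureTypes) type == "CDS"
           else type %in% featureTypes
    tab <- table(seqid[use])
    out <- as.integer(tab)
    names(out) <- names(tab)
    attr(out, "skipped") <- sum(bad)
    out
}

#' Contig lengths from a FASTA or index file
#'
#' Lengths are read from the FASTA itself; a two-column TSV
#' (`contig_id<TAB>length`) is accepted as a lighter alternative.
#'
#' @param path FASTA (`.fa`, `.fasta`, `.fna`) or TSV path.
#' @return Named integer vector of lengths in bp.
#' @export
readContigLengths <- function(path) {
    if (grepl("\\.(fa|fasta|fna)$", path, ignore.case = TRUE)) {
        seqs <- Biostrings::readDNAStringSet(path)
        out <- Biostrings::width(seqs)
        names(out) <- sub("\\s.*$", "", names(seqs))
        out
    } else {
        df <- utils::read.delim(path, header = FALSE,
                                col.names = c("contig_id", "length"),
                                stringsAsFactors = FALSE)
        out <- as.integer(df$length)
        names(out) <- df$contig_id
        out
    }
}
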