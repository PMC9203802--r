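## Validation metrics comparing a eukaryote-tailored re-annotation with
## the initial prokaryotic-caller one: protein length summaries and test,
## intron statistics, BUSCO aggregation with paired tests, and cluster
## bookkeeping.

#' Protein length summary
#'
#' @param lengthsAa Integer vector of protein lengths in amino acids
#'   (n >= 1).
#' @return List: `n`, `total_aa`, `mean_aa` (also rounded to integer for
#'   table parity as `mean_aa_rounded`), `median_aa`, `skewness` (sample
#'   third standardised moment).
#' @examples
#' lengthSummary(c(100L, 200L, 300L))$skewness  # 0: symmetric
#' @export
lengthSummary <- function(lengthsAa) {
    if (!length(lengthsAa)) stop("lengthSummary() needs n >= 1 lengths")
    n <- length(lengthsAa)
    tot <- sum(as.numeric(lengthsAa))
    m <- tot / n
    dev <- lengthsAa - m
    s2 <- mean(dev^2)
    skew <- if (s2 > 0) mean(dev^3) / s2^1.5 else 0
    list(n = n, total_aa = tot, mean_aa = m,
         mean_aa_rounded = round(m), median_aa = stats::median(lengthsAa),
         skewness = skew)
}

#' Unequal-variance t test on protein lengths
#'
#' Welch's two-sample t test; the statistic is positive when the first
#' group's mean exceeds the second's.  Groups of millions of metagenomic
#' protein lengths cannot be assumed to share a variance, hence the
#' unequal-variance form.
#'
#' @param lengthsA,lengthsB Numeric vectors, each n >= 2 with nonzero
#'   variance (at least one group must vary).
#' @return List: `t`, `p` (two-sided), `df`, `mean_a`, `mean_b`.
#' @export
welchT <- function(lengthsA, lengthsB) {
    if (length(lengthsA) < 2L || length(lengthsB) < 2L)
        stop("welchT() needs n >= 2 in both groups")
    if (stats::var(lengthsA) == 0 && stats::var(lengthsB) == 0)
        stop("welchT(): both groups are constant")
    ht <- stats::t.test(lengthsA, lengthsB, var.equal = FALSE)
    list(t = unname(ht$statistic), p = ht$p.value,
         df = unname(ht$parameter),
         mean_a = mean(lengthsA), mean_b = mean(lengthsB))
}

#' Read gene structures from a GFF
#'
#' Collects exon-level features (`CDS` or `exon`) per gene from a
#' GFF3-like file; genes are identified by the `ID=`/`Parent=` attribute.
#' Malformed lines are skipped with a warning.
#'
#' @param gffPath Path to the gene-structure GFF.
#' @param featureTypes Feature types treated as exons (default `CDS`).
#' @return Data.frame: `gene_id`, `contig_id`, `strand`, `start`, `end`
#'   (one row per exon, sorted by gene then start).
#' @export
readGeneStructures <- function(gffPath, featureTypes = "CDS") {
    if (!file.exists(gffPath)) stop("GFF not found: ", gffPath)
    lines <- readLines(gffPath)
    lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- lengths(fields) < 9L
    if (any(bad))
        warning("skipped ", sum(bad), " malformed GFF line(s) in ", gffPath)
    fields <- fields[!bad]
    type <- vapply(fields, `[[`, "", 3L)
    fields <- fields[type %in% featureTypes]
    if (!length(fields))
        return(data.frame(gene_id = character(0), contig_id = character(0),
                          strand = character(0), start = integer(0),
                          end = integer(0), stringsAsFactors = FALSE))
    attrs <- vapply(fields, `[[`, "", 9L)
    gid <- sub(".*(?:Parent|ID)=([^;]+).*", "\\1", attrs)
    out <- data.frame(
        gene_id = gid,
        contig_id = vapply(fields, `[[`, "", 1L),
        strand = vapply(fields, `[[`, "", 7L),
        start = as.integer(vapply(fields, `[[`, "", 4L)),
        end = as.integer(vapply(fields, `[[`, "", 5L)),
        stringsAsFactors = FALSE)
    out[order(out$gene_id, out$start), , drop = FALSE]
}

#' Intron statistics over gene structures
#'
#' Per gene, the genomic span is last exon end minus first exon start
#' plus one (strand-independent); the intron span is that minus the
#' summed exon lengths; the intron fraction is intron span over gene
#' span.  Single-exon genes carry no introns and are excluded from the
#' mean fraction.
#'
#' @param exons Data.frame from [readGeneStructures()] (`gene_id`,
#'   `contig_id`, `start`, `end`); exons of a gene must not overlap.
#' @return List: `n_genes`, `n_genes_with_introns`,
#'   `n_contigs_with_intron_genes`, `mean_intron_fraction` (NaN when no
#'   gene has introns), and `per_gene` (data.frame with `gene_id`,
#'   `contig_id`, `n_exons`, `gene_span`, `intron_span`,
#'   `intron_fraction`).
#' @export
intronStats <- function(exons) {
    sp <- split(seq_len(nrow(exons)), exons$gene_id)
    rows <- lapply(names(sp), function(g) {
        i <- sp[[g]]
        st <- exons$start[i]; en <- exons$end[i]
        o <- order(st)
        st <- st[o]; en <- en[o]
        if (any(st > en)) stop("exon with start > end in gene ", g)
        if (length(st) > 1L && any(st[-1L] <= en[-length(en)]))
            stop("overlapping exons in gene ", g)
        span <- en[length(en)] - st[1L] + 1L
        intron <- span - sum(en - st + 1L)
        data.frame(gene_id = g, contig_id = exons$contig_id[i[1L]],
                   n_exons = length(st), gene_span = span,
                   intron_span = intron,
                   intron_fraction = intron / span,
                   stringsAsFactors = FALSE)
    })
    per <- do.call(rbind, rows)
    rownames(per) <- NULL
    withIntron <- per[per$intron_span > 0L, , drop = FALSE]
    list(n_genes = nrow(per),
         n_genes_with_introns = nrow(withIntron),
         n_contigs_with_intron_genes =
             length(unique(withIntron$contig_id)),
         mean_intron_fraction = mean(withIntron$intron_fraction),
         per_gene = per)
}

#' Parse a BUSCO result table
#'
#' Accepts either the short-summary text (the
#' `C:..%[S:..%,D:..%],F:..%,M:..%,n:..` line) or the full per-marker
#' table (`Busco id<TAB>Status...`), from which percentages are computed
#' over distinct marker ids.  Internal consistency (single + duplicated
#' = complete within 0.1; complete + fragmented + missing = 100 within
#' 0.2) is checked with a warning.
#'
#' @param path Path to the BUSCO output file.
#' @param metagenomeId,method Labels stored in the result (default from
#'   the file name / empty).
#' @return Data.frame row: `metagenome_id`, `method`, `complete_pct`,
#'   `single_pct`, `duplicated_pct`, `fragmented_pct`, `missing_pct`,
#'   `n_markers`.
#' @export
parseBuscoTable <- function(path, metagenomeId = basename(path),
                            method = "") {
    lines <- readLines(path)
    sumLine <- grep("C:.*\\[S:.*,D:.*\\].*,F:.*,M:.*,n:", lines,
                    value = TRUE)
    if (length(sumLine)) {
        num <- function(tag) as.numeric(sub(
            sprintf(".*%s:([0-9.]+).*", tag), "\\1", sumLine[1L]))
        out <- data.frame(metagenome_id = metagenomeId, method = method,
                          complete_pct = num("C"), single_pct = num("S"),
                          duplicated_pct = num("D"),
                          fragmented_pct = num("F"),
                          missing_pct = num("M"),
                          n_markers = as.integer(num("n")),
                          stringsAsFactors = FALSE)
    } else {
        body <- lines[!startsWith(lines, "#") & nzchar(lines)]
        fields <- strsplit(body, "\t", fixed = TRUE)
        fields <- fields[lengths(fields) >= 2L]
        if (!length(fields))
            stop("unrecognised BUSCO dialect in ", path)
        id <- vapply(fields, `[[`, "", 1L)
        status <- vapply(fields, `[[`, "", 2L)
        statusOf <- tapply(status, id, function(s) {
            if ("Complete" %in% s || "Duplicated" %in% s) {
                if ("Duplicated" %in% s || sum(s == "Complete") > 1L)
                    "Duplicated" else "Complete"
            } else if ("Fragmented" %in% s) "Fragmented" else "Missing"
        })
        n <- length(statusOf)
        pct <- function(x) round(100 * sum(statusOf == x) / n, 1)
        out <- data.frame(metagenome_id = metagenomeId, method = method,
                          complete_pct = pct("Complete") +
                              pct("Duplicated"),
                          single_pct = pct("Complete"),
                          duplicated_pct = pct("Duplicated"),
                          fragmented_pct = pct("Fragmented"),
                          missing_pct = pct("Missing"),
                          n_markers = n, stringsAsFactors = FALSE)
    }
    if (abs(out$single_pct + out$duplicated_pct - out$complete_pct) > 0.1)
        warning("inconsistent BUSCO summary (S + D != C) in ", path)
    if (abs(out$complete_pct + out$fragmented_pct + out$missing_pct -
            100) > 0.2)
        warning("inconsistent BUSCO summary (C + F + M != 100) in ", path)
    out
}

#' Compare paired BUSCO summaries between two methods
#'
#' Pairs per-metagenome summaries of method A against method B and runs
#' paired Wilcoxon signed-rank tests on the complete and fragmented
#' percentages (zero-difference pairs dropped, the standard signed-rank
#' convention; ties midranked).  Also reports in how many metagenomes A
#' is at least as complete as B, and the mean improvement among the
#' strictly improved ones.
#'
#' @param summariesA,summariesB Data.frames of [parseBuscoTable()] rows
#'   covering the same metagenome ids.
#' @return List: `n_pairs`, `n_a_ge_b`, `n_improved`,
#'   `mean_improvement` (complete_pct, among strictly improved; NaN when
#'   none), `n_less_fragmented`, `mean_fragmentation_drop`,
#'   `wilcox_complete_p`, `wilcox_fragmented_p` (NA when degenerate, i.e.
#'   no differences at all), `no_difference` (logical).
#' @export
compareBusco <- function(summariesA, summariesB) {
    if (!setequal(summariesA$metagenome_id, summariesB$metagenome_id) ||
        nrow(summariesA) != nrow(summariesB))
        stop("BUSCO summary pairing error: metagenome ids differ")
    m <- match(summariesA$metagenome_id, summariesB$metagenome_id)
    b <- summariesB[m, , drop = FALSE]
    dC <- summariesA$complete_pct - b$complete_pct
    dF <- summariesA$fragmented_pct - b$fragmented_pct
    pairedP <- function(d) {
        if (all(d == 0)) return(NA_real_)
        suppressWarnings(stats::wilcox.test(d, exact = FALSE)$p.value)
    }
    improved <- dC > 0
    lessFrag <- dF < 0
    list(n_pairs = nrow(summariesA),
         n_a_ge_b = sum(dC >= 0),
         n_improved = sum(improved),
         mean_improvement = mean(dC[improved]),
         n_less_fragmented = sum(lessFrag),
         mean_fragmentation_drop = mean(-dF[lessFrag]),
         wilcox_complete_p = pairedP(dC),
         wilcox_fragmented_p = pairedP(dF),
         no_difference = all(dC == 0) && all(dF == 0))
}

#' Cluster-table bookkeeping
#'
#' Reads a two-column cluster membership TSV (representative id, member
#' id; every representative listed as its own member), counts clusters,
#' and extracts the representative subset of a protein FASTA.
#'
#' @param clusterTsv Path to the membership TSV (no header).
#' @param proteins Optional `AAStringSet` of the clustered proteins; when
#'   given, members absent from it are warned about and the
#'   representative FASTA subset is returned.
#' @return List: `n_clusters`, `n_members`, `representatives` (character
#'   vector), `membership` (data.frame `representative_id`, `member_id`),
#'   and `representative_seqs` (`AAStringSet` or NULL).
#' @export
clusterSummary <- function(clusterTsv, proteins = NULL) {
    df <- utils::read.delim(clusterTsv, header = FALSE,
                            col.names = c("representative_id", "member_id"),
                            stringsAsFactors = FALSE)
    reps <- unique(df$representative_id)
    selfless <- setdiff(reps, df$member_id[df$representative_id ==
                                           df$member_id])
    if (length(selfless))
        stop("representative(s) not listed as their own member: ",
             paste(utils::head(selfless, 5L), collapse = ", "))
    repSeqs <- NULL
    if (!is.null(proteins)) {
        unknown <- setdiff(df$member_id, names(proteins))
        if (length(unknown))
            warning(length(unknown),
                    " cluster member(s) absent from the protein set")
        repSeqs <- proteins[intersect(reps, names(proteins))]
    }
    list(n_clusters = length(reps),
         n_members = length(unique(df$member_id)),
         representatives = reps,
         membership = df,
         representative_seqs = repSeqs)
}
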