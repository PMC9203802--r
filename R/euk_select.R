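## Selection of contigs classified inside Eukaryota from per-sequence
## k-mer-classifier output (Kraken2 dialect: C/U, id, taxid, length, kmers).

#' Parse per-sequence classifier output
#'
#' Reads the five-column Kraken2-style per-sequence format.  Lines with
#' fewer than four tab-separated fields are skipped with a warning.
#'
#' @param path Path to the classifier output.
#' @return A data.frame with columns `classified` (logical), `seq_id`,
#'   `taxid` (integer; 0 for unclassified), `seq_len_bp` and `kmer_map`
#'   (the unparsed k-mer LCA string, `""` when absent).
#' @export
parseKrakenOutput <- function(path) {
    if (!file.exists(path)) stop("classifier output not found: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- lengths(fields) < 4L
    if (any(bad))
        warning("skipped ", sum(bad), " malformed classifier line(s) in ",
                path)
    fields <- fields[!bad]
    if (!length(fields))
        return(data.frame(classified = logical(0), seq_id = character(0),
                          taxid = integer(0), seq_len_bp = integer(0),
                          kmer_map = character(0), stringsAsFactors = FALSE))
    data.frame(
        classified = vapply(fields, `[[`, "", 1L) == "C",
        seq_id = vapply(fields, `[[`, "", 2L),
        taxid = as.integer(vapply(fields, `[[`, "", 3L)),
        seq_len_bp = as.integer(vapply(fields, `[[`, "", 4L)),
        kmer_map = vapply(fields, function(f)
            if (length(f) >= 5L) f[[5L]] else "", ""),
        stringsAsFactors = FALSE)
}

#' Select contigs classified inside Eukaryota
#'
#' A sequence is selected iff it is classified and its taxid is the
#' Eukaryota anchor or one of its descendants.  No classifier confidence
#' threshold is applied: the design is sensitive here and specific later,
#' at the protein level.  Taxids absent from the tree are warned about and
#' treated as non-eukaryotic.
#'
#' @param records Data.frame from [parseKrakenOutput()].
#' @param tree A [TaxonomyTree-class].
#' @param config A [PipelineConfig-class] (provides the Eukaryota anchor).
#' @return A list with `seq_ids` (character vector of selected ids) and
#'   `counts` (`n_records`, `n_classified`, `n_unclassified`,
#'   `n_eukaryotic`).
#' @export
selectEukaryotic <- function(records, tree, config = pipelineConfig()) {
    anchor <- config@superkingdomAnchors[["Eukaryota"]]
    cl <- records[records$classified & records$taxid > 0L, , drop = FALSE]
    uniq <- unique(cl$taxid)
    known <- uniq %in% taxIds(tree)
    if (any(!known))
        warning(sum(!known), " classified taxid(s) absent from taxonomy, ",
                "treated as non-eukaryotic")
    eukTaxid <- uniq[known][isDescendant(tree, uniq[known], anchor)]
    sel <- cl$seq_id[cl$taxid %in% eukTaxid]
    list(seq_ids = sel,
         counts = c(n_records = nrow(records),
                    n_classified = nrow(cl),
                    n_unclassified = nrow(records) - nrow(cl),
                    n_eukaryotic = length(sel)))
}
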