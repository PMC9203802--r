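.DEFAULT_ANCHORS <- c(Bacteria = 2L, Archaea = 2157L,
                      Eukaryota = 2759L, Viruses = 10239L)

#' Construct a pipeline configuration
#'
#' All arguments default to the published thresholds; see
#' [PipelineConfig-class] for their meaning and units.
#'
#' @param minContigLen Minimum contig length in bp.
#' @param minGeneCount Minimum initial gene-call count retaining a short
#'   contig.
#' @param evalueMax Homology-hit E-value cutoff.
#' @param scoreMargin Fractional bitscore margin from the best hit.
#' @param eukFractionMin Eukaryotic-protein fraction confirming a contig.
#' @param untraceableTaxids Taxids conveying no usable lineage.
#' @param orphanSubtypes Undetermined subtypes counted as orphans.
#' @param superkingdomAnchors Named anchor taxids (Bacteria, Archaea,
#'   Eukaryota, Viruses); override for synthetic mini-taxonomies.
#' @param clusterMinIdentity,clusterMinTargetCov Clustering thresholds the
#'   redundancy bookkeeping assumes.
#' @return A validated [PipelineConfig-class].
#' @examples
#' pipelineConfig()
#' pipelineConfig(eukFractionMin = 0.75)
#' @export
pipelineConfig <- function(minContigLen = 1000L,
                           minGeneCount = 3L,
                           evalueMax = 1e-6,
                           scoreMargin = 0.10,
                           eukFractionMin = 0.5,
                           untraceableTaxids = c(12908L, 32644L),
                           orphanSubtypes = c("no_hit", "untraceable"),
                           superkingdomAnchors = .DEFAULT_ANCHORS,
                           clusterMinIdentity = 0.99,
                           clusterMinTargetCov = 0.90) {
    new("PipelineConfig",
        minContigLen = as.integer(minContigLen),
        minGeneCount = as.integer(minGeneCount),
        evalueMax = as.numeric(evalueMax),
        scoreMargin = as.numeric(scoreMargin),
        eukFractionMin = as.numeric(eukFractionMin),
        untraceableTaxids = as.integer(untraceableTaxids),
        orphanSubtypes = as.character(orphanSubtypes),
        superkingdomAnchors = vapply(superkingdomAnchors, as.integer,
                                     integer(1)),
        clusterMinIdentity = as.numeric(clusterMinIdentity),
        clusterMinTargetCov = as.numeric(clusterMinTargetCov))
}

setMethod("show", "PipelineConfig", function(object) {
    cat("PipelineConfig\n")
    cat(sprintf("  contig QC       : >= %d bp OR >= %d genes\n",
                object@minContigLen, object@minGeneCount))
    cat(sprintf("  homology filter : E <= %g, bitscore >= %.2f x best\n",
                object@evalueMax, 1 - object@scoreMargin))
    cat(sprintf("  confirmation    : eukaryotic protein fraction >= %.2f\n",
                object@eukFractionMin))
    cat(sprintf("  untraceable     : %s (+ descendants)\n",
                paste(object@untraceableTaxids, collapse = ", ")))
    cat(sprintf("  orphan subtypes : %s\n",
                paste(object@orphanSubtypes, collapse = ", ")))
    cat(sprintf("  anchors         : %s\n",
                paste(names(object@superkingdomAnchors),
                      object@superkingdomAnchors,
                      sep = "=", collapse = ", ")))
    cat(sprintf("  clustering      : id >= %.2f, target cov >= %.2f\n",
                object@clusterMinIdentity, object@clusterMinTargetCov))
})

.CONFIG_KEYS <- c("min_contig_len_bp", "min_gene_count", "evalue_max",
                  "score_margin", "euk_fraction_min", "untraceable_taxids",
                  "orphan_subtypes", "superkingdom_anchors",
                  "cluster_min_identity", "cluster_min_target_cov")

#' Read a configuration file
#'
#' YAML key-value file; unspecified keys take the published defaults.  An
#' out-of-range value raises an error naming the offending key.
#'
#' @param path Path to a YAML file (an empty file yields all defaults).
#' @return A validated [PipelineConfig-class].
#' @seealso [writeConfig()]
#' @export
loadConfig <- function(path) {
    vals <- if (file.exists(path)) yaml::read_yaml(path) else
        stop("config file not found: ", path)
    if (is.null(vals)) vals <- list()
    unknown <- setdiff(names(vals), .CONFIG_KEYS)
    if (length(unknown))
        warning("ignoring unknown config key(s): ",
                paste(unknown, collapse = ", "))
    args <- list()
    pick <- function(key, arg) {
        if (!is.null(vals[[key]])) args[[arg]] <<- vals[[key]]
    }
    pick("min_contig_len_bp", "minContigLen")
    pick("min_gene_count", "minGeneCount")
    pick("evalue_max", "evalueMax")
    pick("score_margin", "scoreMargin")
    pick("euk_fraction_min", "eukFractionMin")
    pick("untraceable_taxids", "untraceableTaxids")
    pick("orphan_subtypes", "orphanSubtypes")
    pick("cluster_min_identity", "clusterMinIdentity")
    pick("cluster_min_target_cov", "clusterMinTargetCov")
    if (!is.null(vals$superkingdom_anchors))
        args$superkingdomAnchors <- unlist(vals$superkingdom_anchors)
    cfg <- try(do.call(pipelineConfig, args), silent = TRUE)
    if (inherits(cfg, "try-error"))
        stop("invalid configuration in ", path, ": ",
             attr(cfg, "condition")$message)
    cfg
}

#' Write a configuration file
#'
#' Serialises a [PipelineConfig-class] to YAML such that
#' `loadConfig(writeConfig(cfg, path))` round-trips.
#'
#' @param config A [PipelineConfig-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeConfig <- function(config, path) {
    yaml::write_yaml(list(
        min_contig_len_bp = config@minContigLen,
        min_gene_count = config@minGeneCount,
        evalue_max = config@evalueMax,
        score_margin = config@scoreMargin,
        euk_fraction_min = config@eukFractionMin,
        untraceable_taxids = config@untraceableTaxids,
        orphan_subtypes = config@orphanSubtypes,
        superkingdom_anchors = as.list(config@superkingdomAnchors),
        cluster_min_identity = config@clusterMinIdentity,
        cluster_min_target_cov = config@clusterMinTargetCov), path)
    invisible(path)
}
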