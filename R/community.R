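#' Construct a Zotu count table with sample metadata and taxonomy
#'
#' Container for denoised amplicon (zero-radius OTU) counts: a Zotu-by-
#' sample matrix of non-negative integer read counts, per-sample metadata
#' (soil, treatment, gradient fraction class), and a taxonomy map assigning
#' every Zotu to a marker gene and lineage/clade labels (e.g. NS-Alpha,
#' NT-Alpha, ComA.2.1, Nitrosospira).
#'
#' @param counts numeric matrix, rows Zotus, columns samples; rownames and
#'   colnames required.
#' @param samples data.frame with a `sample` column matching the count
#'   columns; typically also `soil`, `treatment` and `fraction_class`
#'   (one of "HF", "light", "bulk").
#' @param taxonomy data.frame with a `zotu` column covering every count
#'   row; remaining columns are taxonomy levels (e.g. `gene`, `clade`,
#'   `genus`).
#' @return An object of class `zotu_table`.
#' @export
zotu_table <- function(counts, samples, taxonomy) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts needs Zotu rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicate sample ids", call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  stopifnot(is.data.frame(samples), "sample" %in% names(samples),
            is.data.frame(taxonomy), "zotu" %in% names(taxonomy))
  if (!all(colnames(counts) %in% samples$sample)) {
    stop("samples metadata missing entries for: ",
         paste(setdiff(colnames(counts), samples$sample), collapse = ", "),
         call. = FALSE)
  }
  missing_tax <- setdiff(rownames(counts), taxonomy$zotu)
  if (length(missing_tax)) {
    stop("taxonomy missing for Zotu(s): ",
         paste(missing_tax, collapse = ", "), call. = FALSE)
  }
  structure(list(counts = counts, samples = samples, taxonomy = taxonomy),
            class = "zotu_table")
}

# pooled counts for a sample group, optionally rolled up a taxonomy level
pooled_counts <- function(table, group, level = "zotu") {
  stopifnot(inherits(table, "zotu_table"))
  group <- as.character(group)
  if (length(group) == 0) stop("empty sample group", call. = FALSE)
  if (!all(group %in% colnames(table$counts))) {
    stop("unknown sample(s): ",
         paste(setdiff(group, colnames(table$counts)), collapse = ", "),
         call. = FALSE)
  }
  pooled <- rowSums(table$counts[, group, drop = FALSE])
  if (level == "zotu") return(pooled)
  if (!level %in% names(table$taxonomy)) {
    stop("taxonomy has no level '", level, "'", call. = FALSE)
  }
  labels <- table$taxonomy[[level]][match(names(pooled), table$taxonomy$zotu)]
  tapply(pooled, labels, sum)
}

#' Relative abundance of taxa within a sample group
#'
#' Read counts are pooled (summed, not averaged) across the samples of the
#' group — preserving read-count semantics — and divided by the group
#' total, so proportions sum to 1.
#'
#' @param table a [zotu_table()].
#' @param group character vector of sample ids.
#' @param level `"zotu"` or a taxonomy column name to roll up to (e.g.
#'   `"genus"`, `"clade"`).
#' @return Named numeric vector of proportions summing to 1.
#' @export
relative_abundance <- function(table, group, level = "zotu") {
  pooled <- pooled_counts(table, group, level)
  total <- sum(pooled)
  if (total <= 0) stop("group has zero total counts", call. = FALSE)
  pooled / total
}

#' Clade composition of a sample group
#'
#' Percentage of group reads assigned to each clade (or any other taxonomy
#' level). All clades present in the taxonomy are reported, zero-count
#' clades as 0, and percentages sum to 100.
#'
#' @inheritParams relative_abundance
#' @param level taxonomy column to summarize at (default `"clade"`).
#' @return data.frame with columns `clade`, `reads`, `percent`, sorted by
#'   descending percent.
#' @export
clade_composition <- function(table, group, level = "clade") {
  pooled <- pooled_counts(table, group, level)
  all_clades <- sort(unique(table$taxonomy[[level]]))
  reads <- setNames(numeric(length(all_clades)), all_clades)
  reads[names(pooled)] <- pooled
  total <- sum(reads)
  if (total <= 0) stop("group has zero total counts", call. = FALSE)
  out <- data.frame(clade = names(reads), reads = as.numeric(reads),
                    percent = 100 * as.numeric(reads) / total)
  out <- out[order(-out$percent, out$clade), ]
  rownames(out) <- NULL
  out
}

#' Most abundant taxa in a sample group
#'
#' Taxa sorted by descending pooled relative abundance; ties are broken
#' lexicographically by taxon id so the ordering is deterministic. Returns
#' at most `n` taxa.
#'
#' @inheritParams relative_abundance
#' @param n number of taxa to return (>= 1).
#' @return data.frame with columns `taxon`, `reads`, `rel_abund`.
#' @export
top_n_taxa <- function(table, group, n = 10, level = "zotu") {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  pooled <- pooled_counts(table, group, level)
  total <- sum(pooled)
  if (total <= 0) stop("group has zero total counts", call. = FALSE)
  ord <- order(-pooled, names(pooled))
  keep <- ord[seq_len(min(n, length(pooled)))]
  data.frame(taxon = names(pooled)[keep], reads = as.numeric(pooled[keep]),
             rel_abund = as.numeric(pooled[keep]) / total)
}

#' Classify taxa as active/enriched in 15N heavy fractions
#'
#' Operationalizes "active" for SIP amplicon data: a taxon is *active* when
#' its relative abundance in the 15N heavy-fraction group reaches
#' `min_abund`, and additionally *enriched* when its HF relative abundance
#' is at least `fold` times its abundance in the reference group (typically
#' light fractions of the unlabeled control). A taxon absent from the
#' reference is enriched iff it is active.
#'
#' @param table a [zotu_table()].
#' @param hf_group sample ids of the 15N heavy-fraction group.
#' @param ref_group sample ids of the reference group.
#' @param min_abund minimum HF relative abundance to call a taxon active
#'   (default 0.01).
#' @param fold minimum HF/reference abundance ratio to call it enriched
#'   (default 2).
#' @param level taxonomy level of the classification (default `"zotu"`).
#' @return data.frame with columns `taxon`, `hf_abund`, `ref_abund`,
#'   `active`, `enriched`, sorted by descending `hf_abund`.
#' @export
active_taxa <- function(table, hf_group, ref_group, min_abund = 0.01,
                        fold = 2, level = "zotu") {
  hf <- relative_abundance(table, hf_group, level)
  ref <- relative_abundance(table, ref_group, level)
  taxa <- sort(union(names(hf), names(ref)))
  hf_ab <- setNames(numeric(length(taxa)), taxa)
  ref_ab <- hf_ab
  hf_ab[names(hf)] <- hf
  ref_ab[names(ref)] <- ref
  active <- hf_ab >= min_abund
  enriched <- active & ifelse(ref_ab == 0, TRUE, hf_ab >= fold * ref_ab)
  out <- data.frame(taxon = taxa, hf_abund = as.numeric(hf_ab),
                    ref_abund = as.numeric(ref_ab),
                    active = as.logical(active),
                    enriched = as.logical(enriched))
  out <- out[order(-out$hf_abund, out$taxon), ]
  rownames(out) <- NULL
  out
}

#' Validate a Zotu representative-sequence FASTA against a count table
#'
#' Checks id agreement only: every Zotu in the count table must have a
#' sequence, and duplicate FASTA ids are rejected. Sequences themselves are
#' not analyzed.
#'
#' @param path FASTA file of representative sequences.
#' @param table a [zotu_table()].
#' @return Invisibly, the `DNAStringSet` read from `path`.
#' @export
check_zotu_fasta <- function(path, table) {
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(rownames(table$counts), ids)
  if (length(missing)) {
    stop("FASTA missing sequence(s) for: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(seqs)
}
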