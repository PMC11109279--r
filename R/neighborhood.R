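#' Ten neighbor-gene group labels plus bookkeeping labels
#'
#' HeR anchors are classified by the product of their nearest co-transcribed
#' neighbor into ten frequent neighbor-gene groups; anchors with no
#' co-transcribed neighbor fall in \code{non_co_transcription}, and anchors
#' whose neighbors match no group keyword fall in \code{other}.
#'
#' @format Character vector of the twelve valid labels, in priority order.
#' @export
GROUP_LABELS <- c(
  "glutamine_synthetase", "nad_synthetase", "photolyase", "merR_regulator",
  "terC", "abc_transporter", "sdr_oxidoreductase", "ab_hydrolase",
  "duf2177", "duf2238", "non_co_transcription", "other"
)

#' Default keyword map for neighbor-gene group classification
#'
#' Maps case-insensitive regular expressions matched against neighbor product
#' annotations to group labels. The list order is the priority order used to
#' break ties when a product matches several groups.
#'
#' @return Named list: group label -> character vector of regexes.
#' @export
default_keyword_map <- function() {
  list(
    glutamine_synthetase = c("glutamine synthetase"),
    nad_synthetase       = c("NAD\\+? synth", "NAD synthetase"),
    photolyase           = c("photolyase", "deoxyribodipyrimidine"),
    merR_regulator       = c("MerR family", "MerR.*regulator"),
    terC                 = c("TerC"),
    abc_transporter      = c("ABC transporter", "ATP-binding cassette"),
    sdr_oxidoreductase   = c("SDR family", "short-chain dehydrogenase",
                             "NAD\\(P\\)-dependent oxidoreductase"),
    ab_hydrolase         = c("alpha/beta hydrolase", "alpha/beta fold hydrolase"),
    duf2177              = c("DUF2177"),
    duf2238              = c("DUF2238")
  )
}

new_gene_table <- function(df) {
  req <- c("gene_id", "contig", "start", "end", "strand", "product")
  missing <- setdiff(req, names(df))
  if (length(missing))
    stop("gene table missing columns: ", paste(missing, collapse = ", "))
  if (!"taxon_class" %in% names(df)) df$taxon_class <- NA_character_
  bad <- which(df$end < df$start)
  if (length(bad))
    stop("invalid coordinates (start > end) for feature(s): ",
         paste(df$gene_id[bad], collapse = ", "))
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene ids: ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  if (!all(df$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  df <- df[order(df$contig, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Load genome annotations and protein sequences
#'
#' Reads CDS features from a GFF3 file and matching protein sequences from a
#' FASTA file into a validated gene table. Features must carry an \code{ID}
#' attribute; \code{product} defaults to \code{""} when absent. Coordinates
#' are GFF3-native 1-based inclusive.
#'
#' @param gff3_file Path to a GFF3 annotation file.
#' @param fasta_file Optional path to a protein FASTA whose ids match GFF3 IDs.
#' @param feature_type GFF3 feature type to keep (default \code{"CDS"}).
#' @return List with \code{genes} (data.frame: gene_id, contig, start, end,
#'   strand, product, taxon_class), \code{proteins} (named \code{AAStringSet}
#'   or NULL), and \code{orphans} (FASTA ids without a matching feature).
#' @export
load_annotations <- function(gff3_file, fasta_file = NULL,
                             feature_type = "CDS") {
  if (!file.exists(gff3_file)) stop("GFF3 file not found: ", gff3_file)
  # validate coordinates up front so bad rows are reported by feature id
  raw <- readLines(gff3_file)
  body <- raw[!startsWith(raw, "#") & nzchar(raw)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  for (f in fields) {
    if (length(f) < 9) next
    if (suppressWarnings(as.numeric(f[5]) < as.numeric(f[4]))) {
      id <- sub(".*ID=([^;]+).*", "\\1", f[9])
      stop("invalid coordinates (start > end) for feature: ", id)
    }
  }
  gr <- rtracklayer::import(gff3_file, format = "gff3")
  df <- as.data.frame(gr)
  df <- df[df$type %in% feature_type, , drop = FALSE]
  if (!nrow(df)) stop("no ", feature_type, " features in ", gff3_file)
  product <- if ("product" %in% names(df)) as.character(df$product)
             else rep(NA_character_, nrow(df))
  product[is.na(product)] <- ""
  taxon <- if ("taxon_class" %in% names(df)) as.character(df$taxon_class)
           else rep(NA_character_, nrow(df))
  genes <- data.frame(
    gene_id = as.character(df$ID),
    contig = as.character(df$seqnames),
    start = as.integer(df$start),
    end = as.integer(df$end),
    strand = as.character(df$strand),
    product = product,
    taxon_class = taxon,
    stringsAsFactors = FALSE
  )
  genes <- new_gene_table(genes)
  proteins <- NULL
  orphans <- character(0)
  if (!is.null(fasta_file)) {
    if (!file.exists(fasta_file)) stop("FASTA file not found: ", fasta_file)
    proteins <- Biostrings::readAAStringSet(fasta_file)
    names(proteins) <- sub("\\s.*$", "", names(proteins))
    orphans <- setdiff(names(proteins), genes$gene_id)
    if (length(orphans))
      warning(length(orphans), " FASTA sequence(s) without a matching feature")
  }
  list(genes = genes, proteins = proteins, orphans = orphans)
}

#' Intergenic gap between two genes on the same contig
#'
#' Gap convention on 1-based inclusive coordinates:
#' \code{start(downstream) - end(upstream) - 1}, so abutting genes
#' (end + 1 == start) give 0 and overlapping genes give a negative gap.
#'
#' @param upstream,downstream Single-row gene records (lists or data.frame
#'   rows with \code{contig}, \code{start}, \code{end}).
#' @return Integer gap in bp (may be negative).
#' @export
intergenic_gap <- function(upstream, downstream) {
  if (!identical(as.character(upstream$contig),
                 as.character(downstream$contig)))
    stop("genes are on different contigs")
  if (upstream$start > downstream$start)
    stop("upstream gene must not start after downstream gene")
  as.integer(downstream$start - upstream$end - 1L)
}

karlin_evalue <- function(score, m, n, lambda = 0.267, K = 0.041) {
  bits <- (lambda * score - log(K)) / log(2)
  list(bit_score = bits, e_value = m * n * 2^(-bits))
}

#' Find anchor (HeR-like) genes
#'
#' Anchors are genes whose best homology hit against the reference passes both
#' an identity and an e-value threshold. Supply either a precomputed hit table
#' (BLAST tabular, 12-column outfmt-6 dialect) or a reference protein sequence,
#' in which case a built-in Smith-Waterman local alignment (BLOSUM62, affine
#' gaps) scores each protein; e-values then come from a Karlin-Altschul
#' estimate appropriate for desk-scale inputs.
#'
#' @param genes Gene table from [load_annotations()].
#' @param hits Optional data.frame of hits with columns \code{query_id},
#'   \code{subject_id}, \code{percent_identity}, \code{alignment_length},
#'   \code{bit_score}, \code{e_value} (extra columns ignored), or a path to a
#'   12-column BLAST tabular file.
#' @param reference_protein Optional \code{AAString}/character reference;
#'   requires \code{proteins}.
#' @param proteins Named \code{AAStringSet} of the genome's proteins.
#' @param min_identity Minimum percent identity (default 20).
#' @param max_e_value Maximum e-value (default 1e-5).
#' @return Gene table subset of anchors (possibly 0 rows), with columns
#'   \code{percent_identity} and \code{e_value} of the best hit appended.
#' @export
find_anchor_genes <- function(genes, hits = NULL, reference_protein = NULL,
                              proteins = NULL, min_identity = 20,
                              max_e_value = 1e-5) {
  if (is.null(hits) && is.null(reference_protein))
    stop("supply either a hit table or a reference protein")
  if (!nrow(genes)) {
    out <- genes
    out$percent_identity <- numeric(0)
    out$e_value <- numeric(0)
    return(out)
  }
  if (is.null(hits)) {
    if (is.null(proteins)) stop("reference_protein requires 'proteins'")
    ref <- Biostrings::AAString(as.character(reference_protein))
    aln <- Biostrings::pairwiseAlignment(
      proteins, ref, type = "local",
      substitutionMatrix = "BLOSUM62",
      gapOpening = 10, gapExtension = 0.5
    )
    ka <- karlin_evalue(Biostrings::score(aln),
                        m = length(ref),
                        n = sum(Biostrings::width(proteins)))
    hits <- data.frame(
      query_id = names(proteins),
      subject_id = "reference",
      percent_identity = Biostrings::pid(aln),
      alignment_length = Biostrings::nchar(aln),
      bit_score = ka$bit_score,
      e_value = ka$e_value,
      stringsAsFactors = FALSE
    )
  } else if (is.character(hits) && length(hits) == 1L) {
    hits <- utils::read.table(hits, sep = "\t", header = FALSE,
                              stringsAsFactors = FALSE)
    names(hits)[1:12] <- c("query_id", "subject_id", "percent_identity",
                           "alignment_length", "mismatches", "gap_opens",
                           "q_start", "q_end", "s_start", "s_end",
                           "e_value", "bit_score")
  }
  unknown <- setdiff(hits$query_id, genes$gene_id)
  if (length(unknown)) {
    warning("skipping hit(s) for unknown gene(s): ",
            paste(unknown, collapse = ", "))
    hits <- hits[!hits$query_id %in% unknown, , drop = FALSE]
  }
  if (!nrow(hits)) {
    out <- genes[0, , drop = FALSE]
    out$percent_identity <- numeric(0)
    out$e_value <- numeric(0)
    return(out)
  }
  # best hit per query = highest bit score
  hits <- hits[order(hits$query_id, -hits$bit_score), , drop = FALSE]
  best <- hits[!duplicated(hits$query_id), , drop = FALSE]
  pass <- best[best$percent_identity >= min_identity &
                 best$e_value <= max_e_value, , drop = FALSE]
  out <- genes[match(pass$query_id, genes$gene_id), , drop = FALSE]
  out$percent_identity <- pass$percent_identity
  out$e_value <- pass$e_value
  out <- out[order(out$contig, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the gene neighborhood around an anchor
#'
#' @param genes Gene table (one genome).
#' @param anchor_id Gene id of the anchor.
#' @param flank Number of genes to keep on each side (default 3).
#' @return A \code{neighborhood} list: \code{anchor} (1-row data.frame),
#'   \code{upstream} and \code{downstream} gene tables ordered away from the
#'   anchor, and empty \code{co_transcribed} until
#'   [predict_co_transcription()] is applied.
#' @export
neighborhood <- function(genes, anchor_id, flank = 3L) {
  i <- match(anchor_id, genes$gene_id)
  if (is.na(i)) stop("anchor '", anchor_id, "' not in gene table")
  anchor <- genes[i, , drop = FALSE]
  same <- genes[genes$contig == anchor$contig, , drop = FALSE]
  same <- same[order(same$start), , drop = FALSE]
  j <- match(anchor_id, same$gene_id)
  n_up <- min(flank, j - 1L)
  n_dn <- min(flank, nrow(same) - j)
  up_idx <- if (n_up > 0L) (j - 1L):(j - n_up) else integer(0)
  dn_idx <- if (n_dn > 0L) j + seq_len(n_dn) else integer(0)
  structure(list(
    anchor = anchor,
    upstream = same[up_idx, , drop = FALSE],     # nearest first
    downstream = same[dn_idx, , drop = FALSE],   # nearest first
    co_transcribed = NULL
  ), class = "neighborhood")
}

#' Predict co-transcription of neighbors with the anchor
#'
#' A neighbor chain is co-transcribed with the anchor iff every consecutive
#' link walking outward from the anchor has the same strand (when required)
#' and an intergenic gap inside the window; the chain breaks at the first
#' failing link, with no skipping. The default window (-20..30 bp) follows the
#' characteristic intergenic-distance peak of same-operon gene pairs.
#' External promoter calls, when given, override the heuristic per neighbor.
#'
#' @param unit A \code{neighborhood}.
#' @param gap_window Length-2 numeric \code{c(min_bp, max_bp)}.
#' @param require_same_strand Require neighbors to share the anchor strand.
#' @param promoter_calls Optional data.frame \code{(gene_id, co_transcribed)}
#'   of external calls overriding the heuristic for listed genes.
#' @return The \code{neighborhood} with \code{co_transcribed} filled: a
#'   data.frame of co-transcribed neighbors with their gap to the previous
#'   chain member and side (\code{upstream}/\code{downstream}).
#' @export
predict_co_transcription <- function(unit, gap_window = c(-20L, 30L),
                                     require_same_strand = TRUE,
                                     promoter_calls = NULL) {
  stopifnot(inherits(unit, "neighborhood"), length(gap_window) == 2L,
            gap_window[1] <= gap_window[2])
  anchor <- unit$anchor
  walk <- function(side) {
    nbrs <- unit[[side]]
    kept <- integer(0)
    gaps <- integer(0)
    prev <- anchor
    for (k in seq_len(nrow(nbrs))) {
      g <- nbrs[k, , drop = FALSE]
      gap <- if (side == "upstream") intergenic_gap(g, prev)
             else intergenic_gap(prev, g)
      ok <- NULL
      if (!is.null(promoter_calls) && g$gene_id %in% promoter_calls$gene_id)
        ok <- isTRUE(promoter_calls$co_transcribed[
          match(g$gene_id, promoter_calls$gene_id)])
      if (is.null(ok)) {
        ok <- gap >= gap_window[1] && gap <= gap_window[2]
        if (require_same_strand && g$strand != anchor$strand) ok <- FALSE
      }
      if (!ok) break
      kept <- c(kept, k)
      gaps <- c(gaps, gap)
      prev <- g
    }
    if (!length(kept)) return(NULL)
    out <- nbrs[kept, , drop = FALSE]
    out$gap <- gaps
    out$side <- side
    out
  }
  co <- rbind(walk("upstream"), walk("downstream"))
  if (is.null(co)) {
    co <- unit$anchor[0, , drop = FALSE]
    co$gap <- integer(0)
    co$side <- character(0)
  }
  rownames(co) <- NULL
  unit$co_transcribed <- co
  unit
}

#' Classify an anchor into a neighbor-gene group
#'
#' Anchors with no co-transcribed neighbor get \code{non_co_transcription}.
#' Otherwise co-transcribed neighbors are scanned nearest-first; the first
#' neighbor whose product matches a keyword determines the label. Products
#' matching several groups resolve by the keyword map's fixed priority order.
#' Unmatched products give \code{other}.
#'
#' @param unit A \code{neighborhood} after [predict_co_transcription()].
#' @param keyword_map Named list of regexes per group; see
#'   [default_keyword_map()].
#' @return Single group label (character).
#' @export
classify_neighbor_group <- function(unit, keyword_map = default_keyword_map()) {
  stopifnot(inherits(unit, "neighborhood"))
  co <- unit$co_transcribed
  if (is.null(co))
    stop("run predict_co_transcription() before classification")
  if (!nrow(co)) return("non_co_transcription")
  # nearest-first within each side, upstream before downstream ties are
  # irrelevant because the first keyword match wins per neighbor scan order
  co <- co[order(abs(co$gap)), , drop = FALSE]
  for (k in seq_len(nrow(co))) {
    prod <- co$product[k]
    for (lab in names(keyword_map)) {
      if (any(vapply(keyword_map[[lab]],
                     function(rx) grepl(rx, prod, ignore.case = TRUE),
                     logical(1))))
        return(lab)
    }
  }
  "other"
}

#' Classify every anchor in a cohort
#'
#' @param units List of \code{neighborhood} objects (co-transcription already
#'   predicted or predicted here with the given window).
#' @param keyword_map Keyword map; see [default_keyword_map()].
#' @param gap_window,require_same_strand Passed to
#'   [predict_co_transcription()] for units not yet predicted.
#' @return data.frame: anchor_id, contig, taxon_class, group,
#'   co_transcribed_ids (comma-joined), gaps (comma-joined).
#' @export
classify_cohort <- function(units, keyword_map = default_keyword_map(),
                            gap_window = c(-20L, 30L),
                            require_same_strand = TRUE) {
  rows <- lapply(units, function(u) {
    if (is.null(u$co_transcribed))
      u <- predict_co_transcription(u, gap_window, require_same_strand)
    data.frame(
      anchor_id = u$anchor$gene_id,
      contig = u$anchor$contig,
      taxon_class = u$anchor$taxon_class,
      group = classify_neighbor_group(u, keyword_map),
      co_transcribed_ids = paste(u$co_transcribed$gene_id, collapse = ","),
      gaps = paste(u$co_transcribed$gap, collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize a classified anchor cohort
#'
#' The co-transcription fraction is the number of anchors with at least one
#' co-transcribed adjacent gene over all anchors; per-taxon fractions use the
#' same total-anchor denominator, so they sum to the overall fraction.
#'
#' @param classified data.frame from [classify_cohort()].
#' @param frequent_groups Labels counted as "frequent neighbor" groups
#'   (default: the ten named groups, i.e. everything except
#'   \code{non_co_transcription} and \code{other}).
#' @return \code{cohort_summary} list: n_total_anchors, n_with_adjacent,
#'   n_frequent_neighbor, fraction_co_transcribed, per_taxon_fraction,
#'   per_group_count.
#' @export
summarize_cohort <- function(classified,
                             frequent_groups = setdiff(
                               GROUP_LABELS,
                               c("non_co_transcription", "other"))) {
  if (!nrow(classified)) stop("no anchors to summarize")
  n <- nrow(classified)
  with_adj <- classified$group != "non_co_transcription"
  per_group <- table(factor(classified$group, levels = GROUP_LABELS))
  taxa <- classified$taxon_class[with_adj]
  taxa <- taxa[!is.na(taxa)]
  per_taxon <- if (length(taxa)) as.list(table(taxa) / n) else list()
  structure(list(
    n_total_anchors = n,
    n_with_adjacent = sum(with_adj),
    n_frequent_neighbor = sum(classified$group %in% frequent_groups),
    fraction_co_transcribed = sum(with_adj) / n,
    per_taxon_fraction = lapply(per_taxon, as.numeric),
    per_group_count = as.list(as.integer(per_group)) |>
      stats::setNames(names(per_group))
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Anchor cohort summary\n")
  cat(sprintf("  anchors: %d  with adjacent gene: %d (%.1f%%)  frequent-neighbor: %d\n",
              x$n_total_anchors, x$n_with_adjacent,
              100 * x$fraction_co_transcribed, x$n_frequent_neighbor))
  counts <- unlist(x$per_group_count)
  counts <- counts[counts > 0]
  for (g in names(counts)) cat(sprintf("  %-22s %d\n", g, counts[g]))
  invisible(x)
}
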