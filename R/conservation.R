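AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

#' Read a labeled alignment
#'
#' @param aln_file Aligned FASTA (protein, gaps as \code{-}).
#' @param groups_file Optional TSV with columns \code{id}, \code{group}.
#' @param reference_id Row id of the ungapped-numbering reference (e.g. the
#'   OcHeR row).
#' @return \code{labeled_alignment} list: \code{mat} (character matrix, rows =
#'   sequences), \code{group} (named character), \code{reference_id}.
#' @export
read_labeled_alignment <- function(aln_file, groups_file = NULL,
                                   reference_id) {
  aa <- Biostrings::readAAStringSet(aln_file)
  names(aa) <- sub("\\s.*$", "", names(aa))
  labeled_alignment(as.character(aa),
                    group = if (!is.null(groups_file)) {
                      g <- utils::read.table(groups_file, sep = "\t",
                                             header = TRUE,
                                             stringsAsFactors = FALSE)
                      stats::setNames(g$group, g$id)
                    },
                    reference_id = reference_id)
}

#' Construct a labeled alignment from named gapped strings
#'
#' @param seqs Named character vector of equal-length gapped sequences.
#' @param group Named character vector id -> group label (optional).
#' @param reference_id Reference row id; must be present.
#' @return \code{labeled_alignment}.
#' @export
labeled_alignment <- function(seqs, group = NULL, reference_id) {
  if (length(unique(nchar(seqs))) != 1L)
    stop("alignment rows differ in length")
  if (!reference_id %in% names(seqs))
    stop("reference row '", reference_id, "' absent from alignment")
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(mat) <- names(seqs)
  structure(list(mat = mat, group = group, reference_id = reference_id),
            class = "labeled_alignment")
}

#' Map reference residue numbers to alignment columns
#'
#' Columns where the reference row carries a gap are unmapped and excluded
#' from every downstream profile.
#'
#' @param aln \code{labeled_alignment}.
#' @return Integer vector: element i = alignment column (1-based) of
#'   reference residue i.
#' @export
map_columns_to_reference <- function(aln) {
  stopifnot(inherits(aln, "labeled_alignment"))
  ref <- aln$mat[aln$reference_id, ]
  which(ref != "-")
}

#' Per-reference-position amino-acid frequency profile of a group
#'
#' Frequencies are "per HeR": counts at each mapped column divided by the full
#' group size, so gapped sequences dilute residue frequencies and accrue to
#' \code{na_fraction} (the "not aligned" share). Set
#' \code{denominator = "ungapped"} to divide by the number of non-gap
#' sequences at each position instead.
#'
#' @param aln \code{labeled_alignment}.
#' @param ids Sequence ids of the group; defaults to all rows. Alternatively
#'   give \code{group_label} to select by the alignment's group labels.
#' @param group_label Optional group label used with \code{aln$group}.
#' @param reference_map From [map_columns_to_reference()]; computed if NULL.
#' @param denominator \code{"all"} (default, per-HeR) or \code{"ungapped"}.
#' @return \code{frequency_profile}: \code{freq} (20 x P matrix, rows = amino
#'   acids, columns = reference positions), \code{na_fraction} (length P),
#'   \code{n_sequences}, \code{group}.
#' @export
frequency_per_her <- function(aln, ids = NULL, group_label = NULL,
                              reference_map = NULL,
                              denominator = c("all", "ungapped")) {
  stopifnot(inherits(aln, "labeled_alignment"))
  denominator <- match.arg(denominator)
  if (is.null(ids)) {
    ids <- if (!is.null(group_label)) {
      if (is.null(aln$group)) stop("alignment has no group labels")
      names(aln$group)[aln$group == group_label]
    } else rownames(aln$mat)
  }
  ids <- intersect(ids, rownames(aln$mat))
  if (!length(ids)) stop("empty sequence group")
  cols <- if (is.null(reference_map)) map_columns_to_reference(aln)
          else reference_map
  sub <- aln$mat[ids, cols, drop = FALSE]
  n <- length(ids)
  counts <- vapply(seq_along(cols), function(j)
    tabulate(factor(sub[, j], levels = AA20), nbins = 20L),
    integer(20L))
  gaps <- colSums(sub == "-")
  denom <- if (denominator == "all") rep(n, length(cols)) else pmax(n - gaps, 1L)
  freq <- sweep(counts, 2L, denom, "/")
  rownames(freq) <- AA20
  colnames(freq) <- seq_along(cols)
  structure(list(
    freq = freq,
    na_fraction = if (denominator == "all") gaps / n else rep(0, length(cols)),
    n_sequences = n,
    group = if (!is.null(group_label)) group_label else NA_character_
  ), class = "frequency_profile")
}

#' Differential residue frequencies of a group against a background
#'
#' Computes group minus background frequency per (position, amino acid) and
#' flags entries whose difference strictly exceeds the threshold: enrichment
#' when \code{delta > theta}, depletion when \code{delta < -theta}; a
#' difference equal to the threshold is not flagged.
#'
#' @param group_profile,background_profile \code{frequency_profile}s over the
#'   same reference positions (typically group vs the non-co-transcription
#'   background).
#' @param theta Flagging threshold (default 0.19).
#' @return \code{differential_profile}: \code{delta} (20 x P), \code{flags_up}
#'   and \code{flags_down} (data.frames position/aa/delta), \code{theta}.
#' @export
differential_frequency <- function(group_profile, background_profile,
                                   theta = 0.19) {
  stopifnot(inherits(group_profile, "frequency_profile"),
            inherits(background_profile, "frequency_profile"))
  if (!identical(dim(group_profile$freq), dim(background_profile$freq)))
    stop("profiles cover different reference position sets")
  delta <- group_profile$freq - background_profile$freq
  pick <- function(mask) {
    idx <- which(mask, arr.ind = TRUE)
    data.frame(position = as.integer(colnames(delta)[idx[, 2]]),
               aa = rownames(delta)[idx[, 1]],
               delta = delta[idx],
               stringsAsFactors = FALSE)
  }
  structure(list(
    delta = delta,
    flags_up = pick(delta > theta),
    flags_down = pick(delta < -theta),
    theta = theta
  ), class = "differential_profile")
}

#' Default amino-acid class map
#'
#' Conventional chemistry classes: hydroxylic \{S,T,Y\}, aliphatic
#' \{A,V,L,I,G\}, aromatic \{F,W,Y,H\}, acidic \{D,E\}, basic \{K,R,H\}.
#' Y and H belong to two display classes; [aggregate_classes()] enforces a
#' disjoint effective partition using this list's priority order (first class
#' listing a residue keeps it).
#'
#' @return Named list class -> residues.
#' @export
default_class_map <- function() {
  list(hydroxylic = c("S", "T", "Y"),
       aliphatic = c("A", "V", "L", "I", "G"),
       aromatic = c("F", "W", "Y", "H"),
       acidic = c("D", "E"),
       basic = c("K", "R", "H"))
}

#' Aggregate a frequency profile into amino-acid classes
#'
#' @param profile \code{frequency_profile}.
#' @param class_map Named list class -> residues. Must be disjoint unless
#'   \code{resolve_overlaps} is TRUE, in which case the first class listing a
#'   residue keeps it (priority = list order).
#' @param resolve_overlaps Resolve doubly-listed residues by priority order
#'   instead of erroring (default FALSE).
#' @return Matrix classes x positions of summed member frequencies.
#' @export
aggregate_classes <- function(profile, class_map = default_class_map(),
                              resolve_overlaps = FALSE) {
  stopifnot(inherits(profile, "frequency_profile"))
  all_members <- unlist(class_map, use.names = FALSE)
  if (anyDuplicated(all_members)) {
    if (!resolve_overlaps)
      stop("amino acid(s) in two classes: ",
           paste(unique(all_members[duplicated(all_members)]), collapse = ", "),
           " (set resolve_overlaps = TRUE to use priority order)")
    seen <- character(0)
    class_map <- lapply(class_map, function(m) {
      keep <- setdiff(m, seen)
      seen <<- c(seen, keep)
      keep
    })
  }
  P <- ncol(profile$freq)
  vals <- vapply(class_map, function(members) {
    if (!length(members)) return(rep(0, P))
    colSums(profile$freq[members, , drop = FALSE])
  }, numeric(P))
  out <- t(matrix(vals, nrow = P, ncol = length(class_map)))
  dimnames(out) <- list(names(class_map), colnames(profile$freq))
  out
}

#' Default intracellular-loop topology markers
#'
#' Reference (OcHeR) residue positions of the charged/aromatic ICL markers:
#' 102, 104, 105 in ICL1; 166, 167, 170 in ICL2; 225, 229, 233, 235, 236 in
#' ICL3. Full loop boundaries are user-supplied; markers suffice for the
#' conservation ranking.
#'
#' @return Named list region -> integer positions.
#' @export
default_topology_map <- function() {
  list(ICL1 = c(102L, 104L, 105L),
       ICL2 = c(166L, 167L, 170L),
       ICL3 = c(225L, 229L, 233L, 235L, 236L))
}

#' Charged-residue conservation by membrane-topology region
#'
#' Positive charge frequency is the summed K+R frequency per position (H
#' optionally included); negative is D+E. Within each region, positions are
#' ranked by each charge frequency and positions at or above the conservation
#' cutoff are reported as highly conserved.
#'
#' @param profile \code{frequency_profile}.
#' @param topology_map Named list region -> reference positions; see
#'   [default_topology_map()].
#' @param include_H Count histidine as positive (default FALSE).
#' @param conserved_cutoff Frequency cutoff for "highly conserved"
#'   (default 0.5).
#' @return \code{charge_summary}: \code{per_position} data.frame (position,
#'   region, positive_freq, negative_freq) and \code{per_region} list of
#'   rankings with conserved flags.
#' @export
charge_conservation_by_region <- function(profile,
                                          topology_map = default_topology_map(),
                                          include_H = FALSE,
                                          conserved_cutoff = 0.5) {
  stopifnot(inherits(profile, "frequency_profile"))
  pos_set <- c("K", "R", if (include_H) "H")
  positions <- as.integer(colnames(profile$freq))
  pos_freq <- colSums(profile$freq[pos_set, , drop = FALSE])
  neg_freq <- colSums(profile$freq[c("D", "E"), , drop = FALSE])
  region <- rep("other", length(positions))
  for (r in names(topology_map))
    region[positions %in% topology_map[[r]]] <- r
  per_position <- data.frame(position = positions, region = region,
                             positive_freq = as.numeric(pos_freq),
                             negative_freq = as.numeric(neg_freq))
  per_region <- lapply(names(topology_map), function(r) {
    d <- per_position[per_position$region == r, , drop = FALSE]
    d <- d[order(-pmax(d$positive_freq, d$negative_freq)), , drop = FALSE]
    d$conserved <- pmax(d$positive_freq, d$negative_freq) >= conserved_cutoff
    rownames(d) <- NULL
    d
  })
  names(per_region) <- names(topology_map)
  structure(list(per_position = per_position, per_region = per_region,
                 include_H = include_H, conserved_cutoff = conserved_cutoff),
            class = "charge_summary")
}
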