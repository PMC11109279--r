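group_product_strings <- function() {
  c(glutamine_synthetase = "glutamine synthetase",
    nad_synthetase = "NAD+ synthetase",
    photolyase = "deoxyribodipyrimidine photolyase",
    merR_regulator = "MerR family transcriptional regulator",
    terC = "TerC family protein",
    abc_transporter = "ABC transporter ATP-binding protein",
    sdr_oxidoreductase = "SDR family NAD(P)-dependent oxidoreductase",
    ab_hydrolase = "alpha/beta hydrolase",
    duf2177 = "DUF2177 family protein",
    duf2238 = "DUF2238 domain-containing protein")
}

random_protein <- function(n, len = 120) {
  vapply(seq_len(n), function(i)
    paste(sample(AA20, len, replace = TRUE), collapse = ""), character(1))
}

#' Generate a synthetic genome cohort with planted operon structure
#'
#' Builds one contig per genome, each carrying a planted HeR anchor gene and a
#' downstream neighbor. Co-transcribed anchors get a same-strand neighbor with
#' an intergenic gap drawn strictly inside the co-transcription window and a
#' product from the ten-group mixture; the rest get a neighbor with a gap
#' strictly outside the window (product "hypothetical protein"), so the
#' planted classification truth is unambiguous at default settings. A hit
#' table marks the anchors. Identical seed and config give identical output.
#'
#' @param n_genomes Number of genomes/anchors.
#' @param co_rate Fraction of anchors planted as co-transcribed; the planted
#'   count is \code{round(co_rate * n_genomes)}.
#' @param seed RNG seed.
#' @param gap_window Co-transcription window for inside gaps
#'   (default c(-20, 30)).
#' @param outside_gap Range of gaps for non-co-transcribed neighbors
#'   (default c(100, 500); must lie outside \code{gap_window}).
#' @param group_mixture Named probabilities over the ten groups for
#'   co-transcribed anchors (must sum to 1).
#' @param taxon_labels Optional explicit taxon label per genome; default
#'   samples from a fixed prokaryote-heavy mixture.
#' @param co_flags Optional logical vector overriding which anchors are
#'   planted co-transcribed (length \code{n_genomes}).
#' @param out_dir Optional directory; when given, writes \code{cohort.gff3},
#'   \code{cohort.faa}, \code{hits.tsv}, \code{truth.tsv}.
#' @return List: \code{genes} (cohort gene table), \code{hits} (anchor hit
#'   table), \code{proteins} (named character), \code{truth} (data.frame:
#'   anchor_id, contig, co_transcribed, group, taxon_class, gap), and
#'   \code{files} when written.
#' @export
generate_genome_cohort <- function(n_genomes, co_rate, seed = 1L,
                                   gap_window = c(-20L, 30L),
                                   outside_gap = c(100L, 500L),
                                   group_mixture = NULL,
                                   taxon_labels = NULL,
                                   co_flags = NULL,
                                   out_dir = NULL) {
  stopifnot(n_genomes >= 1, co_rate >= 0, co_rate <= 1)
  if (outside_gap[1] <= gap_window[2] && outside_gap[2] >= gap_window[1])
    stop("outside_gap must not overlap gap_window")
  groups10 <- setdiff(GROUP_LABELS, c("non_co_transcription", "other"))
  if (is.null(group_mixture))
    group_mixture <- stats::setNames(rep(1 / 10, 10), groups10)
  if (abs(sum(group_mixture) - 1) > 1e-8)
    stop("group_mixture probabilities must sum to 1")
  set.seed(seed)
  n_co <- round(co_rate * n_genomes)
  if (is.null(co_flags)) {
    co_flags <- rep(FALSE, n_genomes)
    co_flags[sample.int(n_genomes, n_co)] <- TRUE
  }
  if (is.null(taxon_labels)) {
    taxon_labels <- sample(
      c("Actinobacteria", "Archaea", "Chloroflexota", "Baciliota", "Viruses",
        "Unsorted"),
      n_genomes, replace = TRUE,
      prob = c(0.45, 0.15, 0.12, 0.12, 0.06, 0.10))
  }
  prods <- group_product_strings()
  rows <- vector("list", n_genomes)
  truth <- vector("list", n_genomes)
  for (i in seq_len(n_genomes)) {
    ctg <- sprintf("ctg%04d", i)
    strand <- sample(c("+", "-"), 1)
    a_start <- 1001L; a_end <- 1900L
    if (co_flags[i]) {
      grp <- sample(names(group_mixture), 1, prob = group_mixture)
      gap <- sample(gap_window[1]:gap_window[2], 1)
      nb_strand <- strand
      nb_prod <- prods[[grp]]
    } else {
      grp <- "non_co_transcription"
      gap <- sample(outside_gap[1]:outside_gap[2], 1)
      nb_strand <- sample(c("+", "-"), 1)
      nb_prod <- "hypothetical protein"
    }
    nb_start <- a_end + gap + 1L
    nb_end <- nb_start + 599L
    aid <- sprintf("anchor_%04d", i)
    nid <- sprintf("nbr_%04d", i)
    rows[[i]] <- data.frame(
      gene_id = c(aid, nid), contig = ctg,
      start = c(a_start, nb_start), end = c(a_end, nb_end),
      strand = c(strand, nb_strand),
      product = c("heliorhodopsin", nb_prod),
      taxon_class = taxon_labels[i],
      stringsAsFactors = FALSE)
    truth[[i]] <- data.frame(
      anchor_id = aid, contig = ctg, co_transcribed = co_flags[i],
      group = grp, taxon_class = taxon_labels[i], gap = gap,
      stringsAsFactors = FALSE)
  }
  genes <- new_gene_table(do.call(rbind, rows))
  truth <- do.call(rbind, truth)
  anchors <- truth$anchor_id
  hits <- data.frame(
    query_id = anchors, subject_id = "HeR_reference",
    percent_identity = round(stats::runif(length(anchors), 60, 95), 1),
    alignment_length = 290L, mismatches = 30L, gap_opens = 2L,
    q_start = 1L, q_end = 290L, s_start = 1L, s_end = 290L,
    e_value = 1e-50, bit_score = 400,
    stringsAsFactors = FALSE)
  proteins <- stats::setNames(random_protein(nrow(genes)), genes$gene_id)
  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- list(
      gff3 = file.path(out_dir, "cohort.gff3"),
      faa = file.path(out_dir, "cohort.faa"),
      hits = file.path(out_dir, "hits.tsv"),
      truth = file.path(out_dir, "truth.tsv"))
    write_gff3(genes, files$gff3)
    writeLines(paste0(">", names(proteins), "\n", proteins), files$faa)
    utils::write.table(hits, files$hits, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    utils::write.table(truth, files$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  list(genes = genes, hits = hits, proteins = proteins, truth = truth,
       files = files)
}

# Minimal deterministic GFF3 writer for the synthetic cohorts (attribute
# values here never need percent-encoding).
write_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\theliomod\tCDS\t%d\t%d\t.\t%s\t0\tID=%s;product=%s;taxon_class=%s",
                     genes$contig, genes$start, genes$end, genes$strand,
                     genes$gene_id, genes$product, genes$taxon_class))
  writeLines(lines, path)
  invisible(path)
}

#' Generate a labeled alignment with planted residue enrichment
#'
#' Background columns draw residues from a per-column composition (symmetric
#' Dirichlet); at each planted (group, position, residue) the target group's
#' probability of the planted residue is raised by exactly \code{delta}
#' (other residues rescaled), so the expected group-minus-background
#' frequency difference equals \code{delta}. The reference row is ungapped.
#'
#' @param n_per_group Named integer vector: group label -> number of
#'   sequences. Must include the \code{"non_co_transcription"} background
#'   when differential profiles are wanted.
#' @param L Reference/alignment length (default 260).
#' @param enrichment data.frame with columns \code{group}, \code{position},
#'   \code{aa}, \code{delta}; may be empty.
#' @param gap_rate Per-cell gap probability for non-reference rows
#'   (default 0).
#' @param seed RNG seed.
#' @param concentration Dirichlet concentration of background compositions
#'   (default 0.5, moderately peaked columns).
#' @return \code{labeled_alignment} with an extra \code{truth} attribute
#'   (the enrichment table).
#' @export
generate_labeled_alignment <- function(n_per_group, L = 260L,
                                       enrichment = NULL, gap_rate = 0,
                                       seed = 1L, concentration = 0.5) {
  set.seed(seed)
  if (is.null(enrichment))
    enrichment <- data.frame(group = character(0), position = integer(0),
                             aa = character(0), delta = numeric(0))
  if (nrow(enrichment) && any(enrichment$position > L))
    stop("enrichment positions exceed reference length")
  # per-column background composition
  comp <- vapply(seq_len(L), function(j) {
    g <- stats::rgamma(20, concentration)
    g / sum(g)
  }, numeric(20))
  rownames(comp) <- AA20
  for (k in seq_len(nrow(enrichment)))
    if (comp[enrichment$aa[k], enrichment$position[k]] +
        enrichment$delta[k] > 1)
      stop("planted delta pushes a frequency above 1 at position ",
           enrichment$position[k])
  ref <- vapply(seq_len(L), function(j)
    sample(AA20, 1, prob = comp[, j]), character(1))
  seqs <- character(0)
  grp <- character(0)
  for (g in names(n_per_group)) {
    ng <- n_per_group[[g]]
    if (ng < 1) next
    pg <- comp
    e <- enrichment[enrichment$group == g, , drop = FALSE]
    for (k in seq_len(nrow(e))) {
      j <- e$position[k]; aa <- e$aa[k]; d <- e$delta[k]
      p <- pg[, j]
      target <- p[aa] + d
      p[setdiff(AA20, aa)] <- p[setdiff(AA20, aa)] *
        (1 - target) / (1 - p[aa])
      p[aa] <- target
      pg[, j] <- p
    }
    m <- vapply(seq_len(L), function(j)
      sample(AA20, ng, replace = TRUE, prob = pg[, j]), character(ng))
    if (ng == 1L) m <- matrix(m, nrow = 1L)
    if (gap_rate > 0)
      m[stats::runif(length(m)) < gap_rate] <- "-"
    rows <- apply(m, 1, paste, collapse = "")
    ids <- sprintf("%s_%04d", g, seq_len(ng))
    seqs <- c(seqs, stats::setNames(rows, ids))
    grp <- c(grp, stats::setNames(rep(g, ng), ids))
  }
  seqs <- c(stats::setNames(paste(ref, collapse = ""), "OcHeR"), seqs)
  aln <- labeled_alignment(seqs, group = grp, reference_id = "OcHeR")
  attr(aln, "truth") <- enrichment
  aln
}

#' Write a labeled alignment to aligned FASTA + group TSV
#'
#' @param aln \code{labeled_alignment}.
#' @param aln_file,groups_file Output paths.
#' @return Invisibly, the two paths.
#' @export
write_labeled_alignment <- function(aln, aln_file, groups_file) {
  rows <- apply(aln$mat, 1, paste, collapse = "")
  writeLines(paste0(">", names(rows), "\n", rows), aln_file)
  utils::write.table(
    data.frame(id = names(aln$group), group = unname(aln$group)),
    groups_file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(aln_file, groups_file))
}

#' Generate a synthetic ITC titration
#'
#' Model heats (one-site or sequential) plus i.i.d. Gaussian noise. Defaults
#' emulate a small-cell calorimeter run: 200 uL cell, 20 x 2 uL injections.
#'
#' @param params True model parameters (see [one_site_heat_curve()] /
#'   [sequential_heat_curve()]).
#' @param model \code{"one_site"} or \code{"sequential"}.
#' @param n_injections Number of injections (default 20).
#' @param V0 Cell volume (L, default 2.0e-4).
#' @param inj_vol Per-injection volume (L, default 2e-6).
#' @param Mt0 Cell concentration (M, default 5e-4).
#' @param X_syr Syringe concentration (M, default 8e-3).
#' @param noise_sd Noise standard deviation in microcal; a value in (0, 1) is
#'   interpreted as a fraction of the largest model heat. Must be >= 0.
#' @param temperature Kelvin (default 298.15).
#' @param seed RNG seed.
#' @return \code{titration_experiment} with observed heats and a
#'   \code{truth} attribute (true params + noiseless curve).
#' @export
generate_itc <- function(params, model = c("one_site", "sequential"),
                         n_injections = 20L, V0 = 2.0e-4, inj_vol = 2e-6,
                         Mt0 = 5e-4, X_syr = 8e-3, noise_sd = 0,
                         temperature = 298.15, seed = 1L) {
  model <- match.arg(model)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  expt <- titration_experiment(V0, Mt0, X_syr,
                               rep(inj_vol, n_injections),
                               temperature = temperature)
  clean <- if (model == "one_site") one_site_heat_curve(params, expt)
           else sequential_heat_curve(params, expt)
  sd_abs <- if (noise_sd > 0 && noise_sd < 1) noise_sd * max(abs(clean))
            else noise_sd
  set.seed(seed)
  expt$observed_heats <- clean + stats::rnorm(n_injections, 0, sd_abs)
  attr(expt, "truth") <- list(model = model, params = params, clean = clean)
  expt
}

#' Generate synthetic kinetic / dose-response / decay / pH datasets
#'
#' @param type One of \code{"mm"}, \code{"dose_response"}, \code{"decay"},
#'   \code{"pka"}.
#' @param params True parameters: mm (Vmax, Km), dose_response (A1, A2,
#'   Logx0, p), decay (y0, A1, t1), pka (S_acid, S_base, pKa).
#' @param design Predictor values; defaults per type (mm: 8 ATP levels in mM;
#'   dose_response: 9 log10 concentrations around Logx0; decay: 50 times over
#'   ~5 t1; pka: 10 pH points around pKa).
#' @param noise_sd Gaussian noise SD; a value in (0, 1) is a fraction of the
#'   response range. Must be >= 0.
#' @param seed RNG seed.
#' @return data.frame with predictor and response columns and a \code{truth}
#'   attribute.
#' @export
generate_kinetics <- function(type = c("mm", "dose_response", "decay", "pka"),
                              params, design = NULL, noise_sd = 0,
                              seed = 1L) {
  type <- match.arg(type)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  p <- as.list(params)
  if (is.null(design)) {
    design <- switch(type,
      mm = c(1, 2.5, 5, 10, 20, 40, 80, 160),
      dose_response = p$Logx0 + seq(-2, 2, by = 0.5),
      decay = seq(0, 5 * p$t1, length.out = 50),
      pka = p$pKa + seq(-2.25, 2.25, by = 0.5))
  }
  clean <- switch(type,
    mm = mm_rate(design, p$Vmax, p$Km),
    dose_response = dose_response(design, p$A1, p$A2, p$Logx0, p$p),
    decay = exp_decay(design, p$y0, p$A1, p$t1),
    pka = p$S_acid + (p$S_base - p$S_acid) / (1 + 10^(p$pKa - design)))
  sd_abs <- if (noise_sd > 0 && noise_sd < 1)
    noise_sd * diff(range(clean)) else noise_sd
  set.seed(seed)
  y <- clean + stats::rnorm(length(clean), 0, sd_abs)
  out <- switch(type,
    mm = data.frame(S = design, v = y),
    dose_response = data.frame(x = design, y = y),
    decay = data.frame(t = design, y = y),
    pka = data.frame(pH = design, signal = y))
  attr(out, "truth") <- list(type = type, params = p, clean = clean)
  out
}
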