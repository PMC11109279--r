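gene_row <- function(id, start, end, strand = "+", contig = "ctg1",
                     product = "", taxon = "Actinobacteria") {
  data.frame(gene_id = id, contig = contig, start = start, end = end,
             strand = strand, product = product, taxon_class = taxon,
             stringsAsFactors = FALSE)
}

toy_gff3 <- function(path, rows) {
  writeLines(c("##gff-version 3", rows), path)
  path
}

# one anchor + one neighbor at a chosen gap/strand, classified end to end
toy_unit <- function(gap, nb_strand = "+", product = "glutamine synthetase") {
  genes <- rbind(
    gene_row("anchor", 1001, 1900, product = "heliorhodopsin"),
    gene_row("nbr", 1900 + gap + 1, 1900 + gap + 600, strand = nb_strand,
             product = product))
  neighborhood(genes, "anchor")
}
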