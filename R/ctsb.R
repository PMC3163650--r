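#' Synthetic cathepsin B (Ctsb) gene model
#'
#' A synthetic single-locus model of the mouse Ctsb gene used throughout
#' the package's worked examples and tests. Only its published summary
#' structure is real: ten exons on chromosome 14 (Build-37-style
#' coordinates), a ~2,500 bp promoter, introns each below 2,000 bp, a
#' ~2,000 bp downstream enhancer region (DER) and a 1,020 bp CDS. Exact
#' exon/intron lengths, the anchor coordinate and the CDS sequence are
#' deterministic inventions; do not use this model to interpret real
#' genomic positions.
#'
#' The CDS sequence is drawn from a fixed stream, with the codons hit by
#' the reconstructed coding SNPs forced to `GAA` so that every coding SNP
#' is synonymous (`GAA -> GAG`), matching the published observation that
#' no coding substitution changes an amino acid.
#'
#' @param tss Genomic coordinate assigned to the transcription start.
#' @return A [gene_model()].
#' @export
ctsb_gene_model <- function(tss = 63254000L) {
  exon_len <- c(200L, 120L, 140L, 110L, 130L, 120L, 110L, 130L, 100L, 600L)
  intron_len <- c(900L, 700L, 800L, 700L, 1900L, 500L, 400L, 1200L, 700L)
  starts <- tss + cumsum(c(0L, head(exon_len + c(intron_len, 0L), -1)))
  exons <- tibble::tibble(start = starts, end = starts + exon_len - 1L)
  cds_len <- 1020L
  cds <- with_seed(140237L, sample(c("A", "C", "G", "T"), cds_len, replace = TRUE))
  for (k in ctsb_coding_codons()) {
    cds[(k - 1) * 3 + 1:3] <- c("G", "A", "A")
  }
  gene_model(chrom = "chr14", strand = "+", exons = exons,
             promoter_span = 2500L, der_span = 2000L,
             cds_start = 171L, cds_len = cds_len,
             cds_seq = paste(cds, collapse = ""),
             coord_system = "synthetic Build-37-style, 1-based")
}

# Codon indices carrying the reconstructed (synonymous) coding SNPs.
ctsb_coding_codons <- function() c(20L, 60L, 150L, 230L, 310L, 335L)

#' Synthetic reconstruction of the Ctsb allelic variant table
#'
#' A deterministic variant table for the high- vs low-anxiety line Ctsb
#' locus, reconstructed from the published *summary* accounting because the
#' underlying row-level table is not machine-readable. Every printed
#' marginal is reproduced exactly:
#' * 76 SNPs, 8 insertions and 9 deletions in total (~90 polymorphisms);
#' * ten SNPs and two insertions in the promoter;
#' * eight polymorphic sites in the ten exons, all SNPs, all coding ones
#'   synonymous;
#' * six variants inside a 230 bp promoter window (-2,269 .. -2,045
#'   relative to the TSS);
#' * 18 variants in a 550 bp window of intron 3 and 12 more in a 400 bp
#'   window of intron 4;
#' * 12 variants condensed in a 350 bp window of the DER;
#' * the remaining variants scattered over introns and DER, which hold the
#'   vast majority of all sites.
#'
#' Individual positions and alleles between those constraints are
#' synthetic. The same table ships as the plain-text fixture
#' `inst/extdata/ctsb_variants_synthetic.tsv`.
#'
#' @param model The [ctsb_gene_model()] to annotate against.
#' @return Annotated variant tibble with columns `type`,
#'   `genomic_position`, `hab_allele`, `lab_allele`, `location`, `utr`,
#'   `rel_position`, `mrna_position`, `snp_id`.
#' @examples
#' tally_variants(ctsb_variant_table())
#' @export
ctsb_variant_table <- function(model = ctsb_gene_model()) {
  tss <- model$tss
  rel_row <- function(rel, type) tibble::tibble(genomic_position = tss + rel,
                                                type = type)
  # promoter: dense 230-bp cluster (-2269..-2049) plus scattered sites
  promoter <- dplyr::bind_rows(
    rel_row(c(-2269L, -2225L, -2137L, -2093L, -2049L), "SNP"),
    rel_row(-2181L, "insertion"),
    rel_row(c(-1800L, -1500L, -1200L, -600L, -300L), "SNP"),
    rel_row(-900L, "insertion")
  )
  # exons: one 5'UTR, six synonymous coding, one 3'UTR site - all SNPs
  coding_mrna <- 170L + 3L * ctsb_coding_codons()
  exonic <- tibble::tibble(
    genomic_position = mrna_to_genomic(model, c(100L, coding_mrna, 1400L)),
    type = "SNP"
  )
  # intron 3: 18 variants spanning exactly one 550-bp window
  cl_a_pos <- tss + 2100L + round(549 * (0:17) / 17)
  cl_a <- tibble::tibble(
    genomic_position = as.integer(cl_a_pos),
    type = replace(rep("SNP", 18), c(5, 12, 9, 16),
                   c("insertion", "insertion", "deletion", "deletion"))
  )
  # intron 4: 12 variants spanning one 400-bp window
  cl_b_pos <- tss + 3220L + round(399 * (0:11) / 11)
  cl_b <- tibble::tibble(
    genomic_position = as.integer(cl_b_pos),
    type = replace(rep("SNP", 12), c(6, 3, 10),
                   c("insertion", "deletion", "deletion"))
  )
  # scattered intronic sites (introns 1, 2, 5-8)
  sc_rel <- c(300L, 500L, 700L, 900L, 1080L,
              1280L, 1380L, 1480L,
              4250L, 4450L, 4650L, 4850L, 5050L, 5250L, 5450L, 5650L,
              5920L, 6070L, 6220L,
              6530L, 6680L,
              7060L, 7260L, 7460L, 7660L, 7860L, 8060L)
  sc_type <- rep("SNP", length(sc_rel))
  sc_type[sc_rel %in% c(4450L, 7460L)] <- "insertion"
  sc_type[sc_rel %in% c(500L, 6070L, 8060L)] <- "deletion"
  scattered <- tibble::tibble(genomic_position = tss + sc_rel, type = sc_type)
  # DER: 12 variants in one 350-bp window plus scattered sites
  der_pos <- tss + 10000L + round(349 * (0:11) / 11)
  der_cl <- tibble::tibble(
    genomic_position = as.integer(der_pos),
    type = replace(rep("SNP", 12), c(4, 9), c("insertion", "deletion"))
  )
  der_sc <- tibble::tibble(
    genomic_position = tss + c(9650L, 10800L, 11200L, 11500L),
    type = c("SNP", "SNP", "deletion", "SNP")
  )
  v <- dplyr::bind_rows(promoter, exonic, cl_a, cl_b, scattered, der_cl, der_sc)
  v <- fill_alleles(v[, c("type", "genomic_position")])
  # coding SNPs: GAA -> GAG, third-position, synonymous by construction
  coding_gpos <- mrna_to_genomic(model, coding_mrna)
  v$hab_allele[v$genomic_position %in% coding_gpos] <- "A"
  v$lab_allele[v$genomic_position %in% coding_gpos] <- "G"
  v$snp_id <- "."
  out <- annotate_variants(v, model)
  dplyr::arrange(out, .data$genomic_position)[
    , c("type", "genomic_position", "hab_allele", "lab_allele",
        "location", "utr", "rel_position", "mrna_position", "snp_id")]
}
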