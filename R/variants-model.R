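#' Construct a single-locus gene model
#'
#' Describes the sequencing footprint of one gene: a promoter span upstream
#' of the transcription start site (TSS), exons with optional CDS (hence
#' UTR) boundaries, the introns between them, and a downstream enhancer
#' region (DER) past the gene end. Coordinates are 1-based inclusive
#' genomic positions; promoter offsets are negative relative to the TSS.
#'
#' @param chrom Chromosome label.
#' @param strand `"+"` or `"-"`.
#' @param exons Tibble/data frame with columns `start`, `end` (genomic,
#'   ascending, non-overlapping). The TSS is the transcription-order first
#'   base (first exon start on `"+"`, last exon end on `"-"`).
#' @param promoter_span Width (bp) of the promoter upstream of the TSS.
#' @param der_span Width (bp) of the downstream enhancer region past the
#'   gene end.
#' @param cds_start 1-based position of the first coding base in the
#'   spliced mRNA (NULL if no CDS annotation).
#' @param cds_len Length of the CDS in bases (a multiple of 3).
#' @param cds_seq Optional CDS nucleotide sequence (length `cds_len`),
#'   required by [coding_consequence()].
#' @param coord_system Free-text declaration of the coordinate namespace
#'   (e.g. a genome build).
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(chrom, strand = "+", exons, promoter_span = 2500L,
                       der_span = 2000L, cds_start = NULL, cds_len = NULL,
                       cds_seq = NULL, coord_system = "1-based genomic") {
  exons <- tibble::as_tibble(exons)
  assert_cols(exons, c("start", "end"), "exons")
  if (!strand %in% c("+", "-")) abort("strand must be '+' or '-'")
  if (nrow(exons) == 0) abort("need at least one exon")
  if (any(exons$end < exons$start)) abort("exon end before start")
  o <- order(exons$start)
  exons <- exons[o, ]
  if (nrow(exons) > 1 && any(exons$start[-1] <= exons$end[-nrow(exons)])) {
    abort("exons must be non-overlapping and ordered")
  }
  if (!is.null(cds_start)) {
    if (is.null(cds_len) || cds_len %% 3 != 0) {
      abort("`cds_len` must accompany `cds_start` and be a multiple of 3")
    }
    if (cds_start + cds_len - 1 > sum(exons$end - exons$start + 1)) {
      abort("CDS extends past the spliced mRNA")
    }
  }
  if (!is.null(cds_seq) && nchar(cds_seq) != cds_len) {
    abort("`cds_seq` length must equal `cds_len`")
  }
  tss <- if (strand == "+") exons$start[1] else exons$end[nrow(exons)]
  structure(list(chrom = chrom, strand = strand, exons = exons,
                 promoter_span = as.integer(promoter_span),
                 der_span = as.integer(der_span), tss = tss,
                 cds_start = cds_start, cds_len = cds_len, cds_seq = cds_seq,
                 coord_system = coord_system),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("<gene_model>", x$chrom, paste0("(", x$strand, ")"),
      x$coord_system, "\n")
  cat(sprintf("  %d exons, gene body %d..%d, promoter %d bp, DER %d bp\n",
              nrow(x$exons), min(x$exons$start), max(x$exons$end),
              x$promoter_span, x$der_span))
  if (!is.null(x$cds_start)) {
    cat(sprintf("  CDS: mRNA %d..%d (%d codons)\n", x$cds_start,
                x$cds_start + x$cds_len - 1, x$cds_len / 3))
  }
  invisible(x)
}

# Exons in transcription order, with cumulative spliced-mRNA offsets.
transcript_exons <- function(model) {
  ex <- model$exons
  if (model$strand == "-") ex <- ex[rev(seq_len(nrow(ex))), ]
  ex$len <- ex$end - ex$start + 1
  ex$mrna_start <- cumsum(dplyr::lag(ex$len, default = 0L)) + 1L
  ex$mrna_end <- ex$mrna_start + ex$len - 1L
  ex$exon_no <- seq_len(nrow(ex))
  ex
}

#' Map spliced-mRNA positions to genomic positions (and back)
#'
#' `mrna_to_genomic()` converts 1-based positions in the spliced transcript
#' (counted from the transcription start) to genomic coordinates;
#' `genomic_to_mrna()` is the inverse and returns `NA` for non-exonic
#' positions.
#'
#' @param model A [gene_model()].
#' @param pos Integer vector of positions.
#' @return Integer vector of mapped positions.
#' @export
mrna_to_genomic <- function(model, pos) {
  ex <- transcript_exons(model)
  vapply(pos, function(p) {
    i <- which(p >= ex$mrna_start & p <= ex$mrna_end)
    if (length(i) == 0) return(NA_integer_)
    off <- p - ex$mrna_start[i]
    if (model$strand == "+") as.integer(ex$start[i] + off)
    else as.integer(ex$end[i] - off)
  }, integer(1))
}

#' @rdname mrna_to_genomic
#' @export
genomic_to_mrna <- function(model, pos) {
  ex <- transcript_exons(model)
  vapply(pos, function(p) {
    i <- which(p >= ex$start & p <= ex$end)
    if (length(i) == 0) return(NA_integer_)
    off <- if (model$strand == "+") p - ex$start[i] else ex$end[i] - p
    as.integer(ex$mrna_start[i] + off)
  }, integer(1))
}

# Genomic span (start, end) of a named region of the model:
# "promoter", "exon-k", "intron-k", "DER".
region_span <- function(model, label) {
  ex <- transcript_exons(model)
  gene_lo <- min(model$exons$start); gene_hi <- max(model$exons$end)
  if (label == "promoter") {
    if (model$strand == "+") c(model$tss - model$promoter_span, model$tss - 1)
    else c(model$tss + 1, model$tss + model$promoter_span)
  } else if (label == "DER") {
    if (model$strand == "+") c(gene_hi + 1, gene_hi + model$der_span)
    else c(gene_lo - model$der_span, gene_lo - 1)
  } else if (grepl("^exon-", label)) {
    k <- as.integer(sub("^exon-", "", label))
    if (is.na(k) || k > nrow(ex)) abort(paste("no such exon:", label))
    c(ex$start[k], ex$end[k])
  } else if (grepl("^intron-", label)) {
    k <- as.integer(sub("^intron-", "", label))
    if (is.na(k) || k >= nrow(ex)) abort(paste("no such intron:", label))
    # intron k lies between transcription-order exons k and k+1
    if (model$strand == "+") c(ex$end[k] + 1, ex$start[k + 1] - 1)
    else c(ex$end[k + 1] + 1, ex$start[k] - 1)
  } else {
    abort(paste("unknown region label:", label))
  }
}
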