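#' Annotate variants against a gene model
#'
#' Assigns every variant its region within the locus (`promoter`,
#' `exon-k`, `intron-k`, `DER`, or `flanking` for positions outside the
#' sequenced footprint, with a warning), its position relative to the
#' transcription start (`rel_position`, negative in the promoter), its UTR
#' status for exonic variants with CDS annotation (`utr` in
#' `{"5'UTR", "3'UTR", NA}`), and for exonic variants the offset in the
#' spliced mRNA (`mrna_position`). Annotation is idempotent and independent
#' of record order.
#'
#' @param variants Tibble with at least `type` (`"SNP"`, `"insertion"`,
#'   `"deletion"`) and `genomic_position`.
#' @param model A [gene_model()].
#' @return The input tibble with columns `location`, `utr`,
#'   `rel_position`, `mrna_position` replaced/added.
#' @export
annotate_variants <- function(variants, model) {
  assert_cols(variants, c("type", "genomic_position"))
  stopifnot(inherits(model, "gene_model"))
  ex <- transcript_exons(model)
  pos <- variants$genomic_position
  prom <- region_span(model, "promoter")
  der <- region_span(model, "DER")
  location <- rep("flanking", length(pos))
  for (k in seq_len(nrow(ex))) {
    hit <- pos >= ex$start[k] & pos <= ex$end[k]
    location[hit] <- paste0("exon-", ex$exon_no[k])
  }
  for (k in seq_len(nrow(ex) - 1)) {
    sp <- region_span(model, paste0("intron-", k))
    hit <- pos >= sp[1] & pos <= sp[2]
    location[hit] <- paste0("intron-", k)
  }
  location[pos >= prom[1] & pos <= prom[2]] <- "promoter"
  location[pos >= der[1] & pos <= der[2]] <- "DER"
  if (any(location == "flanking")) {
    warn(sprintf("%d variant(s) outside the model footprint annotated 'flanking'",
                 sum(location == "flanking")))
  }
  rel <- if (model$strand == "+") pos - model$tss else model$tss - pos
  mrna <- genomic_to_mrna(model, pos)
  utr <- rep(NA_character_, length(pos))
  if (!is.null(model$cds_start)) {
    utr[!is.na(mrna) & mrna < model$cds_start] <- "5'UTR"
    utr[!is.na(mrna) & mrna > model$cds_start + model$cds_len - 1] <- "3'UTR"
  }
  variants$location <- location
  variants$utr <- utr
  variants$rel_position <- as.integer(rel)
  variants$mrna_position <- mrna
  variants
}

# Collapse exon-k / intron-k labels to a coarse class.
region_class <- function(location) {
  dplyr::case_when(
    grepl("^exon-", location) ~ "exon",
    grepl("^intron-", location) ~ "intron",
    TRUE ~ location
  )
}

#' Tally variants by type and region class
#'
#' Counts annotated variant records in a type-by-region contingency table
#' (regions collapsed to promoter / exon / intron / DER / flanking), with
#' row, column and grand totals appended when `margins = TRUE`. Margins
#' conserve the total record count.
#'
#' @param variants Annotated variant tibble (columns `type`, `location`).
#' @param margins Append `"total"` rows/columns.
#' @return Tibble `region`, `type`, `n`.
#' @examples
#' tally_variants(ctsb_variant_table())
#' @export
tally_variants <- function(variants, margins = TRUE) {
  assert_cols(variants, c("type", "location"))
  counts <- variants |>
    dplyr::mutate(region = region_class(.data$location)) |>
    dplyr::count(.data$region, .data$type) |>
    tidyr::complete(region = unique(region_class(variants$location)),
                    type = c("SNP", "insertion", "deletion"),
                    fill = list(n = 0L))
  if (margins) {
    by_region <- counts |>
      dplyr::group_by(.data$region) |>
      dplyr::summarise(type = "total", n = sum(.data$n), .groups = "drop")
    by_type <- counts |>
      dplyr::group_by(.data$type) |>
      dplyr::summarise(region = "total", n = sum(.data$n), .groups = "drop")
    grand <- tibble::tibble(region = "total", type = "total", n = sum(counts$n))
    counts <- dplyr::bind_rows(counts, by_region, by_type, grand)
  }
  dplyr::arrange(counts, .data$region, .data$type)
}

#' Scan for dense variant clusters with a sliding window
#'
#' Slides a window of `window_bp` bases over the variant positions (windows
#' anchored at variant positions, half-open `[start, start + window_bp)`)
#' and reports the window(s) of maximal variant count, ties in position
#' order. The maximal count is monotone non-decreasing in `window_bp`.
#'
#' @param variants Variant tibble with `genomic_position` (and `location`
#'   if `region` filtering is used).
#' @param window_bp Window width in bases (>= 1).
#' @param region Optional filter: a coarse class (`"promoter"`, `"exon"`,
#'   `"intron"`, `"DER"`) or an exact label such as `"intron-3"`.
#' @return Tibble `start`, `end`, `n` of maximal-count windows
#'   (`end = start + window_bp - 1`); zero rows if no variant matches.
#' @examples
#' cluster_scan(ctsb_variant_table(), 550, region = "intron")
#' @export
cluster_scan <- function(variants, window_bp, region = NULL) {
  assert_cols(variants, "genomic_position")
  if (!is_scalar_number(window_bp) || window_bp < 1) {
    abort("`window_bp` must be >= 1")
  }
  v <- variants
  if (!is.null(region)) {
    assert_cols(v, "location")
    keep <- if (region %in% c("promoter", "exon", "intron", "DER", "flanking")) {
      region_class(v$location) == region
    } else {
      v$location == region
    }
    v <- v[keep, , drop = FALSE]
  }
  pos <- sort(v$genomic_position)
  if (length(pos) == 0) {
    return(tibble::tibble(start = integer(), end = integer(), n = integer()))
  }
  n_in <- vapply(pos, function(s) sum(pos >= s & pos < s + window_bp), integer(1))
  best <- max(n_in)
  tibble::tibble(start = as.integer(pos[n_in == best]),
                 end = as.integer(pos[n_in == best] + window_bp - 1),
                 n = as.integer(best))
}

#' Coding consequence of an exonic SNP
#'
#' Translates the codon affected by a single-nucleotide variant under both
#' line alleles and reports whether the substitution is synonymous or
#' missense. Non-exonic or UTR variants are `non-coding`; insertions or
#' deletions inside the CDS are reported as `frame-affecting` without an
#' amino-acid call.
#'
#' @param variant One-row tibble (or list) with `type`, `genomic_position`,
#'   `hab_allele`, `lab_allele`.
#' @param model A [gene_model()] with `cds_start`, `cds_len` and `cds_seq`.
#' @param codon_table Named character vector mapping codons to amino
#'   acids; defaults to the standard genetic code.
#' @return One-row tibble `consequence`, `codon_hab`, `codon_lab`,
#'   `aa_hab`, `aa_lab`.
#' @examples
#' m <- gene_model("chrT", exons = tibble::tibble(start = 1, end = 9),
#'                 promoter_span = 0, der_span = 0,
#'                 cds_start = 1, cds_len = 9, cds_seq = "TCTGAAGAA")
#' v <- tibble::tibble(type = "SNP", genomic_position = 1,
#'                     hab_allele = "T", lab_allele = "C")
#' coding_consequence(v, m)  # Ser -> Pro
#' @export
coding_consequence <- function(variant, model,
                               codon_table = genetic_code_table()) {
  variant <- tibble::as_tibble(variant)
  assert_cols(variant, c("type", "genomic_position", "hab_allele", "lab_allele"))
  if (nrow(variant) != 1) abort("`variant` must be a single record")
  if (is.null(model$cds_start) || is.null(model$cds_seq)) {
    abort("model carries no CDS sequence; cannot call consequences")
  }
  mrna <- genomic_to_mrna(model, variant$genomic_position)
  cds_pos <- mrna - model$cds_start + 1
  in_cds <- !is.na(mrna) && cds_pos >= 1 && cds_pos <= model$cds_len
  if (!in_cds) {
    return(tibble::tibble(consequence = "non-coding",
                          codon_hab = NA_character_, codon_lab = NA_character_,
                          aa_hab = NA_character_, aa_lab = NA_character_))
  }
  if (variant$type != "SNP") {
    return(tibble::tibble(consequence = "frame-affecting",
                          codon_hab = NA_character_, codon_lab = NA_character_,
                          aa_hab = NA_character_, aa_lab = NA_character_))
  }
  codon_idx <- (cds_pos - 1) %/% 3
  pos_in_codon <- (cds_pos - 1) %% 3 + 1
  codon_ref <- substr(model$cds_seq, codon_idx * 3 + 1, codon_idx * 3 + 3)
  ref_base <- substr(codon_ref, pos_in_codon, pos_in_codon)
  hab <- toupper(variant$hab_allele); lab <- toupper(variant$lab_allele)
  if (!ref_base %in% c(hab, lab)) {
    warn("neither allele matches the model CDS base at this position")
  }
  sub_base <- function(codon, base) {
    substr(codon, pos_in_codon, pos_in_codon) <- base
    codon
  }
  codon_hab <- sub_base(codon_ref, hab)
  codon_lab <- sub_base(codon_ref, lab)
  aa_hab <- unname(codon_table[codon_hab])
  aa_lab <- unname(codon_table[codon_lab])
  tibble::tibble(
    consequence = if (identical(aa_hab, aa_lab)) "synonymous"
                  else sprintf("missense(%s->%s)", aa_hab, aa_lab),
    codon_hab = codon_hab, codon_lab = codon_lab,
    aa_hab = aa_hab, aa_lab = aa_lab
  )
}

#' Standard genetic code as a codon lookup table
#'
#' Three-letter amino-acid names keyed by DNA codon, built from the
#' standard code shipped with Biostrings.
#' @return Named character vector of length 64.
#' @export
genetic_code_table <- function() {
  code <- Biostrings::GENETIC_CODE
  three <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
             Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
             L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
             S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val",
             "*" = "Stop")
  setNames(three[code], names(code))
}
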